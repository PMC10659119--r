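#' @describeIn LcmsCorpus per-run metadata table.
#' @param object an object.
#' @export
setGeneric("corpusFiles", function(object) standardGeneric("corpusFiles"))

#' @describeIn LcmsCorpus peptide evidence table.
#' @export
setGeneric("corpusPeptides", function(object) standardGeneric("corpusPeptides"))

#' @describeIn LcmsCorpus list of simulated MS2 spectra.
#' @export
setGeneric("corpusSpectra", function(object) standardGeneric("corpusSpectra"))

#' @describeIn SplitBundle training records.
#' @param object an object.
#' @export
setGeneric("trainSet", function(object) standardGeneric("trainSet"))

#' @describeIn SplitBundle validation records.
#' @export
setGeneric("validationSet", function(object) standardGeneric("validationSet"))

#' @describeIn SplitBundle hold-out test records.
#' @export
setGeneric("testSet", function(object) standardGeneric("testSet"))

#' @describeIn SpectrumPeakSet peak m/z values.
#' @param object an object.
#' @export
setGeneric("peakMz", function(object) standardGeneric("peakMz"))

#' @describeIn SpectrumPeakSet peak intensities.
#' @export
setGeneric("peakIntensity", function(object) standardGeneric("peakIntensity"))

#' @describeIn RTModel the model's weight list.
#' @param object an object.
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @describeIn RTModel per-epoch loss history.
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @describeIn RTModel the architecture/schedule configuration.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

setMethod("corpusFiles", "LcmsCorpus", function(object) object@files)
setMethod("corpusPeptides", "LcmsCorpus", function(object) object@peptides)
setMethod("corpusSpectra", "LcmsCorpus", function(object) object@spectra)
setMethod("trainSet", "SplitBundle", function(object) object@train)
setMethod("validationSet", "SplitBundle", function(object) object@validation)
setMethod("testSet", "SplitBundle", function(object) object@test)
setMethod("peakMz", "SpectrumPeakSet", function(object) object@mz)
setMethod("peakIntensity", "SpectrumPeakSet", function(object) object@intensity)
setMethod("modelParams", "RTModel", function(object) object@params)
setMethod("trainingHistory", "RTModel", function(object) object@history)
setMethod("modelConfig", "RTModel", function(object) object@config)

setMethod("show", "LcmsCorpus", function(object) {
  cat(sprintf(
    "LcmsCorpus: %d projects, %d files, %d peptides, %d spectra\n",
    length(unique(object@files$project_id)), nrow(object@files),
    nrow(object@peptides), length(object@spectra)))
})

setMethod("show", "SpectrumPeakSet", function(object) {
  cat(sprintf("SpectrumPeakSet %s (%s): %d peaks, precursor %.4f m/z (%d+)\n",
              object@spectrumId, object@fileId, length(object@mz),
              object@precursorMz, object@charge))
})

setMethod("show", "SplitBundle", function(object) {
  cat(sprintf(
    "SplitBundle (hold-out by %s, seed %d): %d train / %d validation / %d test (%d rejected)\n",
    object@holdoutLevel, object@seed, nrow(object@train),
    nrow(object@validation), nrow(object@test), nrow(object@rejected)))
})

setMethod("show", "RTModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "RTModel [%s]: embed %d, GRU %d/dir, dense (%s), dropout %.2f\n",
    if (object@trained) "trained" else "untrained",
    cfg@embeddingDim, cfg@recurrentUnits,
    paste(cfg@denseUnits, collapse = ", "), cfg@dropoutRate))
  if (object@trained) {
    cat(sprintf("  trained on '%s'%s; %d epochs, best val MSE %.5g\n",
                object@trainedOn,
                if (is.na(object@pretrainedFrom)) ""
                else sprintf(" (transferred from '%s')", object@pretrainedFrom),
                max(object@history$epoch), object@finalValLoss))
  }
})

setMethod("show", "CorpusConfig", function(object) {
  cat(sprintf(
    "CorpusConfig: %d projects x %d-%d files x %d-%d peptides (seed %d)\n",
    object@nProjects, object@filesPerProject[1], object@filesPerProject[2],
    object@peptidesPerFile[1], object@peptidesPerFile[2], object@seed))
  cat(sprintf("  gradients: P(single)=%.2f, P(>2)=%.2f, modes %s min, tail (%g, %g)\n",
              object@pSingleGradient, object@pManyGradients,
              paste(object@gradientModes$minutes, collapse = "/"),
              object@gradientTailMin, object@gradientTailMax))
  cat(sprintf("  filters: modal (%g, %g) at %.3f of files; unique-count probs %s\n",
              object@modalFilter[1], object@modalFilter[2], object@pModalFilter,
              paste(object@filterCountProbs, collapse = "/")))
  cat(sprintf("  RT noise sd (min): project %.2f, file %.2f, peptide %.2f\n",
              object@sigmaProject, object@sigmaFile, object@sigmaPeptide))
})
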