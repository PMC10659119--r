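#' @import methods
NULL

#' Configuration of the synthetic LC-MS corpus simulator
#'
#' Holds every knob of the hierarchical corpus generator: project/file/peptide
#' counts, the gradient-length mixture (discrete modes plus a long uniform
#' tail), within-project gradient and m/z-filter homogeneity probabilities,
#' the additive retention model's variance components, and the MS2 spectrum
#' simulator settings. Use [corpusConfig()] to construct one; defaults encode
#' the published large-repository conventions (70% single-gradient projects,
#' modal 350-1500 m/z window on about a third of runs, gradient modes at 60,
#' 90 and 120 minutes).
#'
#' @slot nProjects number of projects.
#' @slot filesPerProject inclusive integer range, files drawn per project.
#' @slot peptidesPerFile inclusive integer range, peptides drawn per file.
#' @slot seed integer seed; the full corpus is a deterministic function of it.
#' @slot pSingleGradient probability a project uses one gradient for all runs.
#' @slot pManyGradients probability a project uses more than two gradients.
#' @slot gradientModes data.frame with columns `minutes`, `weight`: discrete
#'   gradient-length modes; weights may sum to less than 1, the remainder is
#'   a uniform tail on (`gradientTailMin`, `gradientTailMax`).
#' @slot gradientTailMin,gradientTailMax bounds (minutes) of the tail.
#' @slot modalFilter length-2 numeric, the modal m/z acquisition window.
#' @slot pModalFilter marginal fraction of files carrying the modal window.
#' @slot filterCountProbs length-3 probabilities of 1 / 2 / >2 unique
#'   windows per project; must sum to 1.
#' @slot retentionScale named per-residue additive retention coefficients.
#' @slot sigmaProject,sigmaFile,sigmaPeptide RT noise standard deviations
#'   (minutes) of the project, file and peptide variance components.
#' @slot noiseGradientCoupling unitless; scales peptide noise with gradient
#'   length as `1 + coupling * gradient/100`.
#' @slot selectivityCoupling unitless; the sd of the per-project (per-file)
#'   perturbation of the retention coefficients is `coupling * sigmaProject`
#'   (`coupling * sigmaFile`). Models chromatographic selectivity differences
#'   between laboratories, which survive per-file gradient normalization
#'   where purely additive shifts cancel.
#' @slot edgeNoiseBoost unitless; multiplies peptide noise by
#'   `1 + boost * (2|u - 0.5|)^2` with `u` the relative elution position,
#'   amplifying noise at the gradient extremes.
#' @slot deadTimeFrac fraction of the gradient before which nothing elutes.
#' @slot lengthMean,lengthSd peptide length distribution (rounded normal,
#'   truncated to 7..30 residues).
#' @slot scoreBase,scoreLengthSlope,scoreSd identification score model:
#'   `base + slope * length + N(0, sd)`, floored at 0.
#' @slot chargeProbs probabilities of precursor charge 2 and 3.
#' @slot spectraPerFile number of MS2 spectra simulated per file.
#' @slot noisePeakRate expected number of uniform noise peaks per spectrum.
#' @slot energyRange collision-energy proxy range (uniform per spectrum).
#' @slot species labels sampled uniformly per project.
#' @exportClass CorpusConfig
setClass("CorpusConfig", representation(
  nProjects = "integer", filesPerProject = "integer",
  peptidesPerFile = "integer", seed = "integer",
  pSingleGradient = "numeric", pManyGradients = "numeric",
  gradientModes = "data.frame", gradientTailMin = "numeric",
  gradientTailMax = "numeric",
  modalFilter = "numeric", pModalFilter = "numeric",
  filterCountProbs = "numeric",
  retentionScale = "numeric",
  sigmaProject = "numeric", sigmaFile = "numeric", sigmaPeptide = "numeric",
  noiseGradientCoupling = "numeric", selectivityCoupling = "numeric",
  edgeNoiseBoost = "numeric", deadTimeFrac = "numeric",
  lengthMean = "numeric", lengthSd = "numeric",
  scoreBase = "numeric", scoreLengthSlope = "numeric", scoreSd = "numeric",
  chargeProbs = "numeric", spectraPerFile = "integer",
  noisePeakRate = "numeric", energyRange = "numeric", species = "character"
))

setValidity("CorpusConfig", function(object) {
  msg <- character()
  probs <- c(object@pSingleGradient, object@pManyGradients,
             object@pModalFilter, object@filterCountProbs,
             object@chargeProbs, object@gradientModes$weight)
  if (any(probs < 0 | probs > 1)) {
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  }
  if (abs(sum(object@filterCountProbs) - 1) > 1e-9) {
    msg <- c(msg, "filterCountProbs must sum to 1")
  }
  if (object@pSingleGradient + object@pManyGradients > 1 + 1e-9) {
    msg <- c(msg, "pSingleGradient + pManyGradients must not exceed 1")
  }
  if (sum(object@gradientModes$weight) > 1 + 1e-9) {
    msg <- c(msg, "gradient mode weights must sum to <= 1")
  }
  if (any(c(object@sigmaProject, object@sigmaFile, object@sigmaPeptide) < 0)) {
    msg <- c(msg, "sigmaProject, sigmaFile, sigmaPeptide must be >= 0")
  }
  if (object@nProjects < 1) msg <- c(msg, "nProjects must be >= 1")
  if (any(object@peptidesPerFile < 1)) {
    msg <- c(msg, "peptidesPerFile must request at least one peptide")
  }
  if (any(object@filesPerProject < 1)) {
    msg <- c(msg, "filesPerProject must request at least one file")
  }
  if (length(object@modalFilter) != 2 ||
      object@modalFilter[2] <= object@modalFilter[1]) {
    msg <- c(msg, "modalFilter must be (lower, upper) with upper > lower")
  }
  if (!all(RESIDUES %in% names(object@retentionScale))) {
    msg <- c(msg, "retentionScale must name all 20 canonical residues")
  }
  if (length(msg)) msg else TRUE
})

#' A synthetic multi-project LC-MS corpus
#'
#' Container produced by [simulateCorpus()] (or read back by [readCorpus()]):
#' per-run metadata, the identified-peptide evidence table and a list of
#' simulated MS2 spectra. Access the parts with [corpusFiles()],
#' [corpusPeptides()] and [corpusSpectra()].
#'
#' @slot files data.frame with one row per raw file: `file_id`, `project_id`,
#'   `gradient_length` (minutes), `mz_lower`, `mz_upper`, `species`.
#' @slot peptides data.frame with one row per identified peptide: `sequence`,
#'   `score`, `rt` (minutes), `rt_normalized` (NA until normalization),
#'   `precursor_mz`, `charge`, `file_id`, `project_id`.
#' @slot spectra list of [SpectrumPeakSet-class] objects.
#' @slot config the [CorpusConfig-class] used, or NULL when read from disk
#'   without one.
#' @exportClass LcmsCorpus
setClass("LcmsCorpus", representation(
  files = "data.frame", peptides = "data.frame", spectra = "list",
  config = "ANY"
))

setValidity("LcmsCorpus", function(object) {
  msg <- character()
  needF <- c("file_id", "project_id", "gradient_length", "mz_lower",
             "mz_upper", "species")
  needP <- c("sequence", "score", "rt", "rt_normalized", "precursor_mz",
             "charge", "file_id", "project_id")
  if (!all(needF %in% names(object@files))) {
    msg <- c(msg, "files table is missing required columns")
  }
  if (!all(needP %in% names(object@peptides))) {
    msg <- c(msg, "peptides table is missing required columns")
  }
  if (nrow(object@files) &&
      any(object@files$mz_upper <= object@files$mz_lower)) {
    msg <- c(msg, "every file must have mz_upper > mz_lower")
  }
  if (nrow(object@peptides) && any(object@peptides$rt < 0)) {
    msg <- c(msg, "retention times must be >= 0")
  }
  if (!all(vapply(object@spectra, is, logical(1), "SpectrumPeakSet"))) {
    msg <- c(msg, "spectra must be SpectrumPeakSet objects")
  }
  if (length(msg)) msg else TRUE
})

#' One MS2 spectrum's peak list
#'
#' @slot spectrumId,fileId identifiers.
#' @slot mz strictly increasing m/z values.
#' @slot intensity positive intensities, same length as `mz`.
#' @slot precursorMz precursor m/z.
#' @slot charge precursor charge.
#' @slot energy collision-energy proxy used by the simulator (unitless).
#' @exportClass SpectrumPeakSet
setClass("SpectrumPeakSet", representation(
  spectrumId = "character", fileId = "character",
  mz = "numeric", intensity = "numeric",
  precursorMz = "numeric", charge = "integer", energy = "numeric"
))

setValidity("SpectrumPeakSet", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity)) {
    msg <- c(msg, "mz and intensity must have equal length")
  }
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0)) {
    msg <- c(msg, "mz must be strictly increasing")
  }
  if (length(object@intensity) && any(object@intensity <= 0)) {
    msg <- c(msg, "intensities must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a stratified peptide dataset
#'
#' Mirrors the stratified dataset constructions used for model training:
#' a minimal identification score (boundary inclusive), an optional gradient
#' stratum (`short` = gradient <= 60 min, `long` = gradient >= 100 min), an
#' optional precursor m/z stratum (`lower` = m/z < 360, `upper` = m/z >
#' 1300), an optional species, excluded projects, and a peptide-count cap
#' applied by seeded uniform downsampling. Construct with [datasetSpec()].
#'
#' @slot minScore minimal identification score, inclusive.
#' @slot maxPeptides cap on retained peptides.
#' @slot gradientStratum one of "none", "short", "long".
#' @slot mzStratum one of "none", "lower", "upper".
#' @slot species optional species label (NA = no restriction).
#' @slot excludeProjects project ids removed before anything else.
#' @slot seed integer seed for the downsampling.
#' @exportClass DatasetSpec
setClass("DatasetSpec", representation(
  minScore = "numeric", maxPeptides = "numeric",
  gradientStratum = "character", mzStratum = "character",
  species = "character", excludeProjects = "character", seed = "integer"
))

setValidity("DatasetSpec", function(object) {
  msg <- character()
  if (object@minScore < 0) msg <- c(msg, "minScore must be >= 0")
  if (object@maxPeptides < 1) msg <- c(msg, "maxPeptides must be >= 1")
  if (!object@gradientStratum %in% c("none", "short", "long")) {
    msg <- c(msg, "gradientStratum must be none/short/long")
  }
  if (!object@mzStratum %in% c("none", "lower", "upper")) {
    msg <- c(msg, "mzStratum must be none/lower/upper")
  }
  if (length(msg)) msg else TRUE
})

#' Train/validation/test partition with leakage guarantees
#'
#' Produced by [buildSplitBundle()]. The hold-out test set consists of whole
#' projects (multi-project data) or whole raw files (single-project data);
#' train and validation are split by peptide sequence so no sequence occurs
#' in both. Test-train sequence overlap is permitted, matching how hold-out
#' projects/files naturally share peptides with the remainder.
#'
#' @slot train,validation,test peptide record data.frames.
#' @slot holdoutLevel `"project"` or `"file"`.
#' @slot seed the split seed.
#' @slot rejected records dropped before splitting (from degenerate files).
#' @exportClass SplitBundle
setClass("SplitBundle", representation(
  train = "data.frame", validation = "data.frame", test = "data.frame",
  holdoutLevel = "character", seed = "integer", rejected = "data.frame"
))

setValidity("SplitBundle", function(object) {
  msg <- character()
  if (length(intersect(unique(object@train$sequence),
                       unique(object@validation$sequence)))) {
    msg <- c(msg, "train and validation share peptide sequences")
  }
  unit <- if (identical(object@holdoutLevel, "project")) "project_id" else "file_id"
  tu <- unique(object@test[[unit]])
  ru <- unique(c(object@train[[unit]], object@validation[[unit]]))
  if (length(intersect(tu, ru))) {
    msg <- c(msg, sprintf("test shares %ss with train/validation", unit))
  }
  if (length(msg)) msg else TRUE
})

#' Hyperparameters of the retention-time network
#'
#' Sequence embedding, one bidirectional GRU layer, attention pooling and a
#' dense regression head, trained with Adam on mean squared error of the
#' normalized retention time, with early stopping (100 epochs, patience 20
#' by default). Construct with [rtModelConfig()].
#'
#' @slot vocab named integer map residue -> index (padding is index 0).
#' @slot maxLength maximal encodable sequence length.
#' @slot embeddingDim embedding dimension.
#' @slot recurrentUnits GRU units per direction.
#' @slot denseUnits hidden dense layer widths.
#' @slot dropoutRate dropout probability at every dropout site (after the
#'   attention context and after each hidden dense activation).
#' @slot learningRate,batchSize,maxEpochs,patience training schedule.
#' @slot seed initialization/training seed.
#' @exportClass RTModelConfig
setClass("RTModelConfig", representation(
  vocab = "integer", maxLength = "integer", embeddingDim = "integer",
  recurrentUnits = "integer", denseUnits = "integer",
  dropoutRate = "numeric", learningRate = "numeric", batchSize = "integer",
  maxEpochs = "integer", patience = "integer", seed = "integer"
))

setValidity("RTModelConfig", function(object) {
  msg <- character()
  if (object@dropoutRate < 0 || object@dropoutRate >= 1) {
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  }
  if (object@patience > object@maxEpochs) {
    msg <- c(msg, "patience must not exceed maxEpochs")
  }
  if (length(object@vocab) < 20) {
    msg <- c(msg, "vocab must cover the 20 canonical residues")
  }
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) retention-time regressor
#'
#' Weights, architecture and training history of the sequence -> normalized
#' retention time model. Built by [buildRTModel()], fitted by
#' [trainRTModel()] or [transferRTModel()].
#'
#' @slot config an [RTModelConfig-class].
#' @slot params named list of weight matrices.
#' @slot history per-epoch train/validation loss (epoch 0 is the pre-update
#'   validation loss).
#' @slot trainedOn free-text identifier of the training dataset.
#' @slot pretrainedFrom identifier of the transfer source, or NA.
#' @slot finalValLoss best validation loss (the restored weights').
#' @slot trained logical.
#' @exportClass RTModel
setClass("RTModel", representation(
  config = "RTModelConfig", params = "list", history = "data.frame",
  trainedOn = "character", pretrainedFrom = "character",
  finalValLoss = "numeric", trained = "logical"
))
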