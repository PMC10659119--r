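# shared fixtures: small corpora and reduced model configs, all built in code

tinyCorpusConfig <- function(seed = 1L, ...) {
  args <- list(nProjects = 4L, filesPerProject = c(2L, 3L),
               peptidesPerFile = c(30L, 60L), spectraPerFile = 2L,
               seed = as.integer(seed))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(corpusConfig, args)
}

noiseFreeConfig <- function(seed = 1L, ...) {
  tinyCorpusConfig(seed,
                   pSingleGradient = 1, pManyGradients = 0,
                   gradientModes = data.frame(minutes = 60, weight = 1),
                   sigmaProject = 0, sigmaFile = 0, sigmaPeptide = 0,
                   selectivityCoupling = 0, spectraPerFile = 0L, ...)
}

smallModelConfig <- function(seed = 1L, epochs = 3L, ...) {
  args <- list(embeddingDim = 8L, recurrentUnits = 12L, denseUnits = 16L,
               batchSize = 64L, maxEpochs = as.integer(epochs),
               patience = as.integer(epochs), seed = as.integer(seed))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(rtModelConfig, args)
}

normalizedPeptides <- function(corpus) {
  normalizeEffectiveGradient(corpusPeptides(corpus))
}

# train a small model once per session and reuse it across tests
.modelCache <- new.env(parent = emptyenv())

cachedSmallModel <- function() {
  if (is.null(.modelCache$model)) {
    corp <- simulateCorpus(tinyCorpusConfig(5L, nProjects = 3L,
                                            peptidesPerFile = c(60L, 60L),
                                            spectraPerFile = 0L))
    rec <- normalizedPeptides(corp)
    bundle <- buildSplitBundle(rec, holdoutLevel = "project", seed = 5L,
                               normalize = FALSE)
    model <- trainRTModel(buildRTModel(smallModelConfig(5L, epochs = 3L)),
                          trainSet(bundle), validationSet(bundle),
                          trainedOn = "cached")
    .modelCache$model <- model
    .modelCache$bundle <- bundle
  }
  list(model = .modelCache$model, bundle = .modelCache$bundle)
}
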