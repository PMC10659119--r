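test_that("sequence encoding pads right and round-trips", {
  cfg <- smallModelConfig(maxLength = 4L)
  enc <- encodeSequences("GA", cfg)
  expect_equal(enc$x[1, ], c(cfg@vocab[["G"]], cfg@vocab[["A"]], 0L, 0L),
               ignore_attr = TRUE)
  empty <- encodeSequences(character(0), cfg)
  expect_equal(dim(empty$x), c(0, 4))
  expect_error(encodeSequences("GAGAGAGAG", cfg), "maxLength")
  expect_error(encodeSequences("GXA", cfg), "invalid residue")

  cfg30 <- smallModelConfig()
  seqs <- withr::with_seed(1L, vapply(1:200, function(i) {
    paste(sample(names(cfg30@vocab), sample(7:30, 1), replace = TRUE),
          collapse = "")
  }, character(1)))
  enc2 <- encodeSequences(seqs, cfg30)
  expect_identical(decodeSequences(enc2$x, cfg30), seqs)
})

test_that("model construction is seeded and shape-correct", {
  cfg <- smallModelConfig(3L)
  m1 <- buildRTModel(cfg)
  m2 <- buildRTModel(cfg)
  expect_identical(modelParams(m1), modelParams(m2))
  m3 <- buildRTModel(smallModelConfig(4L))
  expect_false(identical(modelParams(m1), modelParams(m3)))
  expect_equal(dim(modelParams(m1)$Emb), c(21, cfg@embeddingDim))
  expect_equal(dim(modelParams(m1)$denseW[[1]]),
               c(2 * cfg@recurrentUnits, cfg@denseUnits[1]))
  expect_error(rtModelConfig(dropoutRate = 1), "dropoutRate")
  expect_error(rtModelConfig(patience = 200L, maxEpochs = 100L), "patience")
})

test_that("attention weights are a masked softmax over real positions", {
  cfg <- smallModelConfig(3L)
  m <- buildRTModel(cfg)
  seqs <- c("GARFIELDK", "CAT", "ACDEFGHIKLMNPQRSTVWY")
  enc <- encodeSequences(seqs, cfg)
  masks <- rtvarlab:::.onesMasks(3L, cfg)
  res <- rtvarlab:::rtnet_eval(modelParams(m), enc$x, numeric(0),
                               masks$ctx, masks$dense, FALSE)
  alpha <- res$attention
  expect_equal(rowSums(alpha), rep(1, 3), tolerance = 1e-6)
  expect_true(all(alpha >= 0))
  # padded positions carry exactly zero weight
  expect_true(all(alpha[2, 4:30] == 0))
  expect_length(res$pred, 3)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- rtModelConfig(embeddingDim = 3L, recurrentUnits = 4L,
                       denseUnits = 5L, maxLength = 6L, seed = 8L)
  params <- modelParams(buildRTModel(cfg))
  X <- withr::with_seed(2L,
    matrix(c(sample.int(20, 12, TRUE), 0L, 0L, 0L, 0L, 0L, 0L), 3, 6))
  X[X[, 1] == 0, 1] <- 1L  # every sequence nonempty
  storage.mode(X) <- "integer"
  y <- c(0.2, 0.5, 0.8)
  masks <- withr::with_seed(3L, rtvarlab:::.dropMasks(3L, cfg))
  res <- rtvarlab:::rtnet_eval(params, X, y, masks$ctx, masks$dense, TRUE)
  flat <- function(p) unlist(p, use.names = FALSE)
  gA <- flat(res$grads[names(params)])
  pv <- flat(params)
  relist <- function(v) utils::relist(v, params)
  eps <- 1e-6
  idx <- withr::with_seed(4L, sort(sample(length(pv), 80)))
  gN <- vapply(idx, function(i) {
    up <- pv; up[i] <- up[i] + eps
    dn <- pv; dn[i] <- dn[i] - eps
    lp <- rtvarlab:::rtnet_eval(relist(up), X, y, masks$ctx, masks$dense,
                                FALSE)$loss
    lm <- rtvarlab:::rtnet_eval(relist(dn), X, y, masks$ctx, masks$dense,
                                FALSE)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  relerr <- abs(gN - gA[idx]) / pmax(1e-6, abs(gN) + abs(gA[idx]))
  expect_lt(max(relerr), 1e-4)
})

test_that("prediction is deterministic, permutation-equivariant and chunk-free", {
  fx <- cachedSmallModel()
  te <- testSet(fx$bundle)
  p1 <- predictRt(fx$model, te)
  p2 <- predictRt(fx$model, te)
  expect_identical(p1, p2)
  perm <- withr::with_seed(9L, sample(nrow(te)))
  expect_equal(predictRt(fx$model, te[perm, ]), p1[perm], tolerance = 1e-10)
  expect_equal(predictRt(fx$model, te, chunkSize = 7L), p1,
               tolerance = 1e-5)
  expect_error(predictRt(buildRTModel(smallModelConfig()), te), "untrained")
})

test_that("evaluation metrics follow their definitions", {
  ev <- evaluateRt(c(0.1, 0.2), c(0.15, 0.25))
  expect_equal(ev$mae, 0.05)
  expect_equal(ev$mse, 0.0025)
  expect_equal(ev$rt_delta, 0.05)
  expect_equal(ev$n, 2)
  expect_equal(evaluateRt(c(0.3, 0.7), c(0.3, 0.7))$mse, 0)
  a <- evaluateRt(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.8))
  b <- evaluateRt(c(0.9, 0.1, 0.5), c(0.8, 0.2, 0.4))
  expect_equal(a, b)
  expect_error(evaluateRt(1:3, 1:2), "length")
})

test_that("training minimizes loss on a learnable deterministic target", {
  corp <- simulateCorpus(noiseFreeConfig(71L, nProjects = 2L,
                                         filesPerProject = c(2L, 2L),
                                         peptidesPerFile = c(200L, 200L)))
  rec <- normalizedPeptides(corp)
  b <- buildSplitBundle(rec, holdoutLevel = "file", seed = 1L,
                        normalize = FALSE)
  m <- trainRTModel(buildRTModel(smallModelConfig(1L, epochs = 12L)),
                    trainSet(b), validationSet(b))
  h <- trainingHistory(m)
  expect_equal(h$epoch[1], 0)
  expect_gt(h$val_loss[1] / m@finalValLoss, 10)  # >= 10x improvement
  expect_true(m@trained)
  expect_lte(nrow(h), m@config@maxEpochs + 1)
})

test_that("training starts from the supplied weights and restores the best", {
  fx <- cachedSmallModel()
  m0 <- buildRTModel(smallModelConfig(5L, epochs = 3L))
  va <- validationSet(fx$bundle)
  manual <- mean((rtvarlab:::.forwardChunks(
    modelParams(m0), encodeSequences(va, m0@config)$x, m0@config) -
      va$rt_normalized)^2)
  expect_equal(trainingHistory(fx$model)$val_loss[1], manual,
               tolerance = 1e-10)
  expect_equal(m0@config@seed, fx$model@config@seed)
  # restored weights reproduce the recorded best validation loss
  best <- mean((predictRt(fx$model, va) - va$rt_normalized)^2)
  expect_equal(best, fx$model@finalValLoss, tolerance = 1e-10)
})

test_that("transfer copies source weights and records provenance", {
  fx <- cachedSmallModel()
  src <- fx$model
  tm <- transferRTModel(src, trainSet(fx$bundle), validationSet(fx$bundle),
                        trainedOn = "same-data")
  # before the first update the transferred model IS the source: its
  # epoch-0 validation loss on the source's own data equals the source's
  # final (best, restored) validation loss
  expect_equal(trainingHistory(tm)$val_loss[1], src@finalValLoss,
               tolerance = 1e-5)
  expect_identical(tm@pretrainedFrom, "cached")
  expect_error(transferRTModel(buildRTModel(smallModelConfig()),
                               trainSet(fx$bundle),
                               validationSet(fx$bundle)), "trained")
  expect_error(assertSameArchitecture(smallModelConfig(),
                                      smallModelConfig(embeddingDim = 9L)),
               "embeddingDim")
})
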