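mkRecords <- function(score = c(90, 100, 150), mz = c(350, 360, 400)) {
  n <- max(length(score), length(mz))
  data.frame(sequence = paste0("PEPTIDEK", seq_len(n)),
             score = rep_len(score, n), rt = seq_len(n),
             rt_normalized = NA_real_, precursor_mz = rep_len(mz, n),
             charge = 2L, file_id = "f1", project_id = "p1",
             stringsAsFactors = FALSE)
}

test_that("score and m/z strata follow the stated boundary semantics", {
  rec <- mkRecords()
  kept <- filterPeptides(rec, datasetSpec(minScore = 100))
  expect_equal(nrow(kept), 2)           # >= 100 is inclusive
  low <- filterPeptides(rec, datasetSpec(minScore = 0, mzStratum = "lower"))
  expect_equal(nrow(low), 1)            # strictly below 360
  expect_equal(low$precursor_mz, 350)
  up <- filterPeptides(rec, datasetSpec(minScore = 0, mzStratum = "upper"))
  expect_equal(nrow(up), 0)             # strictly above 1300
})

test_that("gradient strata evaluate against per-file metadata", {
  corp <- simulateCorpus(tinyCorpusConfig(51L, nProjects = 20L,
                                          spectraPerFile = 0L))
  rec <- corpusPeptides(corp)
  files <- corpusFiles(corp)
  short <- filterPeptides(rec, datasetSpec(minScore = 0,
                                           gradientStratum = "short"), files)
  long <- filterPeptides(rec, datasetSpec(minScore = 0,
                                          gradientStratum = "long"), files)
  g <- files$gradient_length[match(short$file_id, files$file_id)]
  expect_true(all(g <= 60))
  g2 <- files$gradient_length[match(long$file_id, files$file_id)]
  expect_true(all(g2 >= 100))
  expect_error(filterPeptides(rec, datasetSpec(gradientStratum = "short")),
               "metadata")
})

test_that("downsampling is seeded, capped and idempotent", {
  rec <- mkRecords(score = rep(200, 10))
  spec <- datasetSpec(minScore = 0, maxPeptides = 3, seed = 99L)
  a <- filterPeptides(rec, spec)
  b <- filterPeptides(rec, spec)
  expect_equal(nrow(a), 3)
  expect_identical(a, b)
  expect_identical(filterPeptides(a, spec), a)  # filtering twice = identity
})

test_that("modified peptides are removed by alphabet", {
  rec <- data.frame(sequence = c("PEPTIDE", "PEM(ox)TIDE", "peptide",
                                 "ACDEFGHIK", "SEQ_WITH_X"),
                    stringsAsFactors = FALSE)
  out <- removeModified(rec)
  expect_equal(out$sequence, c("PEPTIDE", "ACDEFGHIK"))
})

test_that("effective-gradient normalization maps endpoints exactly", {
  rec <- data.frame(file_id = "f", rt = c(5, 10, 15))
  out <- normalizeEffectiveGradient(rec)
  expect_equal(out$rt_normalized, c(0, 0.5, 1))
  rec2 <- data.frame(file_id = "f", rt = c(7, 7, 9))
  expect_equal(normalizeEffectiveGradient(rec2)$rt_normalized, c(0, 0, 1))
  # affine invariance: same elution order on different gradients gives
  # identical normalized vectors
  rec3 <- data.frame(file_id = c(rep("a", 4), rep("b", 4)),
                     rt = c(6, 12, 18, 24, 15, 30, 45, 60))
  out3 <- normalizeEffectiveGradient(rec3)
  expect_equal(out3$rt_normalized[1:4], out3$rt_normalized[5:8])
  # raw retention times are retained
  expect_true("rt" %in% names(out3) && all(out3$rt == rec3$rt))
})

test_that("degenerate files are rejected loudly, not zeroed", {
  rec <- data.frame(file_id = c("ok", "ok", "flat", "flat"),
                    rt = c(1, 2, 5, 5))
  expect_warning(out <- normalizeEffectiveGradient(rec), "flat")
  expect_equal(attr(out, "rejectedFiles"), "flat")
  expect_equal(nrow(out), 2)
  expect_equal(nrow(attr(out, "rejected")), 2)
})

test_that("hold-out split takes whole units closest to the target share", {
  rec <- data.frame(sequence = sprintf("S%03d", 1:100),
                    project_id = rep(sprintf("p%02d", 1:10), each = 10),
                    file_id = rep(sprintf("f%02d", 1:10), each = 10),
                    rt = 1, stringsAsFactors = FALSE)
  sp <- holdoutSplit(rec, "project", fraction = 0.10, seed = 3L)
  expect_length(sp$testUnits, 1)
  expect_equal(nrow(sp$test), 10)
  spf <- holdoutSplit(rec, "file", fraction = 0.10, seed = 3L)
  expect_length(spf$testUnits, 1)

  # unequal projects 50/30/10/10%: the test set is exactly one 10% project
  rec2 <- data.frame(sequence = sprintf("S%03d", 1:100),
                     project_id = rep(c("big", "mid", "sm1", "sm2"),
                                      c(50, 30, 10, 10)),
                     file_id = "f", rt = 1, stringsAsFactors = FALSE)
  for (s in 1:10) {
    sp2 <- holdoutSplit(rec2, "project", fraction = 0.10, seed = s)
    expect_true(sp2$testUnits %in% c("sm1", "sm2"))
    expect_length(sp2$testUnits, 1)
  }
  one <- rec2[rec2$project_id == "big", ]
  expect_error(holdoutSplit(one, "project"), "other level")
})

test_that("sequence split keeps records together with zero overlap", {
  rec <- data.frame(sequence = rep(sprintf("S%02d", 1:10), each = 3),
                    file_id = rep(c("a", "b", "c"), 10),
                    project_id = "p", rt = 1, stringsAsFactors = FALSE)
  sp <- trainValSplitBySequence(rec, ratio = 0.8, seed = 1L)
  expect_equal(length(unique(sp$train$sequence)), 8)
  expect_equal(length(unique(sp$validation$sequence)), 2)
  expect_length(intersect(sp$train$sequence, sp$validation$sequence), 0)
  # all 3 records of any sequence travel together
  tab <- table(sp$train$sequence)
  expect_true(all(tab == 3))
})

test_that("a full bundle conserves records and holds its guarantees", {
  corp <- simulateCorpus(tinyCorpusConfig(61L, spectraPerFile = 0L))
  rec <- corpusPeptides(corp)
  bundle <- buildSplitBundle(rec, seed = 2L)
  expect_s4_class(bundle, "SplitBundle")
  expect_equal(nrow(trainSet(bundle)) + nrow(validationSet(bundle)) +
                 nrow(testSet(bundle)) + nrow(bundle@rejected), nrow(rec))
  expect_length(intersect(trainSet(bundle)$sequence,
                          validationSet(bundle)$sequence), 0)
  expect_length(intersect(testSet(bundle)$project_id,
                          c(trainSet(bundle)$project_id,
                            validationSet(bundle)$project_id)), 0)
  # hold-out share is near, not exactly, 10% (whole-unit splitting)
  share <- nrow(testSet(bundle)) / nrow(rec)
  expect_gt(share, 0.02)
  expect_lt(share, 0.35)
  # manifest writing
  d <- file.path(tempdir(), "bundle_out")
  writeSplitBundle(bundle, d)
  man <- jsonlite::read_json(file.path(d, "split_manifest.json"))
  expect_equal(man$n_train, nrow(trainSet(bundle)))
  expect_true(file.exists(file.path(d, "train.csv")))
})
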