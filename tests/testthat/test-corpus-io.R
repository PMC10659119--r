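test_that("a corpus round-trips through CSV + MGF with stable bytes", {
  corp <- simulateCorpus(tinyCorpusConfig(31L))
  d1 <- file.path(tempdir(), "corpus_rt1")
  d2 <- file.path(tempdir(), "corpus_rt2")
  writeCorpus(corp, d1)
  back <- readCorpus(d1)
  expect_equal(corpusFiles(back)$file_id, corpusFiles(corp)$file_id)
  expect_equal(corpusFiles(back)$gradient_length,
               corpusFiles(corp)$gradient_length, tolerance = 1e-4)
  expect_equal(corpusPeptides(back)$sequence, corpusPeptides(corp)$sequence)
  expect_equal(corpusPeptides(back)$rt, corpusPeptides(corp)$rt,
               tolerance = 1e-6)
  expect_equal(length(corpusSpectra(back)), length(corpusSpectra(corp)))
  s1 <- corpusSpectra(corp)[[3]]
  s2 <- corpusSpectra(back)[[3]]
  expect_equal(peakMz(s2), peakMz(s1), tolerance = 1e-6)
  expect_equal(s2@precursorMz, s1@precursorMz, tolerance = 1e-6)
  expect_identical(s2@spectrumId, s1@spectrumId)
  # second write of the re-read corpus is byte-identical
  writeCorpus(back, d2)
  for (f in c("files.csv", "peptides.csv", "spectra.mgf")) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)))
  }
})

test_that("an empty corpus writes valid files and round-trips", {
  empty <- new("LcmsCorpus",
               files = data.frame(file_id = character(),
                                  project_id = character(),
                                  gradient_length = numeric(),
                                  mz_lower = numeric(),
                                  mz_upper = numeric(),
                                  species = character()),
               peptides = data.frame(sequence = character(),
                                     score = numeric(), rt = numeric(),
                                     rt_normalized = numeric(),
                                     precursor_mz = numeric(),
                                     charge = integer(),
                                     file_id = character(),
                                     project_id = character()),
               spectra = list(), config = NULL)
  d <- file.path(tempdir(), "corpus_empty")
  writeCorpus(empty, d)
  back <- readCorpus(d)
  expect_equal(nrow(corpusFiles(back)), 0)
  expect_equal(nrow(corpusPeptides(back)), 0)
  expect_length(corpusSpectra(back), 0)
})

test_that("malformed MGF input names the offending line", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=s1 FILE=f1", "PEPMASS=500.1",
               "CHARGE=2+", "100.0 33.0", "oops", "END IONS"), f)
  expect_error(readMgf(f), "line 6")
  writeLines(c("NOT A BLOCK"), f)
  expect_error(readMgf(f), "expected BEGIN IONS")
  writeLines(c("BEGIN IONS", "TITLE=s1", "100.0 5.0"), f)
  expect_error(readMgf(f), "unterminated")
})

test_that("corpus configuration round-trips through YAML", {
  cfg <- tinyCorpusConfig(9L, sigmaProject = 2.5)
  f <- tempfile(fileext = ".yaml")
  writeCorpusConfig(cfg, f)
  back <- readCorpusConfig(f)
  expect_equal(back@sigmaProject, 2.5)
  expect_equal(back@gradientModes, cfg@gradientModes)
  expect_equal(back@retentionScale, cfg@retentionScale)
  expect_identical(corpusPeptides(simulateCorpus(back)),
                   corpusPeptides(simulateCorpus(cfg)))
})
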