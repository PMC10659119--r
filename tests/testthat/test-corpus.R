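test_that("degenerate probabilities collapse the metadata hierarchy", {
  corp <- simulateCorpus(tinyCorpusConfig(2L, nProjects = 10L,
                                          pSingleGradient = 1,
                                          pManyGradients = 0,
                                          spectraPerFile = 0L))
  u <- uniqueValuesPerProject(corpusFiles(corp), "gradient_length")
  expect_true(all(u$counts_per_project == 1))

  corp2 <- simulateCorpus(tinyCorpusConfig(3L, nProjects = 8L,
                                           pModalFilter = 1,
                                           spectraPerFile = 0L))
  files <- corpusFiles(corp2)
  expect_true(all(files$mz_lower == 350 & files$mz_upper == 1500))
})

test_that("the corpus is a deterministic function of its configuration", {
  cfg <- tinyCorpusConfig(11L)
  a <- simulateCorpus(cfg)
  b <- simulateCorpus(cfg)
  expect_identical(corpusFiles(a), corpusFiles(b))
  expect_identical(corpusPeptides(a), corpusPeptides(b))
  expect_identical(corpusSpectra(a)[[1]]@mz, corpusSpectra(b)[[1]]@mz)
  c2 <- simulateCorpus(tinyCorpusConfig(12L))
  expect_false(identical(corpusPeptides(a)$rt, corpusPeptides(c2)$rt))
})

test_that("every recorded precursor lies inside its file's m/z window", {
  corp <- simulateCorpus(tinyCorpusConfig(7L, nProjects = 6L))
  pep <- corpusPeptides(corp)
  files <- corpusFiles(corp)
  m <- match(pep$file_id, files$file_id)
  expect_true(all(pep$precursor_mz >= files$mz_lower[m] &
                    pep$precursor_mz <= files$mz_upper[m]))
  expect_true(all(pep$rt >= 0 &
                    pep$rt <= files$gradient_length[m] + 1e-9))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep$sequence)))
})

test_that("noise-free retention time is an exact monotone map of coefficient sums", {
  cfg <- noiseFreeConfig(1L)
  fm <- list(gradient_length = 60)
  # equal coefficient sums (permuted sequences) elute identically
  rt <- simulateRetentionTime(c("GASPV", "VPSAG", "WWWWW"), fm, config = cfg)
  expect_equal(rt[1], rt[2])
  scale <- cfg@retentionScale
  sums <- c(sum(scale[strsplit("GASPV", "")[[1]]]),
            sum(scale[strsplit("WWWWW", "")[[1]]]))
  expect_equal(order(rt[c(1, 3)]), order(sums))
  # dead time: nothing elutes before 5% of the gradient
  expect_true(all(rt >= 0.05 * 60 - 1e-9))
  # same peptide, same effects, sigma zero: identical across files
  rt2 <- simulateRetentionTime("GASPV", fm, projectEffect = 2,
                               fileEffect = 0, config = cfg)
  rt3 <- simulateRetentionTime("GASPV", fm, projectEffect = 2,
                               fileEffect = 0, config = cfg)
  expect_identical(rt2, rt3)
  expect_error(simulateRetentionTime("GAXSP", fm, config = cfg),
               "non-canonical")
})

test_that("between-project RT variance dominates when sigma_project = 3 sigma_file", {
  # one-way variance decomposition of a shared peptide's RT across a
  # hierarchy drawn exactly as the generator draws it
  cfg <- noiseFreeConfig(1L, sigmaProject = 3, sigmaFile = 1)
  fm <- list(gradient_length = 60)
  set.seed(42)
  nProj <- 60L
  nFile <- 4L
  rt <- matrix(0, nProj, nFile)
  for (p in seq_len(nProj)) {
    pe <- rnorm(1, 0, cfg@sigmaProject)
    for (f in seq_len(nFile)) {
      fe <- rnorm(1, 0, cfg@sigmaFile)
      rt[p, f] <- simulateRetentionTime("ELVISLIVESK", fm, pe, fe, cfg)
    }
  }
  between <- var(rowMeans(rt))
  within <- mean(apply(rt, 1, var))
  expect_gt(between, within)
})

test_that("spectra contain exactly the b/y backbone at zero noise and energy", {
  cfg <- tinyCorpusConfig(1L, noisePeakRate = 0)
  rec <- list(sequence = "GADSK", file_id = "f1", precursor_mz = 500,
              charge = 2L)
  set.seed(1)
  sp <- simulateSpectrum(rec, cfg, energy = 0)
  expect_length(peakMz(sp), 2 * (nchar(rec$sequence) - 1))
  # b1 of G and y1 of the C-terminal K per the integer-offset convention
  rec2 <- list(sequence = "GA", file_id = "f1", precursor_mz = 200,
               charge = 2L)
  sp2 <- simulateSpectrum(rec2, cfg, energy = 0)
  expect_equal(sort(peakMz(sp2)),
               sort(c(57.02146 + 1, 71.03711 + 19)), tolerance = 1e-6)
})

test_that("higher collision energy emits more low-mass single-residue ions", {
  cfg <- tinyCorpusConfig(1L, noisePeakRate = 0)
  rec <- list(sequence = "ELVISLIVESK", file_id = "f1", precursor_mz = 600,
              charge = 2L)
  countLow <- function(energy, seed) {
    set.seed(seed)
    mean(vapply(1:200, function(i) {
      mz <- peakMz(simulateSpectrum(rec, cfg, energy = energy))
      sum(mz >= 50 & mz <= 250)
    }, numeric(1)))
  }
  expect_gt(countLow(3, 1), countLow(0.2, 1))
})

test_that("gradient histogram mass recovers the configured mode weights", {
  cfg <- tinyCorpusConfig(21L, nProjects = 400L, filesPerProject = c(5L, 5L),
                          peptidesPerFile = c(1L, 1L), spectraPerFile = 0L)
  g <- corpusFiles(simulateCorpus(cfg))$gradient_length
  expect_gte(length(g), 2000)
  for (i in seq_len(nrow(cfg@gradientModes))) {
    expect_lt(abs(mean(g == cfg@gradientModes$minutes[i]) -
                    cfg@gradientModes$weight[i]), 0.05)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(corpusConfig(filterCountProbs = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(corpusConfig(sigmaProject = -1), "must be >= 0")
  expect_error(corpusConfig(peptidesPerFile = c(0L, 0L)), "at least one")
  expect_error(corpusConfig(gradientModes = data.frame(
    minutes = c(60, 90), weight = c(0.8, 0.4))), "<= 1")
})
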