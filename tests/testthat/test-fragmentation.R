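# independent oracle: standard monoisotopic residue masses (typed from the
# IUPAC/Unimod reference values) plus the integer series offsets
ORACLE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
ORACLE_OFFSETS <- c(a = -27, b = 1, y = 19, c = 18, z = 2)

test_that("the ion table equals the brute-force mass + offset oracle", {
  tab <- buildIonTable()
  expect_equal(nrow(tab), 100)
  oracle <- outer(ORACLE_MASS, ORACLE_OFFSETS, `+`)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$mz[i], oracle[tab$residue[i], tab$ion_type[i]],
                 tolerance = 1e-5)
  }
  expect_equal(subset(tab, residue == "G" & ion_type == "y")$mz,
               57.02146 + 19, tolerance = 1e-6)
  expect_equal(subset(tab, residue == "G" & ion_type == "a")$mz,
               57.02146 - 27, tolerance = 1e-6)
  # within every residue: a < b < z < c < y, and y - b = 18 exactly
  for (r in names(ORACLE_MASS)) {
    sub <- tab[tab$residue == r, ]
    mz <- structure(sub$mz, names = sub$ion_type)
    expect_true(mz["a"] < mz["b"] && mz["b"] < mz["z"] &&
                  mz["z"] < mz["c"] && mz["c"] < mz["y"])
    expect_equal(unname(mz["y"] - mz["b"]), 18)
  }
})

mkSpec <- function(mz, intensity = NULL, id = "s1") {
  ord <- order(mz)
  new("SpectrumPeakSet", spectrumId = id, fileId = "f1", mz = mz[ord],
      intensity = (intensity %||% rep(1, length(mz)))[ord],
      precursorMz = 500, charge = 2L, energy = 1)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top-n peak picking keeps the most intense, ties to low m/z", {
  sp <- mkSpec(c(100, 200, 300, 400, 500), c(5, 1, 4, 3, 2))
  top3 <- topNPeaks(sp, 3)
  expect_equal(peakMz(top3), c(100, 300, 400))
  expect_equal(peakMz(topNPeaks(sp, 99)), peakMz(sp))  # n >= |peaks|
  tied <- mkSpec(c(100, 200, 300), c(7, 7, 7))
  expect_equal(peakMz(topNPeaks(tied, 2)), c(100, 200))
})

test_that("binning conserves in-range peaks with half-open bins", {
  sp <- mkSpec(c(100, 300))
  bd <- binPeaks(sp, 2)
  expect_equal(bd$counts, c(2, 0))
  expect_equal(sum(bd$density), 1)
  # a peak exactly at 2000 lands in the (closed) last bin
  edge <- mkSpec(c(1999.5, 2000))
  bd2 <- binPeaks(edge, 50)
  expect_equal(bd2$counts[50], 2)
  expect_equal(bd2$n_peaks_out, 0)
  out <- mkSpec(c(100, 2500))
  bd3 <- binPeaks(out, 10)
  expect_equal(bd3$n_peaks_in, 1)
  expect_equal(bd3$n_peaks_out, 1)
  # rebinning never changes the total
  expect_equal(sum(binPeaks(sp, 500)$counts), sum(binPeaks(sp, 50)$counts))
})

test_that("synthetic spectra are bimodal with one mode in 50-250 m/z", {
  cfg <- tinyCorpusConfig(91L, energyRange = c(2, 3))
  rec <- list(sequence = "ELVISLIVESKDELK", file_id = "f", precursor_mz = 800,
              charge = 2L)
  spectra <- withr::with_seed(1L, lapply(1:200, function(i)
    simulateSpectrum(rec, cfg, spectrumId = paste0("s", i))))
  bd <- binPeaks(spectra, 100)
  mid <- (head(bd$bin_edges, -1) + tail(bd$bin_edges, -1)) / 2
  low <- sum(bd$density[mid >= 50 & mid <= 250])
  high <- sum(bd$density[mid > 250])
  expect_gt(low, 0.2)   # a real mode below 250
  expect_gt(high, 0.2)  # and another above
})

test_that("the low-mass cumulative distribution is a proper CDF", {
  # one m/z value pooled from three spectra: a step function 0 -> 1
  one <- list(mkSpec(120), mkSpec(120), mkSpec(120))
  cd <- cumulativeLowMass(one)
  expect_equal(cd$cdf, c(1, 2, 3) / 3)
  expect_equal(unique(cd$mz), 120)
  unif <- mkSpec(seq(50, 250, length.out = 101))
  cdu <- cumulativeLowMass(unif)
  expect_true(all(diff(cdu$cdf) >= 0))
  expect_equal(cdu$cdf[nrow(cdu)], 1)
  # roughly linear for uniform peaks
  expect_lt(max(abs(cdu$cdf - (cdu$mz - 50) / 200)), 0.02)
  none <- mkSpec(c(300, 400))
  cdn <- cumulativeLowMass(none)
  expect_equal(nrow(cdn), 0)
  expect_true(attr(cdn, "empty"))
  expect_error(cumulativeLowMass(one, lo = 250, hi = 50))
})

test_that("annotation preserves multiple matches and shrinks with tolerance", {
  tab <- buildIonTable()
  ann <- annotateLowMassPeaks(76.02, tab, tolerance = 0.25)
  expect_true(any(ann$residue == "G" & ann$ion_type == "y"))
  expect_equal(nrow(annotateLowMassPeaks(300, tab, tolerance = 0.25)), 0)
  # K(b) = 129.095 and Q(b) = 129.0586 both match a 129.07 peak at 0.25
  multi <- annotateLowMassPeaks(129.07, tab, tolerance = 0.25)
  expect_true(all(c("K", "Q") %in% multi$residue))
  # monotone: annotations never increase as the tolerance shrinks
  mzs <- c(76.02, 129.07, 57.5, 186.1)
  nAt <- function(tol) sum(annotateLowMassPeaks(mzs, tab,
                                                tolerance = tol)$ion_type !=
                             "background")
  tols <- c(0.5, 0.25, 0.1, 0.02, 0)
  expect_true(all(diff(vapply(tols, nAt, numeric(1))) <= 0))
  # unmatched in-window peaks are labeled background
  bg <- annotateLowMassPeaks(249.9, tab, tolerance = 0.01)
  expect_equal(bg$ion_type, "background")
})

test_that("annotated fraction of low-mass peaks rises with collision energy", {
  cfg <- tinyCorpusConfig(1L, noisePeakRate = 3)
  rec <- list(sequence = "ACDEFGHIK", file_id = "f", precursor_mz = 600,
              charge = 2L)
  tab <- buildIonTable()
  # fraction of low-mass PEAK INSTANCES carrying at least one ion match
  annFrac <- function(energy, seed) {
    spectra <- withr::with_seed(seed, lapply(1:150, function(i)
      simulateSpectrum(rec, cfg, energy = energy)))
    ann <- annotateLowMassPeaks(spectra, tab)
    mz <- unlist(lapply(spectra, peakMz))
    nPeaks <- sum(mz >= 50 & mz <= 250)
    if (!nPeaks) return(0)
    1 - sum(ann$ion_type == "background") / nPeaks
  }
  expect_gt(annFrac(3, 7), annFrac(0.3, 7))
})

test_that("binned density midpoints can be annotated directly", {
  sp <- mkSpec(c(76.02, 1500))
  bd <- binPeaks(sp, 500)  # 4 m/z wide bins
  ann <- annotateLowMassPeaks(bd, buildIonTable(), tolerance = 2.1)
  expect_true(nrow(ann) >= 1)
  expect_true(all(ann$mz >= 50 & ann$mz <= 250))
})
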