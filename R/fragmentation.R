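#' Single-residue fragment-ion table
#'
#' All 100 (residue, ion type) singly charged single-residue ion masses,
#' computed by adding the series offsets a = -27, b = +1, y = +19, c = +18,
#' z = +2 to the monoisotopic residue masses. Within every residue the
#' ordering a < b < z < c < y follows directly from the offsets.
#'
#' @return data.frame of class `IonTable` with columns `residue`,
#'   `ion_type`, `mz` (100 rows).
#' @examples
#' tab <- buildIonTable()
#' subset(tab, residue == "G" & ion_type == "y")  # 57.02146 + 19
#' @export
buildIonTable <- function() {
  res <- names(RESIDUE_MASS)
  out <- expand.grid(residue = res, ion_type = names(ION_OFFSETS),
                     stringsAsFactors = FALSE)
  out$mz <- RESIDUE_MASS[out$residue] + ION_OFFSETS[out$ion_type]
  out <- out[order(out$residue, out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("IonTable", "data.frame")
  out
}

#' Keep the top-n most intense peaks of a spectrum
#'
#' Retains the `min(n, #peaks)` highest-intensity peaks; intensity ties are
#' broken towards the lower m/z. Output is m/z-sorted.
#'
#' @param spectrum a [SpectrumPeakSet-class].
#' @param n number of peaks to keep.
#' @return a [SpectrumPeakSet-class].
#' @export
topNPeaks <- function(spectrum, n) {
  stopifnot(n >= 1)
  k <- min(n, length(spectrum@mz))
  ord <- order(-spectrum@intensity, spectrum@mz)
  keep <- sort(ord[seq_len(k)])
  new("SpectrumPeakSet", spectrumId = spectrum@spectrumId,
      fileId = spectrum@fileId, mz = spectrum@mz[keep],
      intensity = spectrum@intensity[keep],
      precursorMz = spectrum@precursorMz, charge = spectrum@charge,
      energy = spectrum@energy)
}

#' Pool spectra into an m/z histogram
#'
#' Equal-width half-open bins (last bin closed, so a peak exactly at the
#' upper range edge lands in the last bin) over 0-2000 m/z by default.
#' Peaks outside the range are excluded from the counts and reported
#' separately; the bin counts always sum to the retained in-range peak
#' count.
#'
#' @param spectra a [SpectrumPeakSet-class] or list thereof.
#' @param nBins number of bins.
#' @param range m/z range, default `c(0, 2000)`.
#' @param peakSelection label recording any prior top-n selection
#'   (`"all"` or the n used).
#' @return list of class `BinnedDensity`: `bin_edges`, `counts`, `density`
#'   (sums to 1 when peaks exist), `n_peaks_in`, `n_peaks_out`,
#'   `peak_selection`.
#' @export
binPeaks <- function(spectra, nBins, range = c(0, 2000),
                     peakSelection = "all") {
  stopifnot(nBins >= 1)
  if (is(spectra, "SpectrumPeakSet")) spectra <- list(spectra)
  mz <- unlist(lapply(spectra, peakMz), use.names = FALSE)
  inRange <- mz >= range[1] & mz <= range[2]
  edges <- seq(range[1], range[2], length.out = nBins + 1)
  counts <- .binCounts(mz[inRange], edges)
  nIn <- sum(inRange)
  out <- list(bin_edges = edges, counts = counts,
              density = if (nIn > 0) counts / nIn else counts,
              n_peaks_in = nIn, n_peaks_out = sum(!inRange),
              peak_selection = as.character(peakSelection))
  class(out) <- "BinnedDensity"
  out
}

#' Cumulative distribution of low-mass peaks
#'
#' Empirical CDF of pooled peak m/z values within the low-mass window
#' (50-250 m/z by default), where single-residue ions concentrate. The CDF
#' is nondecreasing, 0 below the window and exactly 1 at the upper edge,
#' computed over in-window peaks only.
#'
#' @param spectra a [SpectrumPeakSet-class] or list thereof.
#' @param lo,hi window bounds, `lo < hi`.
#' @return data.frame with sorted `mz` and `cdf`; zero rows (with attribute
#'   `empty = TRUE`) when no peak falls in the window.
#' @export
cumulativeLowMass <- function(spectra, lo = 50, hi = 250) {
  stopifnot(lo < hi)
  if (is(spectra, "SpectrumPeakSet")) spectra <- list(spectra)
  mz <- unlist(lapply(spectra, peakMz), use.names = FALSE)
  mz <- sort(mz[mz >= lo & mz <= hi])
  if (!length(mz)) {
    out <- data.frame(mz = numeric(0), cdf = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- data.frame(mz = mz, cdf = seq_along(mz) / length(mz))
  attr(out, "empty") <- FALSE
  out
}

#' Annotate low-mass peaks with single-residue ions
#'
#' Every peak inside the low-mass window receives the full set of
#' (residue, ion type) assignments whose table mass lies within the match
#' tolerance — multiple matches are preserved, never collapsed, since
#' several residue ions can share an m/z within tolerance. Peaks without a
#' match are labeled `background`; peaks outside the window are not
#' annotated. Shrinking the tolerance can only remove annotations.
#'
#' The input may be raw peaks (numeric m/z vector, a
#' [SpectrumPeakSet-class] or a list of them) or a `BinnedDensity`, in
#' which case the midpoints of occupied bins are annotated.
#'
#' @param x peaks or a `BinnedDensity`.
#' @param table an `IonTable` from [buildIonTable()].
#' @param tolerance match tolerance in m/z, > 0 (default 0.25).
#' @param window annotation window, default `c(50, 250)`.
#' @return data.frame with `mz`, `residue`, `ion_type` (`"background"`
#'   rows carry NA residue).
#' @export
annotateLowMassPeaks <- function(x, table = buildIonTable(),
                                 tolerance = 0.25, window = c(50, 250)) {
  stopifnot(tolerance >= 0)
  mz <- if (inherits(x, "BinnedDensity")) {
    mid <- (utils::head(x$bin_edges, -1) + utils::tail(x$bin_edges, -1)) / 2
    mid[x$counts > 0]
  } else if (is(x, "SpectrumPeakSet")) {
    peakMz(x)
  } else if (is.list(x)) {
    unlist(lapply(x, peakMz), use.names = FALSE)
  } else {
    as.numeric(x)
  }
  mz <- mz[mz >= window[1] & mz <= window[2]]
  if (!length(mz)) {
    return(data.frame(mz = numeric(0), residue = character(0),
                      ion_type = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(mz, function(m) {
    hit <- which(abs(table$mz - m) <= tolerance)
    if (length(hit)) {
      data.frame(mz = m, residue = table$residue[hit],
                 ion_type = table$ion_type[hit], stringsAsFactors = FALSE)
    } else {
      data.frame(mz = m, residue = NA_character_, ion_type = "background",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
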