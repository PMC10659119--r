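#' Gradient-length distribution of a file collection
#'
#' Histogram of gradient lengths as relative frequencies with the running
#' cumulative distribution, the repository-scale view of how acquisition
#' gradients cluster at a few conventional lengths. Bins are half-open
#' `[lo, hi)` with the last bin closed.
#'
#' @param files per-run metadata data.frame (needs `gradient_length`).
#' @param nBins number of equal-width bins over the observed range.
#' @return a list of class `HistogramSummary`: `bin_edges` (length
#'   `nBins + 1`), `probabilities` (sum 1), `cdf` (nondecreasing, ends at 1).
#' @examples
#' files <- data.frame(gradient_length = c(60, 60, 120))
#' gradientDistribution(files, nBins = 2)
#' @export
gradientDistribution <- function(files, nBins = 50) {
  if (!nrow(files)) stop("empty file list")
  stopifnot(nBins >= 1)
  x <- files$gradient_length
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) hi <- lo + 1  # degenerate: all mass in one bin
  edges <- seq(lo, hi, length.out = nBins + 1)
  counts <- .binCounts(x, edges)
  probs <- counts / length(x)
  out <- list(bin_edges = edges, probabilities = probs, cdf = cumsum(probs))
  class(out) <- "HistogramSummary"
  out
}

# half-open [lo, hi) bins, last bin closed at the upper edge
.binCounts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(edges) - 1]
  tabulate(idx, nbins = length(edges) - 1)
}

#' Unique metadata values per project
#'
#' Counts, per project, the number of distinct gradient lengths (compared
#' after rounding to 1 minute) or distinct m/z filter-bound pairs, and the
#' distribution of those counts across projects — the within-project
#' homogeneity statistic.
#'
#' @param files per-run metadata data.frame.
#' @param field `"gradient_length"` or `"filter_bounds"`.
#' @return a list of class `ProjectUniquenessSummary`: `counts_per_project`
#'   (named integer) and `distribution` (named fractions over k, sum 1).
#' @examples
#' files <- data.frame(project_id = c("p1", "p1", "p1"),
#'                     gradient_length = c(60, 60, 90))
#' uniqueValuesPerProject(files, "gradient_length")
#' @export
uniqueValuesPerProject <- function(files,
                                   field = c("gradient_length",
                                             "filter_bounds")) {
  field <- match.arg(field)
  if (!nrow(files)) stop("empty file list")
  key <- if (field == "gradient_length") {
    as.character(round(files$gradient_length))
  } else {
    paste(files$mz_lower, files$mz_upper, sep = "_")
  }
  counts <- vapply(split(key, files$project_id),
                   function(k) length(unique(k)), integer(1))
  tab <- table(counts)
  dist <- as.numeric(tab) / length(counts)
  names(dist) <- names(tab)
  out <- list(counts_per_project = counts, distribution = dist)
  class(out) <- "ProjectUniquenessSummary"
  out
}

#' m/z acquisition-window summary
#'
#' Collects the lower bounds, upper bounds and window lengths of all runs,
#' and identifies the modal (most frequent) window and its file share. Ties
#' are broken towards the smaller lower bound.
#'
#' @param files per-run metadata data.frame (needs `file_id`, `mz_lower`,
#'   `mz_upper`).
#' @return a list of class `FilterSummary`: `lower_values`, `upper_values`,
#'   `lengths`, `modal_filter` (length-2 numeric), `modal_fraction`.
#' @examples
#' files <- data.frame(file_id = c("a", "b", "c"),
#'                     mz_lower = c(350, 350, 300),
#'                     mz_upper = c(1500, 1500, 1800))
#' mzFilterSummary(files)$modal_fraction
#' @export
mzFilterSummary <- function(files) {
  if (!nrow(files)) stop("empty file list")
  bad <- which(files$mz_upper <= files$mz_lower)
  if (length(bad)) {
    stop("invalid filter bounds (upper <= lower) for file(s): ",
         paste(utils::head(files$file_id[bad], 5), collapse = ", "))
  }
  key <- paste(files$mz_lower, files$mz_upper, sep = "_")
  tab <- table(key)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1) {
    lowers <- as.numeric(sub("_.*", "", best))
    best <- best[order(lowers)][1]
  }
  modal <- as.numeric(strsplit(best, "_")[[1]])
  out <- list(
    lower_values = files$mz_lower, upper_values = files$mz_upper,
    lengths = files$mz_upper - files$mz_lower,
    modal_filter = modal,
    modal_fraction = as.numeric(max(tab)) / nrow(files))
  class(out) <- "FilterSummary"
  out
}

#' Plot a gradient histogram with its CDF overlay
#'
#' @param hist a `HistogramSummary` from [gradientDistribution()].
#' @param file optional path; when given the figure is written there.
#' @return a ggplot object, invisibly when written to file.
#' @export
plotGradientDistribution <- function(hist, file = NULL) {
  mid <- (utils::head(hist$bin_edges, -1) + utils::tail(hist$bin_edges, -1)) / 2
  df <- data.frame(mid = mid, probability = hist$probabilities,
                   cdf = hist$cdf)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mid)) +
    ggplot2::geom_col(ggplot2::aes(y = probability), fill = "steelblue",
                      width = diff(hist$bin_edges)[1] * 0.95) +
    ggplot2::geom_line(ggplot2::aes(y = cdf), color = "firebrick") +
    ggplot2::labs(x = "gradient length (min)",
                  y = "probability / cumulative fraction") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4)
    return(invisible(p))
  }
  p
}
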