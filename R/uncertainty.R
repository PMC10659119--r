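#' Monte-Carlo-dropout predictive uncertainty
#'
#' Runs model inference `nRepeats` times (25 by default) with every dropout
#' site active at its training rate, approximating a Bayesian predictive
#' distribution. Per record it reports the repeat mean, the unbiased sample
#' variance (n-1 denominator), and the min-max normalized variance across
#' the evaluated set. With dropout rate 0 all repeats coincide, every
#' variance is exactly 0 and the normalization is undefined; a warning is
#' emitted and normalized variances are set to 0. Results are a
#' deterministic function of the seed, which is independent of the training
#' seed.
#'
#' @param model a trained [RTModel-class].
#' @param records peptide records (or encoded list).
#' @param nRepeats number of stochastic forward passes, >= 2.
#' @param seed seed of the dropout stream.
#' @return data.frame of class `UncertaintyEstimate`: `target` (NA when
#'   unknown), `mean_prediction`, `variance`, `normalized_variance`,
#'   `n_repeats`.
#' @export
mcDropoutPredict <- function(model, records, nRepeats = 25L, seed = 1L) {
  if (!model@trained) stop("model is untrained; call trainRTModel() first")
  if (nRepeats < 2) stop("nRepeats must be >= 2")
  config <- model@config
  enc <- if (is.list(records) && !is.data.frame(records)) records
         else encodeSequences(records, config)
  n <- nrow(enc$x)
  if (config@dropoutRate <= 0) {
    warning("all dropout rates are 0: repeat variance is identically 0 ",
            "and normalized variance is set to 0")
  }
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nRepeats), function(r) {
      .forwardChunks(model@params, enc$x, config, withDropout = TRUE)
    }, numeric(n))
  })
  if (n == 1) reps <- matrix(reps, nrow = 1)
  meanPred <- rowMeans(reps)
  variance <- apply(reps, 1, stats::var)
  vrange <- max(variance) - min(variance)
  normVar <- if (vrange > 0) (variance - min(variance)) / vrange
             else rep(0, n)
  out <- data.frame(
    target = if (length(enc$y)) enc$y else NA_real_,
    mean_prediction = meanPred, variance = variance,
    normalized_variance = normVar, n_repeats = as.integer(nRepeats))
  class(out) <- c("UncertaintyEstimate", "data.frame")
  out
}

#' Uncertainty report: table and figure
#'
#' Produces the plot-ready table of (target, mean prediction, normalized
#' variance) triples and a scatter figure colored by normalized variance,
#' overlaid with a density curve of the observed retention times and the
#' identity line y = x as the perfect-alignment reference.
#'
#' @param estimates an `UncertaintyEstimate` from [mcDropoutPredict()].
#' @param file optional path; when given the figure is written there.
#' @return list with `table` (data.frame) and `plot` (ggplot).
#' @export
uncertaintyReport <- function(estimates, file = NULL) {
  if (!nrow(estimates)) stop("empty estimate set")
  tab <- estimates[, c("target", "mean_prediction", "normalized_variance")]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = target, y = mean_prediction)) +
    ggplot2::geom_point(ggplot2::aes(color = normalized_variance),
                        size = 0.8, alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_color_viridis_c(name = "normalized\nvariance") +
    ggplot2::labs(x = "observed normalized RT",
                  y = "mean MC-dropout prediction") +
    ggplot2::theme_minimal()
  if (nrow(tab) > 1 && !anyNA(tab$target) &&
      stats::sd(tab$target) > 0) {
    p <- p + ggplot2::geom_density(
      data = tab, ggplot2::aes(x = target, y = ggplot2::after_stat(scaled)),
      inherit.aes = FALSE, color = "grey30")
  }
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5)
  list(table = tab, plot = p)
}

#' Mean MC-dropout variance per target decile
#'
#' Helper for the positional-uncertainty pattern: averages the repeat
#' variance within deciles of the observed normalized retention time, so
#' the gradient extremes (first/last deciles) can be compared with the
#' middle of the gradient.
#'
#' @param estimates an `UncertaintyEstimate` with known targets.
#' @return data.frame with `decile` (1..10) and `mean_variance`.
#' @export
varianceByDecile <- function(estimates) {
  if (anyNA(estimates$target)) stop("targets are required")
  dec <- pmin(10L, pmax(1L, floor(estimates$target * 10) + 1L))
  agg <- tapply(estimates$variance, dec, mean)
  data.frame(decile = as.integer(names(agg)),
             mean_variance = as.numeric(agg))
}
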