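.needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Histogram of heteroplasmic fractions with the detection floor
#'
#' @param hf Numeric vector of heteroplasmic fractions (typically the
#'   pre-floor list, HF > 0).
#' @param floor Detection floor drawn as a vertical line (default 0.02).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plotHFHistogram <- function(hf, floor = 0.02, bins = 100) {
  .needGgplot()
  ggplot2::ggplot(data.frame(hf = hf), ggplot2::aes(x = hf)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = floor, colour = "red") +
    ggplot2::labs(x = "heteroplasmic fraction", y = "variants") +
    ggplot2::theme_classic()
}

#' Strip chart of length-normalized somatic burden by locus class
#'
#' @param burdens Output of [burdenByLocus()].
#' @return A ggplot object.
#' @export
plotBurdenByLocus <- function(burdens) {
  .needGgplot()
  ggplot2::ggplot(burdens,
                  ggplot2::aes(x = .data$locusClass, y = .data$normCount)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::labs(x = NULL, y = "somatic variants / locus bp / cell") +
    ggplot2::theme_classic()
}

#' Histogram of pathogenicity scores with threshold
#'
#' @param scores Numeric score vector (NAs dropped).
#' @param threshold Pathogenicity threshold drawn as a dashed line.
#' @param label Axis label for the predictor.
#' @return A ggplot object.
#' @export
plotScoreDistribution <- function(scores, threshold, label = "score") {
  .needGgplot()
  ggplot2::ggplot(data.frame(s = scores[!is.na(scores)]),
                  ggplot2::aes(x = .data$s)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = label, y = "variants") +
    ggplot2::theme_classic()
}
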