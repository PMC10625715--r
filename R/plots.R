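#' Plot a calibration fit
#'
#' Scatter of persistent-A percentage against designed m6A percentage with
#' the fitted line and its r-squared.
#'
#' @param object An `etam_calibration` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.etam_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$designed_pct, y = .data$persistent_a_pct)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "designed m6A (%)", y = "persistent A (%)",
      title = sprintf("persistent A vs designed m6A (r² = %.2f)", object$r_squared)
    )
}

#' Plot a methylation call set
#'
#' Methylation-level histogram of evaluated sites, split by pass status
#' (and motif class when available).
#'
#' @param object An `etam_calls` tibble from [call_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.etam_calls <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$true_m), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$true_m, fill = .data$passed)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0, position = "stack") +
    ggplot2::labs(x = "estimated methylation level", y = "sites", fill = "passed")
  if ("motif_class" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$motif_class))
  }
  p
}

#' Observed median neighbour gap against its permutation null
#'
#' @param null_medians Tibble from [permutation_gap_null()].
#' @param observed_median Observed median gap from [neighbor_gaps()].
#' @return A ggplot object.
#' @export
plot_gap_null <- function(null_medians, observed_median) {
  ggplot2::ggplot(null_medians, ggplot2::aes(x = .data$median_gap)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70") +
    ggplot2::geom_vline(xintercept = observed_median, colour = "red") +
    ggplot2::labs(x = "median neighbour gap (nt)", y = "permutation draws",
                  title = "observed (red) vs permutation null")
}

#' Half-life distributions by methylation-load bin
#'
#' @param bins Output of [bin_by_load()].
#' @param half_lives Data frame with `transcript_id`, `half_life_hours`.
#' @return A ggplot object.
#' @export
plot_half_life_bins <- function(bins, half_lives) {
  joined <- dplyr::inner_join(as_tibble(bins), as_tibble(half_lives),
                              by = "transcript_id")
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$bin, y = .data$half_life_hours)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = "methylation load bin", y = "half-life (h)")
}
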