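#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal scale_y_continuous coord_flip
#' @export
ggplot2::autoplot

#' Plot a likelihood-threshold sweep
#'
#' AMI (thresholded and random-removal baseline) and percentage of cells
#' predicted against the rejection threshold.
#'
#' @param object A `cc_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_sweep
#' @export
autoplot.cc_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("ami", "baseline_ami"),
    names_to = "series", values_to = "value")
  long$series <- ifelse(long$series == "ami", "thresholded",
                        "random removal")
  ggplot(long, aes(x = .data$threshold)) +
    geom_line(aes(y = .data$value, colour = .data$series)) +
    geom_point(aes(y = .data$value, colour = .data$series)) +
    geom_line(aes(y = .data$pct_predicted / 100), linetype = "dashed") +
    scale_y_continuous(
      "AMI",
      sec.axis = ggplot2::sec_axis(~ . * 100, name = "% cells predicted")) +
    labs(x = "likelihood threshold", colour = NULL,
         title = "Threshold sweep (dashed: % predicted)") +
    theme_minimal()
}

#' Plot an AMI similarity calibration curve
#'
#' Mean AMI against similarity to the reference, one panel per reference
#' state count and one line per predicted state count.
#'
#' @param object A `cc_calibration` from [simulate_ami_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_calibration
#' @export
autoplot.cc_calibration <- function(object, ...) {
  ggplot(object, aes(x = .data$similarity, y = .data$mean_ami,
                     colour = factor(.data$k_pred),
                     group = .data$k_pred)) +
    geom_line() +
    facet_wrap(~ k_ref, labeller = ggplot2::label_both) +
    labs(x = "similarity to reference", y = "mean AMI",
         colour = "predicted\nstates") +
    theme_minimal()
}

#' Plot missing-gene sensitivity
#'
#' Error rate against the fraction of classifier genes zeroed, one line per
#' likelihood threshold.
#'
#' @param object A `cc_sensitivity` from [missing_gene_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_sensitivity
#' @export
autoplot.cc_sensitivity <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$fraction_missing, .data$threshold) |>
    dplyr::summarise(error_rate = median(.data$error_rate, na.rm = TRUE),
                     .groups = "drop")
  ggplot(summ, aes(x = .data$fraction_missing, y = .data$error_rate,
                   colour = factor(.data$threshold))) +
    geom_line() +
    geom_point() +
    labs(x = "fraction of classifier genes missing",
         y = "median error rate", colour = "threshold") +
    theme_minimal()
}

#' Plot top permutation-importance features per state
#'
#' The `n` most important features (most negative mean delta likelihood) per
#' state, as horizontal bars.
#'
#' @param object A `cc_importance` from [permutation_importance()].
#' @param n Features per state (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cc_importance
#' @export
autoplot.cc_importance <- function(object, n = 15L, ...) {
  top <- object |>
    dplyr::group_by(.data$state) |>
    dplyr::slice_min(.data$mean_delta_likelihood, n = n,
                     with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot(top, aes(x = stats::reorder(.data$gene,
                                     -.data$mean_delta_likelihood),
                  y = .data$mean_delta_likelihood)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~ state, scales = "free_y") +
    labs(x = NULL, y = "mean Δ likelihood under permutation") +
    theme_minimal()
}
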