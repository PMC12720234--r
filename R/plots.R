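#' Plot per-mode potential energy scans
#'
#' One panel per mode, energy against the scaling factor, one colour per
#' electronic state, with the quadratic fits overdrawn.
#'
#' @param object A `pes_scans` tibble.
#' @param modes Optional subset of mode indices to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pes_scans
#' @export
autoplot.pes_scans <- function(object, modes = NULL, ...) {
  df <- if (is.null(modes)) object else object[object$mode %in% modes, ]
  fits <- fit_scans(df)
  curves <- fits |>
    dplyr::mutate(curve = purrr::map(.data$fit, function(f) {
      xx <- seq(min(f$factors), max(f$factors), length.out = 101)
      tibble::tibble(i = xx, energy = predict(f, xx))
    })) |>
    dplyr::select("mode", "state", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$energy, colour = .data$state)) +
    ggplot2::geom_line(data = curves, linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~mode, scales = "free_y", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "scaling factor i", y = "energy (eV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-mode anharmonicity and FC-activity metrics
#'
#' Bar panels of delta a, delta b, delta RMSD/E_average and lambda per
#' mode, with the mean + k.SD thresholds drawn where applicable.
#'
#' @param object A [mode_metrics()] tibble.
#' @param thresholds Optional [compute_thresholds()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mode_metrics
#' @export
autoplot.mode_metrics <- function(object, thresholds = NULL, ...) {
  long <- object |>
    dplyr::select("mode", "delta_a", "delta_b", "delta_rmsd_ratio", "lambda") |>
    tidyr::pivot_longer(-"mode", names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("delta_a", "delta_b", "delta_rmsd_ratio", "lambda")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mode, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "mode", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    hl <- tibble::tibble(
      metric = factor(c("delta_rmsd_ratio", "lambda"),
                      levels = levels(long$metric)),
      value = c(thresholds$s1_excess_threshold, thresholds$fc_threshold)
    )
    p <- p + ggplot2::geom_hline(data = hl, ggplot2::aes(yintercept = .data$value),
                                 colour = "firebrick", linetype = "dotted")
  }
  p
}

#' Case-count summary plot
#'
#' @param cases An [assign_cases()] tibble.
#' @return A ggplot bar chart of modes per case.
#' @export
plot_case_summary <- function(cases) {
  df <- cases |>
    dplyr::count(case = factor(.data$case, levels = 1:8))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$case, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "case", y = "modes") +
    ggplot2::theme_minimal()
}
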