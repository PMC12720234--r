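#' Mean + k.SD anharmonicity and FC-activity thresholds
#'
#' A mode is called anharmonic, excess-anharmonic or FC active when its
#' metric lies strictly more than `k_sd` standard deviations above the
#' population mean over all modes. Three thresholds are derived:
#' \describe{
#'   \item{s0_anh_threshold}{on the ground-state RMSD/E_average ratio.}
#'   \item{s1_excess_threshold}{on the excited-minus-ground
#'     delta RMSD/E_average.}
#'   \item{fc_threshold}{on the relaxation energy lambda (eV).}
#' }
#'
#' @param metrics A [mode_metrics()] tibble (at least 2 modes).
#' @param k_sd Standard-deviation multiplier.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return A one-row tibble of class `threshold_set` with the three
#'   thresholds plus `k_sd` and `sd_convention`.
#' @export
compute_thresholds <- function(metrics, k_sd = 1, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (nrow(metrics) < 2L) stop("thresholds need at least 2 modes", call. = FALSE)
  if (k_sd <= 0) stop("k_sd must be positive", call. = FALSE)
  sdev <- function(x) {
    s <- stats::sd(x)
    if (sd_convention == "population") s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  thr <- function(x) mean(x) + k_sd * sdev(x)
  out <- tibble::tibble(
    s0_anh_threshold = thr(metrics$ratio_s0),
    s1_excess_threshold = thr(metrics$delta_rmsd_ratio),
    fc_threshold = thr(metrics$lambda),
    k_sd = k_sd, sd_convention = sd_convention
  )
  class(out) <- c("threshold_set", class(out))
  out
}

# The eight cases as a (S0 anharmonic, S1 excess, FC active) -> case map:
#   TRUE  TRUE  TRUE  -> 1   both anharmonic, S1 more, FC active
#   TRUE  TRUE  FALSE -> 2   both anharmonic, S1 more, FC inactive
#   TRUE  FALSE TRUE  -> 3   similar anharmonicity, FC active
#   TRUE  FALSE FALSE -> 4   similar anharmonicity, FC inactive
#   FALSE TRUE  TRUE  -> 5   S0 harmonic, S1 anharmonic, FC active
#   FALSE TRUE  FALSE -> 6   S0 harmonic, S1 anharmonic, FC inactive
#   FALSE FALSE TRUE  -> 7   both harmonic, FC active
#   FALSE FALSE FALSE -> 8   both harmonic, FC inactive
case_from_flags <- function(s0_anh, s1_excess, fc_active) {
  dplyr::case_when(
    s0_anh & s1_excess & fc_active ~ 1L,
    s0_anh & s1_excess & !fc_active ~ 2L,
    s0_anh & !s1_excess & fc_active ~ 3L,
    s0_anh & !s1_excess & !fc_active ~ 4L,
    !s0_anh & s1_excess & fc_active ~ 5L,
    !s0_anh & s1_excess & !fc_active ~ 6L,
    !s0_anh & !s1_excess & fc_active ~ 7L,
    TRUE ~ 8L
  )
}

#' Assign each mode to one of the eight anharmonicity/FC cases
#'
#' Applies the three thresholds (strict inequality: a metric exactly at
#' its threshold is not flagged) and maps the flag triple to case
#' numbers 1-8. The cases partition the modes: every mode lands in
#' exactly one.
#'
#' @param metrics A [mode_metrics()] tibble.
#' @param thresholds A [compute_thresholds()] result (computed from the
#'   same metric population).
#' @param eps Absolute numerical guard: a metric must exceed its
#'   threshold by more than `eps` to be flagged, so machine-epsilon
#'   residuals in an exactly-harmonic population (where all metrics and
#'   the threshold are numerical zero) cannot flag modes. Far below any
#'   physically meaningful metric value.
#' @return The metrics tibble reduced to `mode`, `s0_anharmonic`,
#'   `s1_excess`, `fc_active`, `case`.
#' @export
assign_cases <- function(metrics, thresholds, eps = 1e-9) {
  tibble::tibble(
    mode = metrics$mode,
    s0_anharmonic = metrics$ratio_s0 > thresholds$s0_anh_threshold + eps,
    s1_excess = metrics$delta_rmsd_ratio > thresholds$s1_excess_threshold + eps,
    fc_active = metrics$lambda > thresholds$fc_threshold + eps
  ) |>
    dplyr::mutate(case = case_from_flags(.data$s0_anharmonic, .data$s1_excess, .data$fc_active))
}
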