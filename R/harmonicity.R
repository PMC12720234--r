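#' Normalized fit RMSD (RMSD over average scan energy)
#'
#' Reporting the quadratic-fit RMSD relative to the mean energy of the
#' scan puts localized modes (which change the energy a lot per unit
#' scaling factor) and delocalized modes on an equal footing. For an
#' excited state the mean is first reduced by the vertical excitation
#' energy, so the denominator measures the energy change produced by the
#' distortion rather than the electronic gap.
#'
#' @param fit A [fit_quadratic()] result for the state.
#' @param energies The scan energies (eV) the fit was made on.
#' @param state_kind `"ground"` or `"excited"`.
#' @param excitation_offset Vertical excitation energy (eV) subtracted
#'   from the mean for excited states. Ignored for the ground state.
#' @return The unitless ratio RMSD / E_average.
#' @export
rmsd_ratio <- function(fit, energies, state_kind = c("ground", "excited"),
                       excitation_offset = 0) {
  state_kind <- match.arg(state_kind)
  denom <- mean(energies)
  if (state_kind == "excited") denom <- denom - excitation_offset
  if (abs(denom) < 1e-12) {
    stop("undefined RMSD/E_average: zero mean scan energy",
         if (state_kind == "excited") " after subtracting the excitation offset",
         call. = FALSE)
  }
  fit$rmsd / denom
}

#' Per-mode relaxation energy of an excited state
#'
#' The relaxation energy lambda along one mode is the energy of the
#' excited state at the ground-state equilibrium (the Franck-Condon
#' point, i = 0) minus the lowest point of the excited state along that
#' mode. Franck-Condon-active modes, whose excited-state minimum is
#' displaced from i = 0, have large lambda.
#'
#' The minimum is taken from the fitted parabola over the scanned
#' interval; when the fit is concave (a <= 0, no vertex minimum) the
#' minimum scanned data point is used instead and the fallback is
#' recorded. Lambda is clamped at zero.
#'
#' @param fit The excited state's [fit_quadratic()] result.
#' @param factors The scan grid.
#' @param energies The excited state's scan energies (eV).
#' @return A list with `lambda` (eV), `fallback` (logical) and
#'   `minimum_at` (scaling factor of the minimum used).
#' @examples
#' g <- displacement_grid()
#' y <- 10 * (g - 0.05)^2 + 2.9
#' relaxation_energy(fit_quadratic(g, y), g, y)$lambda  # 0.025
#' @export
relaxation_energy <- function(fit, factors, energies) {
  factors <- as.numeric(factors)
  at_zero <- which(factors == 0)
  e_fc <- if (length(at_zero) == 1L) energies[at_zero] else predict(fit, 0)
  if (fit$a > 0) {
    pm <- parabola_min_on(fit, min(factors), max(factors))
    lam <- e_fc - pm$value
    fallback <- FALSE
    at <- pm$at
  } else {
    k <- which.min(energies)
    lam <- e_fc - energies[k]
    fallback <- TRUE
    at <- factors[k]
  }
  list(lambda = max(lam, 0), fallback = fallback, minimum_at = at)
}

#' Quadratic fits for every (mode, state) scan
#'
#' @param scans A `pes_scans` tibble from [assemble_scans()] (or
#'   [diabatize()]).
#' @return A tibble with one row per mode and state: fit coefficients
#'   `a`, `b`, `c`, plus `r2`, `rmsd`, `n`, and the `quad_fit` object in
#'   list-column `fit`.
#' @export
fit_scans <- function(scans) {
  scans |>
    dplyr::group_by(.data$mode, .data$state) |>
    dplyr::summarise(fit = list(fit_quadratic(.data$i, .data$energy)), .groups = "drop") |>
    dplyr::mutate(purrr::map_dfr(.data$fit, glance)) |>
    dplyr::select("mode", "state", "a", "b", "c", "r2", "rmsd", "n", "fit")
}

#' Per-mode anharmonicity and Franck-Condon metrics
#'
#' Computes, for every mode, the quadratic-fit statistics of the ground
#' and excited state, the normalized RMSD ratios, the excited-minus-
#' ground deltas (`delta_a`, `delta_b`, `delta_rmsd`,
#' `delta_rmsd_ratio`) and the relaxation energy `lambda`. Supply
#' diabatized scans for crossing modes so the fits follow the smooth
#' diabatic curves.
#'
#' @param scans A `pes_scans` tibble, diabatized where applicable.
#' @param ground,excited State labels for the ground and excited scan.
#' @param excitation_offset `"auto"` (default) computes the vertical
#'   excitation energy per mode as the excited-minus-ground energy gap
#'   at i = 0; a single number fixes it globally (e.g. a molecule's
#'   known gas-phase value).
#' @param mode_set Optional [mode_set()] used only to join harmonic
#'   frequencies into the output.
#' @return A tibble of class `mode_metrics`, one row per mode, with
#'   columns `mode`, `freq_cm1`, `a_s0` .. `rmsd_s1`, `ratio_s0`,
#'   `ratio_s1`, `delta_a`, `delta_b`, `delta_rmsd`, `delta_rmsd_ratio`,
#'   `lambda`, `excitation_offset`, `diabatized`, `lambda_fallback`.
#' @export
mode_metrics <- function(scans, ground = "S0", excited = "S1",
                         excitation_offset = "auto", mode_set = NULL) {
  diab <- attr(scans, "diabatization")
  diab_modes <- if (!is.null(diab)) diab$mode[diab$swapped] else integer()
  rows <- list()
  for (m in sort(unique(scans$mode))) {
    sub <- scans[scans$mode == m, , drop = FALSE]
    if (!all(c(ground, excited) %in% sub$state)) {
      stop("mode ", m, ": states ", ground, "/", excited, " not both present", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(sub, id_cols = "i", names_from = "state",
                               values_from = "energy") |> dplyr::arrange(.data$i)
    y0 <- wide[[ground]]; y1 <- wide[[excited]]
    f0 <- fit_quadratic(wide$i, y0)
    f1 <- fit_quadratic(wide$i, y1)
    off <- if (identical(excitation_offset, "auto")) {
      y1[wide$i == 0] - y0[wide$i == 0]
    } else as.numeric(excitation_offset)
    r0 <- rmsd_ratio(f0, y0, "ground")
    r1 <- rmsd_ratio(f1, y1, "excited", excitation_offset = off)
    rel <- relaxation_energy(f1, wide$i, y1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mode = m,
      a_s0 = f0$a, b_s0 = f0$b, c_s0 = f0$c, r2_s0 = f0$r2, rmsd_s0 = f0$rmsd,
      a_s1 = f1$a, b_s1 = f1$b, c_s1 = f1$c, r2_s1 = f1$r2, rmsd_s1 = f1$rmsd,
      ratio_s0 = r0, ratio_s1 = r1,
      delta_a = f1$a - f0$a, delta_b = f1$b - f0$b,
      delta_rmsd = f1$rmsd - f0$rmsd, delta_rmsd_ratio = r1 - r0,
      lambda = rel$lambda, excitation_offset = off,
      diabatized = m %in% diab_modes, lambda_fallback = rel$fallback
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(mode_set)) {
    out <- dplyr::left_join(mode_set$modes[, c("mode", "freq_cm1")], out, by = "mode")
  } else {
    out <- dplyr::mutate(out, freq_cm1 = NA_real_, .after = "mode")
  }
  class(out) <- c("mode_metrics", class(out))
  out
}
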