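#' Assemble per-mode electronic-state scans from an energy table
#'
#' Takes the long table of single-point energies produced by an external
#' electronic-structure engine (or by [generate_two_state()]) and turns
#' it into validated scan data: energies converted to eV and shifted per
#' mode so the ground state at i = 0 is 0.
#'
#' @param energy_table Data frame with columns `mode` (integer), `i`
#'   (scaling factor), `state` (labels `"S0"`, `"S1"`, ...) and `energy`.
#' @param unit Unit of the `energy` column: `"hartree"` or `"ev"`.
#' @param ground Label of the ground state used as the energy reference.
#' @return A tibble of class `pes_scans` with columns `mode`, `i`,
#'   `state`, `energy` (eV relative to the ground-state equilibrium of
#'   each mode's scan), ordered by mode, state, i.
#' @examples
#' tab <- generate_two_state(two_state_spec())$energies
#' scans <- assemble_scans(tab, unit = "ev")
#' @export
assemble_scans <- function(energy_table, unit = c("hartree", "ev"), ground = "S0") {
  unit <- match.arg(unit)
  stopifnot(all(c("mode", "i", "state", "energy") %in% names(energy_table)))
  tab <- tibble::as_tibble(energy_table) |>
    dplyr::mutate(mode = as.integer(.data$mode), i = as.numeric(.data$i),
                  state = as.character(.data$state), energy = as.numeric(.data$energy))

  dup <- tab |> dplyr::count(.data$mode, .data$state, .data$i) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate energy record(s), e.g. mode ", dup$mode[1], " state ", dup$state[1],
         " i = ", dup$i[1], call. = FALSE)
  }
  # every (mode, state) must cover the same grid as that mode's ground state
  miss <- tab |>
    dplyr::distinct(.data$mode, .data$i) |>
    tidyr::crossing(tab |> dplyr::distinct(.data$mode, .data$state) |>
                      dplyr::rename(mode2 = "mode")) |>
    dplyr::filter(.data$mode == .data$mode2) |>
    dplyr::select("mode", "state", "i") |>
    dplyr::anti_join(tab, by = c("mode", "state", "i"))
  if (nrow(miss) > 0L) {
    stop("incomplete scan: missing energy for (mode ", miss$mode[1], ", state ",
         miss$state[1], ", i = ", miss$i[1], ")",
         if (nrow(miss) > 1L) paste0(" and ", nrow(miss) - 1L, " more"), call. = FALSE)
  }
  if (!all(tab$mode %in% tab$mode[tab$i == 0])) {
    stop("every scan must include the equilibrium point i = 0", call. = FALSE)
  }
  if (!ground %in% tab$state) stop("ground-state label '", ground, "' absent from table", call. = FALSE)

  if (unit == "hartree") tab$energy <- tab$energy * energy_units[["hartree_to_ev"]]
  ref <- tab |>
    dplyr::filter(.data$state == ground, .data$i == 0) |>
    dplyr::select("mode", e0 = "energy")
  out <- tab |>
    dplyr::left_join(ref, by = "mode") |>
    dplyr::mutate(energy = .data$energy - .data$e0) |>
    dplyr::select("mode", "i", "state", "energy") |>
    dplyr::arrange(.data$mode, .data$state, .data$i)
  if (!all(is.finite(out$energy))) stop("non-finite energies after assembly", call. = FALSE)
  class(out) <- c("pes_scans", class(out))
  attr(out, "ground") <- ground
  out
}

# Interior local minimum of the adiabatic gap along one mode.
# Returns NULL when no interior minimum falls below the threshold.
crossing_one <- function(factors, ea, eb, gap_threshold) {
  n <- length(factors)
  if (n < 5L) stop("crossing detection needs at least 5 grid points", call. = FALSE)
  gap <- abs(eb - ea)
  interior <- which(vapply(2:(n - 1L), function(j) {
    gap[j] <= gap[j - 1L] && gap[j] <= gap[j + 1L]
  }, logical(1))) + 1L
  if (length(interior) == 0L) return(NULL)
  j <- interior[which.min(gap[interior])]
  if (gap[j] >= gap_threshold) return(NULL)
  lower_min <- min(pmin(ea, eb))
  e_ci <- (ea[j] + eb[j]) / 2
  list(crossing_index = j, i_cross = factors[j], gap_min = gap[j],
       delta_e_ci = e_ci - lower_min)
}

#' Detect excited-state crossings along each mode's scan
#'
#' Scans the absolute energy gap between two adiabatic states along each
#' mode and reports the interior local minimum of the gap when it falls
#' below `gap_threshold`. Endpoint minima are never reported: a crossing
#' must be bracketed by the scan. The crossing-point energy above the
#' lower state's scan minimum (the quantity plotted against the S1
#' minimum for conical intersections met along a mode) is returned as
#' `delta_e_ci`, by default read at the minimum-gap grid point as the
#' mean of the two state energies there.
#'
#' @param scans A `pes_scans` tibble from [assemble_scans()].
#' @param state_a,state_b The two state labels to compare (symmetric).
#' @param gap_threshold Maximum gap (eV) for a minimum to count as a
#'   crossing. The default 0.15 eV comfortably admits gaps of a few
#'   hundredths of an eV while rejecting well-separated states.
#' @param interpolate If `TRUE`, refine `i_cross` and `delta_e_ci` by
#'   linear interpolation of the signed gap between the bracketing grid
#'   points; the default reads values at the grid point.
#' @return A tibble with one row per mode showing a crossing: `mode`,
#'   `state_a`, `state_b`, `crossing_index` (grid position), `i_cross`,
#'   `gap_min` (eV), `delta_e_ci` (eV above the lower state's minimum),
#'   `swapped` (filled in by [diabatize()]). Zero rows when no mode
#'   crosses.
#' @export
detect_crossings <- function(scans, state_a = "S1", state_b = "S2",
                             gap_threshold = 0.15, interpolate = FALSE) {
  rows <- list()
  for (m in sort(unique(scans$mode))) {
    sub <- scans[scans$mode == m, , drop = FALSE]
    if (!all(c(state_a, state_b) %in% sub$state)) next
    wide <- tidyr::pivot_wider(sub, id_cols = "i", names_from = "state",
                               values_from = "energy") |> dplyr::arrange(.data$i)
    res <- crossing_one(wide$i, wide[[state_a]], wide[[state_b]], gap_threshold)
    if (is.null(res)) next
    if (interpolate) {
      res <- interpolate_crossing(wide$i, wide[[state_a]], wide[[state_b]], res)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mode = m, state_a = state_a, state_b = state_b,
      crossing_index = res$crossing_index, i_cross = res$i_cross,
      gap_min = res$gap_min, delta_e_ci = res$delta_e_ci, swapped = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(mode = integer(), state_a = character(), state_b = character(),
                          crossing_index = integer(), i_cross = numeric(),
                          gap_min = numeric(), delta_e_ci = numeric(), swapped = logical()))
  }
  dplyr::bind_rows(rows)
}

# Linear refinement of the crossing position: find the sign change of the
# signed gap adjacent to the minimum-gap grid point and interpolate.
interpolate_crossing <- function(factors, ea, eb, res) {
  d <- ea - eb
  j <- res$crossing_index
  cand <- c(j - 1L, j)
  cand <- cand[cand >= 1L & cand < length(factors)]
  for (k in cand) {
    if (sign(d[k]) != sign(d[k + 1L]) && d[k] != d[k + 1L]) {
      t <- d[k] / (d[k] - d[k + 1L])
      i_star <- factors[k] + t * (factors[k + 1L] - factors[k])
      e_star <- ea[k] + t * (ea[k + 1L] - ea[k])
      lower_min <- min(pmin(ea, eb))
      res$i_cross <- i_star
      res$delta_e_ci <- e_star - lower_min
      res$gap_min <- 0
      break
    }
  }
  res
}

#' Relabel states diabatically past a detected crossing
#'
#' Past a crossing, following the adiabatic (energy-ordered) states kinks
#' both curves; a smooth potential follows the diabatic state that keeps
#' a consistent electronic character through the crossing. Without
#' wavefunction data, the operational criterion is that a branch swap on
#' the far side of the crossing (the side away from i = 0) is applied if
#' and only if it reduces the summed quadratic-fit RMSD of the two
#' curves. An optional per-point state-character scalar (e.g. oscillator
#' strength) can override this: when `character_values` is supplied, the
#' swap that maximizes character continuity across the crossing is
#' chosen instead.
#'
#' @param scans A `pes_scans` tibble.
#' @param crossings Crossing table from [detect_crossings()]. Each row is
#'   handled independently; a crossing on the + side swaps only points
#'   beyond it on that side.
#' @param character_values Optional data frame `mode`, `i`, `state`,
#'   `value` of per-point electronic-character scalars.
#' @return The scans tibble with energies exchanged between the two
#'   states beyond each accepted swap point. The sorted multiset of
#'   energies at every grid point is unchanged. The updated crossing
#'   table (with `swapped` and `swap_index` filled in) is attached as
#'   attribute `"diabatization"`.
#' @export
diabatize <- function(scans, crossings, character_values = NULL) {
  if (nrow(crossings) == 0L) {
    attr(scans, "diabatization") <- crossings
    return(scans)
  }
  crossings$swap_index <- NA_integer_
  for (r in seq_len(nrow(crossings))) {
    m <- crossings$mode[r]
    sa <- crossings$state_a[r]; sb <- crossings$state_b[r]
    sub <- scans[scans$mode == m, , drop = FALSE]
    wide <- tidyr::pivot_wider(sub, id_cols = "i", names_from = "state",
                               values_from = "energy") |> dplyr::arrange(.data$i)
    factors <- wide$i
    ea <- wide[[sa]]; eb <- wide[[sb]]
    j <- crossings$crossing_index[r]
    side <- sign(crossings$i_cross[r])
    if (side == 0) side <- 1  # crossing at i = 0: treat + side as the far side

    # candidate swap starts: the crossing point and its neighbor away from zero
    starts <- if (side > 0) c(j, min(j + 1L, length(factors))) else c(j, max(j - 1L, 1L))
    starts <- unique(starts)

    total_rmsd <- function(ya, yb) {
      fit_quadratic(factors, ya)$rmsd + fit_quadratic(factors, yb)$rmsd
    }
    apply_swap <- function(start) {
      idx <- if (side > 0) seq(start, length(factors)) else seq(1L, start)
      ya <- ea; yb <- eb
      ya[idx] <- eb[idx]; yb[idx] <- ea[idx]
      list(ya = ya, yb = yb, idx = idx)
    }

    if (!is.null(character_values)) {
      best <- choose_swap_by_character(character_values, m, sa, sb, factors, side, starts)
    } else {
      base <- total_rmsd(ea, eb)
      best <- NULL; best_rmsd <- base
      for (s in starts) {
        cand <- apply_swap(s)
        r2 <- total_rmsd(cand$ya, cand$yb)
        if (r2 < best_rmsd - 1e-15) { best <- s; best_rmsd <- r2 }
      }
    }

    if (!is.null(best)) {
      sw <- apply_swap(best)
      for (k in sw$idx) {
        ii <- factors[k]
        scans$energy[scans$mode == m & scans$i == ii & scans$state == sa] <- sw$ya[k]
        scans$energy[scans$mode == m & scans$i == ii & scans$state == sb] <- sw$yb[k]
      }
      crossings$swapped[r] <- TRUE
      crossings$swap_index[r] <- best
    }
  }
  attr(scans, "diabatization") <- crossings
  scans
}

# Character-continuity criterion: pick the swap start whose relabeled
# character traces have the smallest summed absolute step across the grid.
choose_swap_by_character <- function(character_values, m, sa, sb, factors, side, starts) {
  cv <- tibble::as_tibble(character_values)
  sub <- cv[cv$mode == m, , drop = FALSE]
  wide <- tidyr::pivot_wider(sub, id_cols = "i", names_from = "state",
                             values_from = "value") |> dplyr::arrange(.data$i)
  ca <- wide[[sa]]; cb <- wide[[sb]]
  roughness <- function(x) sum(abs(diff(x)))
  base <- roughness(ca) + roughness(cb)
  best <- NULL; best_val <- base
  for (s in starts) {
    idx <- if (side > 0) seq(s, length(factors)) else seq(1L, s)
    ya <- ca; yb <- cb
    ya[idx] <- cb[idx]; yb[idx] <- ca[idx]
    val <- roughness(ya) + roughness(yb)
    if (val < best_val - 1e-15) { best <- s; best_val <- val }
  }
  best
}
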