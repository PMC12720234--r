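## Simplified potential-energy-distribution (PED) style categorization of
## normal modes: project each Cartesian mode vector onto first-order
## displacement rows of redundant internal coordinates (stretches, bends,
## torsions, out-of-plane) and bucket modes by the dominant motion type.
## This is deliberately a fixed redundant-coordinate projection, not a
## reimplementation of a PED program's coordinate-set optimization: the
## six buckets, not exact percentage values, are the product.

#' Perceive the bonded topology of a geometry
#'
#' Distance-based perception: two atoms are bonded when their distance is
#' below 1.2 times the sum of their covalent radii. From the bond list,
#' all bonded angle triples, all proper torsion quadruples, and one
#' out-of-plane coordinate at every atom with exactly three bonded
#' neighbors are enumerated.
#'
#' @param geom A geometry tibble.
#' @param tol Bond tolerance factor applied to the covalent-radius sum.
#' @return A tibble of internal coordinates: `kind` (`STRE`, `BEND`,
#'   `TORS`, `OUT`), atom indices `a1`-`a4` (NA where unused; for `OUT`,
#'   `a1` is the central atom), and `involves_hydrogen` (stretches only).
#' @examples
#' w <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' perceive_topology(w)
#' @export
perceive_topology <- function(geom, tol = 1.2) {
  n <- n_atoms(geom)
  xyz <- coord_matrix(geom)
  radii <- covalent_radius(geom$element)
  bonds <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < tol * (radii[i] + radii[j])) bonds[[length(bonds) + 1L]] <- c(i, j)
    }
  }
  if (length(bonds) == 0L) {
    warning("no bonds perceived: disconnected topology", call. = FALSE)
    return(tibble::tibble(kind = character(), a1 = integer(), a2 = integer(),
                          a3 = integer(), a4 = integer(), involves_hydrogen = logical()))
  }
  nb <- vector("list", n)
  for (b in bonds) {
    nb[[b[1]]] <- c(nb[[b[1]]], b[2])
    nb[[b[2]]] <- c(nb[[b[2]]], b[1])
  }
  rows <- list()
  add <- function(kind, a, involves_h = NA) {
    a <- c(a, rep(NA_integer_, 4L - length(a)))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4],
      involves_hydrogen = involves_h)
  }
  is_h <- geom$element == "H"
  for (b in bonds) add("STRE", b, involves_h = is_h[b[1]] || is_h[b[2]])
  for (j in seq_len(n)) {
    nbj <- sort(nb[[j]])
    if (length(nbj) >= 2L) {
      for (p in utils::combn(nbj, 2L, simplify = FALSE)) add("BEND", c(p[1], j, p[2]))
    }
  }
  seen <- character()
  for (b in bonds) {
    j <- b[1]; k <- b[2]
    for (i in setdiff(nb[[j]], k)) {
      for (l in setdiff(nb[[k]], c(j, i))) {
        key <- paste(min(i, l), if (i < l) paste(j, k) else paste(k, j), max(i, l))
        if (key %in% seen) next
        seen <- c(seen, key)
        add("TORS", c(i, j, k, l))
      }
    }
  }
  for (cc in seq_len(n)) {
    if (length(nb[[cc]]) == 3L) add("OUT", c(cc, sort(nb[[cc]])))
  }
  dplyr::bind_rows(rows)
}

# Value of one internal coordinate given an N x 3 coordinate matrix.
internal_value <- function(kind, a, xyz) {
  switch(kind,
    STRE = sqrt(sum((xyz[a[1], ] - xyz[a[2], ])^2)),
    BEND = {
      u <- xyz[a[1], ] - xyz[a[2], ]
      v <- xyz[a[3], ] - xyz[a[2], ]
      acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
    },
    TORS = {
      b1 <- xyz[a[2], ] - xyz[a[1], ]
      b2 <- xyz[a[3], ] - xyz[a[2], ]
      b3 <- xyz[a[4], ] - xyz[a[3], ]
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
              n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
      atan2(sum(m1 * n2), sum(n1 * n2))
    },
    OUT = {
      # signed distance of the central atom from its three neighbors' plane
      p <- xyz[a[1], ]
      q1 <- xyz[a[2], ]; q2 <- xyz[a[3], ]; q3 <- xyz[a[4], ]
      u <- q2 - q1; v <- q3 - q1
      nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      sum((p - q1) * nrm) / sqrt(sum(nrm^2))
    },
    stop("unknown internal-coordinate kind: ", kind, call. = FALSE)
  )
}

# First-order (Wilson-B-style) row of one internal coordinate: central
# finite-difference gradient of its value with respect to the 3N
# Cartesian coordinates, flattened atom-major.
b_row <- function(kind, a, xyz, h = 1e-5) {
  atoms <- a[!is.na(a)]
  g <- matrix(0, nrow(xyz), 3)
  for (at in atoms) {
    for (d in 1:3) {
      xp <- xyz; xp[at, d] <- xp[at, d] + h
      xm <- xyz; xm[at, d] <- xm[at, d] - h
      vp <- internal_value(kind, a, xp)
      vm <- internal_value(kind, a, xm)
      dv <- vp - vm
      if (kind == "TORS" && abs(dv) > pi) dv <- dv - sign(dv) * 2 * pi
      g[at, d] <- dv / (2 * h)
    }
  }
  as.numeric(t(g))  # atom-major flattening: x1 y1 z1 x2 ...
}

#' PED-style percentage breakdown of one normal mode
#'
#' Each internal coordinate's contribution is the squared projection of
#' the (unit-norm) Cartesian mode vector onto the unit direction of that
#' coordinate's first-order displacement row, normalized so the
#' contributions over all coordinates sum to 100 percent. Stretch
#' contributions are split by whether a hydrogen takes part.
#'
#' @param ms A [mode_set()].
#' @param mode_index Mode to analyse.
#' @param coords Internal coordinates from [perceive_topology()];
#'   defaults to perceiving the equilibrium geometry.
#' @return A one-row tibble: `mode`, `pct_stre_heavy`, `pct_stre_h`,
#'   `pct_bend`, `pct_tors`, `pct_out`.
#' @export
ped_percentages <- function(ms, mode_index, coords = perceive_topology(ms$equilibrium)) {
  if (nrow(coords) == 0L) stop("empty internal-coordinate list", call. = FALSE)
  xyz <- coord_matrix(ms$equilibrium)
  v <- as.numeric(t(mode_vector(ms, mode_index)))
  contrib <- numeric(nrow(coords))
  for (r in seq_len(nrow(coords))) {
    row <- b_row(coords$kind[r], c(coords$a1[r], coords$a2[r], coords$a3[r], coords$a4[r]), xyz)
    nrm <- sqrt(sum(row^2))
    if (nrm > 0) contrib[r] <- (sum(row * v) / nrm)^2
  }
  total <- sum(contrib)
  if (total <= 0) stop("mode ", mode_index, ": zero projection onto every internal coordinate",
                       call. = FALSE)
  pct <- 100 * contrib / total
  lab <- ifelse(coords$kind == "STRE",
                ifelse(coords$involves_hydrogen, "STRE_H", "STRE_HEAVY"),
                coords$kind)
  by_kind <- tapply(pct, factor(lab, levels = c("STRE_HEAVY", "STRE_H", "BEND", "TORS", "OUT")),
                    sum, default = 0)
  tibble::tibble(
    mode = mode_index,
    pct_stre_heavy = by_kind[["STRE_HEAVY"]], pct_stre_h = by_kind[["STRE_H"]],
    pct_bend = by_kind[["BEND"]], pct_tors = by_kind[["TORS"]], pct_out = by_kind[["OUT"]]
  )
}

#' Categorize a PED breakdown
#'
#' The motion type with the largest percentage wins when it reaches the
#' dominance threshold (a tie at exactly the threshold counts as
#' dominant); otherwise the mode is `MIX`.
#'
#' @param breakdown One-row tibble from [ped_percentages()] (or any data
#'   frame with the five `pct_*` columns).
#' @param dominance Dominance threshold in percent.
#' @return One of `"STRE_HEAVY"`, `"STRE_H"`, `"BEND"`, `"TORS"`,
#'   `"OUT"`, `"MIX"`.
#' @export
categorize <- function(breakdown, dominance = 60) {
  kinds <- c("STRE_HEAVY", "STRE_H", "BEND", "TORS", "OUT")
  pct <- vapply(paste0("pct_", tolower(kinds)), function(cn) breakdown[[cn]][1], numeric(1))
  names(pct) <- kinds
  top <- which.max(pct)
  if (pct[top] >= dominance) names(pct)[top] else "MIX"
}

#' PED categories for every mode of a mode set
#'
#' @param ms A [mode_set()].
#' @param coords Internal coordinates (defaults to perceiving the
#'   equilibrium geometry once).
#' @param dominance Dominance threshold passed to [categorize()].
#' @return A tibble `mode`, `category`, `pct_stre_heavy`, `pct_stre_h`,
#'   `pct_bend`, `pct_tors`, `pct_out`.
#' @export
ped_table <- function(ms, coords = perceive_topology(ms$equilibrium), dominance = 60) {
  purrr::map_dfr(ms$modes$mode, function(k) {
    bd <- ped_percentages(ms, k, coords)
    dplyr::mutate(bd, category = categorize(bd, dominance), .after = "mode")
  })
}
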