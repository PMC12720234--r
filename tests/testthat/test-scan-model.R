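make_table <- function(grid = displacement_grid(), mode = 1L,
                       s0 = function(x) 50 * x^2,
                       s1 = function(x) 3 + 40 * x^2) {
  x <- as.numeric(grid)
  dplyr::bind_rows(
    tibble::tibble(mode = mode, i = x, state = "S0", energy = s0(x)),
    tibble::tibble(mode = mode, i = x, state = "S1", energy = s1(x))
  )
}

test_that("assembly shifts the ground state to zero at i = 0", {
  tab <- make_table(s0 = function(x) 10 + 50 * x^2, s1 = function(x) 13 + 40 * x^2)
  scans <- assemble_scans(tab, unit = "ev")
  expect_equal(scans$energy[scans$state == "S0" & scans$i == 0], 0)
  expect_equal(scans$energy[scans$state == "S1" & scans$i == 0], 3)
  expect_equal(nrow(scans), 42L)
})

test_that("hartree energies convert with the CODATA factor", {
  tab <- make_table(s0 = function(x) ifelse(x == 0.1, 0.1, 0), s1 = function(x) 0.05)
  scans <- assemble_scans(tab, unit = "hartree")
  # a point 0.1 hartree above the reference lands at 2.7211 eV
  expect_equal(scans$energy[scans$state == "S0" & scans$i == 0.1],
               2.7211, tolerance = 1e-3 / 2.7211)
  expect_equal(scans$energy[scans$state == "S1" & scans$i == 0],
               0.05 * 27.211386245988, tolerance = 1e-12)
})

test_that("missing and duplicate records are rejected with named offenders", {
  tab <- make_table(mode = 3L)
  expect_error(assemble_scans(tab[!(tab$state == "S1" & tab$i == 0.07), ], unit = "ev"),
               "mode 3, state S1, i = 0.07")
  expect_error(assemble_scans(dplyr::bind_rows(tab, tab[1, ]), unit = "ev"), "duplicate")
})

test_that("a zero-coupling crossing is found at the grid point nearest the degeneracy", {
  spec <- two_state_spec(delta_e2 = 3.0 + 75 * 0.08 * (0.03 - 0.04), delta2 = 0.08,
                         s1_diabat = harmonic_potential(75),
                         s2_diabat = harmonic_potential(75),
                         expect_crossing = TRUE)
  out <- generate_two_state(spec)
  expect_equal(out$truth$crossing_i, 0.03, tolerance = 1e-8)
  scans <- assemble_scans(out$energies, unit = "ev")
  cr <- detect_crossings(scans)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$i_cross, 0.03)
  expect_gte(cr$gap_min, 0)
  expect_gte(cr$delta_e_ci, 0)
})

test_that("parallel states separated by a constant 1 eV yield no crossing", {
  x <- as.numeric(displacement_grid())
  tab <- dplyr::bind_rows(
    tibble::tibble(mode = 1L, i = x, state = "S0", energy = 50 * x^2),
    tibble::tibble(mode = 1L, i = x, state = "S1", energy = 3 + 40 * x^2),
    tibble::tibble(mode = 1L, i = x, state = "S2", energy = 4 + 40 * x^2)
  )
  scans <- assemble_scans(tab, unit = "ev")
  expect_equal(nrow(detect_crossings(scans, "S1", "S2", gap_threshold = 0.1)), 0L)
})

test_that("a gap minimum at a grid endpoint is not reported as a crossing", {
  x <- as.numeric(displacement_grid())
  # gap = 0.12 - x shrinks monotonically to 0.02 eV at the +0.1 endpoint
  tab <- dplyr::bind_rows(
    tibble::tibble(mode = 1L, i = x, state = "S0", energy = 50 * x^2),
    tibble::tibble(mode = 1L, i = x, state = "S1", energy = 3 + 2 * x),
    tibble::tibble(mode = 1L, i = x, state = "S2", energy = 3.12 + x)
  )
  scans <- assemble_scans(tab, unit = "ev")
  expect_equal(nrow(detect_crossings(scans, gap_threshold = 0.15)), 0L)
})

test_that("crossing detection is symmetric in the two state labels", {
  suite <- generate_benchmark_suite(30, seed = 8)
  scans <- assemble_scans(suite$energies, unit = "ev")
  a <- detect_crossings(scans, "S1", "S2")
  b <- detect_crossings(scans, "S2", "S1")
  expect_equal(a$mode, b$mode)
  expect_equal(a$crossing_index, b$crossing_index)
  expect_equal(a$gap_min, b$gap_min)
  expect_equal(a$delta_e_ci, b$delta_e_ci)
})

test_that("diabatization recovers the generator's diabats exactly at zero coupling", {
  spec <- two_state_spec(delta_e2 = 3.0 + 60 * 0.08 * (0.05 - 0.04), delta2 = 0.08,
                         s1_diabat = harmonic_potential(60),
                         s2_diabat = harmonic_potential(60),
                         expect_crossing = TRUE)
  out <- generate_two_state(spec)
  scans <- assemble_scans(out$energies, unit = "ev")
  cr <- detect_crossings(scans)
  expect_equal(nrow(cr), 1L)
  diab <- diabatize(scans, cr)
  # relabeled S1 must equal diabat 1 (the harmonic 60-curvature branch) everywhere
  x <- as.numeric(displacement_grid())
  v1 <- 3.0 + 0.5 * 60 * x^2
  s1 <- diab$energy[diab$state == "S1"][order(diab$i[diab$state == "S1"])]
  expect_lt(max(abs(s1 - v1)), 1e-9)
  expect_true(attr(diab, "diabatization")$swapped[1])
})

test_that("diabatization is a no-op without a crossing and preserves point-wise energy multisets", {
  suite <- generate_benchmark_suite(40, seed = 21)
  scans <- assemble_scans(suite$energies, unit = "ev")
  cr <- detect_crossings(scans)
  diab <- diabatize(scans, cr)
  uncrossed <- setdiff(unique(scans$mode), cr$mode)
  expect_equal(diab$energy[diab$mode %in% uncrossed], scans$energy[scans$mode %in% uncrossed])
  # energy conservation: the sorted energies at every (mode, i) are unchanged
  before <- scans |> dplyr::group_by(mode, i) |>
    dplyr::summarise(e = list(sort(energy)), .groups = "drop")
  after <- diab |> dplyr::group_by(mode, i) |>
    dplyr::summarise(e = list(sort(energy)), .groups = "drop")
  expect_equal(before, after)
})

test_that("diabatization is idempotent", {
  suite <- generate_benchmark_suite(30, seed = 22)
  scans <- assemble_scans(suite$energies, unit = "ev")
  once <- diabatize(scans, detect_crossings(scans))
  twice <- diabatize(once, detect_crossings(once))
  expect_equal(twice$energy, once$energy)
  expect_equal(twice$state, once$state)
})

test_that("branch swapping never increases, and on crossings strictly reduces, summed fit RMSD", {
  suite <- generate_benchmark_suite(100, seed = 23,
                                    proportions = c(harmonic = 0, fc_shift = 0,
                                                    morse_s1 = 0, morse_s1_fc = 0,
                                                    both_anh = 0, crossing = 1))
  scans <- assemble_scans(suite$energies, unit = "ev")
  cr <- detect_crossings(scans)
  expect_equal(sort(cr$mode), sort(suite$truth$mode))
  diab <- diabatize(scans, cr)
  total_rmsd <- function(s, m) {
    f <- fit_scans(s[s$mode == m & s$state %in% c("S1", "S2"), ])
    sum(f$rmsd)
  }
  for (m in cr$mode) {
    expect_lt(total_rmsd(diab, m), total_rmsd(scans, m))
  }
})

test_that("a supplied state-character scalar drives the relabeling", {
  spec <- two_state_spec(delta_e2 = 3.0 + 60 * 0.08 * (0.05 - 0.04), delta2 = 0.08,
                         s1_diabat = harmonic_potential(60),
                         s2_diabat = harmonic_potential(60),
                         expect_crossing = TRUE)
  out <- generate_two_state(spec)
  scans <- assemble_scans(out$energies, unit = "ev")
  cr <- detect_crossings(scans)
  # oscillator-strength-like trace: diabat 1 bright (1.0), diabat 2 dark (0.0)
  lab <- out$truth$labels
  chars <- dplyr::bind_rows(
    tibble::tibble(mode = 1L, i = lab$i, state = "S1",
                   value = ifelse(lab$lower_diabat == 1L, 1, 0)),
    tibble::tibble(mode = 1L, i = lab$i, state = "S2",
                   value = ifelse(lab$lower_diabat == 1L, 0, 1))
  )
  diab <- diabatize(scans, cr, character_values = chars)
  x <- sort(unique(scans$i))
  v1 <- 3.0 + 0.5 * 60 * x^2
  s1 <- diab$energy[diab$state == "S1"][order(diab$i[diab$state == "S1"])]
  expect_lt(max(abs(s1 - v1)), 1e-9)
})
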