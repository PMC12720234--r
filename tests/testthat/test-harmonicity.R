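test_that("an exact parabola is recovered with zero RMSD and unit R^2", {
  g <- as.numeric(displacement_grid())
  f <- fit_quadratic(g, 2 * g^2 + 3 * g + 1)
  expect_equal(c(f$a, f$b, f$c), c(2, 3, 1), tolerance = 1e-10)
  expect_lt(f$rmsd, 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("constant data fit as a = b = 0, c = value, R^2 = 1 by convention", {
  g <- as.numeric(displacement_grid())
  f <- fit_quadratic(g, rep(5, length(g)))
  expect_equal(c(f$a, f$b, f$c), c(0, 0, 5), tolerance = 1e-10)
  expect_lt(f$rmsd, 1e-12)
  expect_equal(f$r2, 1)
})

test_that("fit coefficients agree with the normal-equations oracle on a Morse curve", {
  g <- as.numeric(displacement_grid())
  D <- 4; alpha <- 1
  y <- D * (1 - exp(-alpha * g))^2
  f <- fit_quadratic(g, y)
  o <- quad_oracle(g, y)
  expect_equal(c(f$a, f$b, f$c), o, tolerance = 1e-10)
  # on a symmetric grid the cubic cancels; the quartic Taylor term nudges the
  # fitted curvature just above the i -> 0 value D * alpha^2
  expect_gt(f$a, D * alpha^2)
  expect_lt(abs(f$a / (D * alpha^2) - 1), 0.01)
})

test_that("fit coefficients match the oracle to 1e-10 on 1000 random scans", {
  set.seed(881)
  g <- as.numeric(displacement_grid())
  worst <- 0
  for (r in 1:1000) {
    y <- runif(1, -50, 150) * g^2 + runif(1, -10, 10) * g + runif(1, -1, 4) +
      rnorm(length(g), sd = 10^runif(1, -4, -1))
    f <- fit_quadratic(g, y)
    worst <- max(worst, abs(c(f$a, f$b, f$c) - quad_oracle(g, y)))
  }
  expect_lt(worst, 1e-10)
})

test_that("adding a constant shifts only c, never a, b, RMSD or R^2", {
  set.seed(882)
  g <- as.numeric(displacement_grid())
  for (r in 1:50) {
    y <- runif(1, 10, 100) * g^2 + runif(1, -5, 5) * g + rnorm(length(g), sd = 0.01)
    f1 <- fit_quadratic(g, y)
    f2 <- fit_quadratic(g, y + 7.3)
    expect_equal(f2$a, f1$a, tolerance = 1e-9)
    expect_equal(f2$b, f1$b, tolerance = 1e-9)
    expect_equal(f2$c, f1$c + 7.3, tolerance = 1e-9)
    expect_equal(f2$rmsd, f1$rmsd, tolerance = 1e-9)
  }
})

test_that("coefficients recovered from noisy harmonic scans are unbiased", {
  set.seed(883)
  g <- as.numeric(displacement_grid())
  a0 <- 60; b0 <- -2; c0 <- 3; sigma <- 0.01
  est <- t(replicate(500, {
    f <- fit_quadratic(g, a0 * g^2 + b0 * g + c0 + rnorm(length(g), sd = sigma))
    c(f$a, f$b, f$c)
  }))
  # mean estimate within 3 standard errors of the truth for each coefficient
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - c(a0, b0, c0)) < 3 * se))
})

test_that("RMSD/E_average follows the ground and excited definitions", {
  g <- as.numeric(displacement_grid())
  f <- list(rmsd = 0.02)
  class(f) <- "quad_fit"
  y <- rep(0.5, 21)
  expect_equal(rmsd_ratio(f, y, "ground"), 0.04)
  f$rmsd <- 0.001
  y2 <- rep(3.0934006, 21)
  expect_equal(rmsd_ratio(f, y2, "excited", excitation_offset = 2.9934006), 0.01,
               tolerance = 1e-9)
  f$rmsd <- 0
  expect_equal(rmsd_ratio(f, y, "ground"), 0)
  expect_error(rmsd_ratio(f, rep(2.9934006, 21), "excited", excitation_offset = 2.9934006),
               "undefined")
})

test_that("relaxation energy follows vertex algebra for interior minima", {
  g <- as.numeric(displacement_grid())
  # parabola with vertex at i0 = 0.05, curvature coefficient a = 10
  y <- 10 * (g - 0.05)^2 + 2.9
  rel <- relaxation_energy(fit_quadratic(g, y), g, y)
  expect_equal(rel$lambda, 10 * 0.05^2, tolerance = 1e-10)
  expect_false(rel$fallback)
  expect_equal(rel$minimum_at, 0.05, tolerance = 1e-8)
  # symmetric scan: vertex at the origin, lambda = 0
  y0 <- 10 * g^2 + 2.9
  expect_equal(relaxation_energy(fit_quadratic(g, y0), g, y0)$lambda, 0, tolerance = 1e-12)
  # lambda = b^2 / (4 a) for an exact fit with interior vertex
  f <- fit_quadratic(g, y)
  expect_equal(relaxation_energy(f, g, y)$lambda, f$b^2 / (4 * f$a), tolerance = 1e-8)
})

test_that("concave fits fall back to the minimum scanned point and record it", {
  g <- as.numeric(displacement_grid())
  y <- 3 - 5 * g^2
  rel <- relaxation_energy(fit_quadratic(g, y), g, y)
  expect_true(rel$fallback)
  expect_equal(rel$lambda, 0.05, tolerance = 1e-10)  # 3 - (3 - 5 * 0.01)
  expect_gte(rel$lambda, 0)
})

test_that("lambda recovery on synthetic FC-active scans is within 2% of truth", {
  set.seed(884)
  errs <- numeric(50)
  for (r in 1:50) {
    k1 <- runif(1, 50, 120)
    delta <- runif(1, 0.03, 0.07)
    spec <- two_state_spec(s1_diabat = harmonic_potential(k1),
                           s2_diabat = harmonic_potential(k1),
                           delta1 = delta, delta2 = delta)
    out <- generate_two_state(spec)
    scans <- assemble_scans(out$energies, unit = "ev")
    m <- mode_metrics(scans)
    errs[r] <- abs(m$lambda - out$truth$lambda_interval[["s1"]]) /
      out$truth$lambda_interval[["s1"]]
  }
  expect_lt(max(errs), 0.02)
})

test_that("mode metrics obey their definitional identities", {
  suite <- generate_benchmark_suite(30, seed = 31, noise_sd = 1e-3)
  scans <- assemble_scans(suite$energies, unit = "ev")
  scans <- diabatize(scans, detect_crossings(scans))
  m <- mode_metrics(scans)
  expect_equal(m$delta_rmsd_ratio, m$ratio_s1 - m$ratio_s0, tolerance = 1e-12)
  expect_equal(m$delta_a, m$a_s1 - m$a_s0)
  expect_true(all(m$lambda >= 0))
  # identical S0 and S1 curves give all-zero deltas and lambda
  x <- as.numeric(displacement_grid())
  tab <- dplyr::bind_rows(
    tibble::tibble(mode = 1L, i = x, state = "S0", energy = 50 * x^2),
    tibble::tibble(mode = 1L, i = x, state = "S1", energy = 3 + 50 * x^2)
  )
  m1 <- mode_metrics(assemble_scans(tab, unit = "ev"))
  expect_equal(m1$delta_a, 0, tolerance = 1e-10)
  expect_equal(m1$delta_b, 0, tolerance = 1e-10)
  expect_equal(m1$lambda, 0, tolerance = 1e-10)
})

test_that("delta a is negative exactly when the excited curvature is smaller", {
  suite <- generate_benchmark_suite(40, seed = 32)
  scans <- assemble_scans(suite$energies, unit = "ev")
  scans <- diabatize(scans, detect_crossings(scans))
  m <- mode_metrics(scans)
  j <- dplyr::inner_join(m, suite$truth, by = "mode")
  # generator draws always have S1 curvature below S0 curvature
  expect_true(all(j$curvature_s1 < j$curvature_s0))
  # for harmonic excited states the fitted curvature is the true one, so the
  # smaller S1 curvature shows up directly as delta_a < 0 (a Morse S1 adds a
  # positive quartic contribution to the fitted a, so it is excluded here)
  harm_s1 <- j$scenario %in% c("harmonic", "fc_shift", "crossing")
  expect_true(all(j$delta_a[harm_s1] < 0))
})

test_that("the default excitation offset equals the i = 0 vertical gap and can be overridden", {
  x <- as.numeric(displacement_grid())
  tab <- dplyr::bind_rows(
    tibble::tibble(mode = 1L, i = x, state = "S0", energy = 50 * x^2),
    tibble::tibble(mode = 1L, i = x, state = "S1",
                   energy = 2.9934006 + 40 * x^2 + 5 * x^3)
  )
  scans <- assemble_scans(tab, unit = "ev")
  m_auto <- mode_metrics(scans)
  expect_equal(m_auto$excitation_offset, 2.9934006)
  m_fix <- mode_metrics(scans, excitation_offset = 2.5)
  expect_equal(m_fix$excitation_offset, 2.5)
  expect_false(isTRUE(all.equal(m_fix$ratio_s1, m_auto$ratio_s1)))
})
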