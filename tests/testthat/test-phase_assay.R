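test_that("absorbance-to-turbidity follows the transmittance relation", {
  expect_equal(as.numeric(absorbance_to_turbidity(0.3, 0.3)), 0)
  expect_equal(as.numeric(absorbance_to_turbidity(1.3, 0.3)), 90)
  # readings below the blank go negative and are flagged, not clamped
  t <- absorbance_to_turbidity(0.3 - 0.0458, 0.3)
  expect_equal(as.numeric(t), 100 * (1 - 10^0.0458), tolerance = 1e-12)
  expect_lt(as.numeric(t), -11)
  expect_true(attr(t, "negative"))
  expect_error(absorbance_to_turbidity(NaN, 0.3), "non-finite")
})

test_that("salt series accounts for cumulative dilution", {
  r <- titration_record(100, 0, 1000, 100, c(0.5, 0.4), 0.05)
  expect_equal(salt_series(r), c(0, 500))
  r2 <- titration_record(100, 0, 3000, c(10, 10), c(0.5, 0.4, 0.3), 0.05)
  expect_equal(salt_series(r2), c(0, 3000 * 10 / 110, 3000 * 20 / 120))
  r3 <- titration_record(100, 150, 3000, numeric(0), 0.5, 0.05)
  expect_equal(salt_series(r3), 150)
})

test_that("titration record validates its shape", {
  expect_error(titration_record(100, 0, 1000, c(10, -5), c(1, 2, 3), 0.05),
               "addition volumes")
  expect_error(titration_record(100, 0, 1000, 10, c(1, 2, 3), 0.05),
               "length")
})

test_that("steepest tangent picks the maximal-|slope| window, first on ties", {
  f <- steepest_tangent(x = c(0, 50, 100, 150, 200),
                        y = c(100, 100, 50, 0, 0))
  expect_equal(f$slope, -1)
  expect_equal(f$window_start_index, 2L)
  # perfectly linear curve: every window ties; the first is returned
  g <- steepest_tangent(x = 1:10, y = 2 * (1:10) + 3)
  expect_equal(g$window_start_index, 1L)
  expect_equal(g$slope, 2)
  expect_error(steepest_tangent(x = 1:2, y = 1:2), "at least 3")
})

test_that("steepest tangent equals exhaustive enumeration on random curves", {
  set.seed(42)
  for (i in 1:25) {
    x <- sort(runif(12, 0, 100))
    y <- 100 / (1 + exp(0.2 * (x - 50))) + rnorm(12, 0, 3)
    f <- steepest_tangent(x = x, y = y)
    o <- oracle_steepest(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$window_start_index, o$start)
  }
})

test_that("CSC is the tangent's x-intercept", {
  t1 <- structure(list(slope = -1, intercept = 120), class = "tangent_fit")
  expect_equal(csc_from_tangent(t1), 120)
  t2 <- structure(list(slope = -0.5, intercept = 120), class = "tangent_fit")
  expect_equal(csc_from_tangent(t2), 240)
  t0 <- structure(list(slope = 0, intercept = 50), class = "tangent_fit")
  expect_error(csc_from_tangent(t0), "degenerate")
})

test_that("CSC extraction converges to the logistic closed form c0 + 2/k", {
  s1 <- gen_titration(seed = 1, k = 0.1, c0 = 100, n_points = 1000,
                      noise_sd = 0, c_max = 300)
  expect_equal(extract_csc(s1$record)$csc, 120, tolerance = 1 / 120)
  s2 <- gen_titration(seed = 1, k = 0.2, c0 = 200, n_points = 1000,
                      noise_sd = 0, c_max = 400)
  expect_equal(extract_csc(s2$record)$csc, 210, tolerance = 1 / 210)
})

test_that("flat curves raise an insufficient-signal error", {
  r <- titration_record(100, 0, 1000, rep(10, 10),
                        rep(0.05, 11), 0.05)
  expect_error(extract_csc(r), "insufficient signal")
})

test_that("incomplete dissolution is flagged", {
  # curve that never decays to the blank level
  s <- gen_titration(seed = 1, k = 0.1, c0 = 900, n_points = 50,
                     noise_sd = 0, c_max = 800)
  expect_warning(extract_csc(s$record), "incomplete")
})

test_that("CSC, onset and minimal-complex outputs scale with concentration units", {
  s <- gen_titration(seed = 7, k = 0.1, c0 = 150, noise_sd = 0.5)
  curve <- turbidity_curve(s$record)
  base <- extract_csc(curve)$csc
  for (sc in c(0.001, 10)) {
    scaled <- curve
    scaled$salt_conc <- scaled$salt_conc * sc
    expect_equal(extract_csc(scaled)$csc, base * sc, tolerance = 1e-9)
  }
  conc <- c(1, 2, 3, 4)
  turb <- c(5, 10, 25, 80)
  expect_equal(onset_concentration(conc * 5, turb),
               5 * onset_concentration(conc, turb))
})

test_that("onset is the first strict crossing of 20% turbidity", {
  expect_equal(onset_concentration(c(1, 2, 3, 4), c(5, 10, 25, 80)), 3)
  out <- onset_concentration(c(1, 2, 3), c(5, 10, 19))
  expect_true(is.na(out))
  expect_true(attr(out, "no_onset"))
  expect_equal(onset_concentration(c(1, 2), c(21, 90)), 1)
  # exactly 20% does not trigger (strict >)
  expect_equal(onset_concentration(c(1, 2), c(20, 30)), 2)
})

test_that("minimal complex concentration is the rising tangent's x-intercept", {
  conc <- seq(0, 4, length.out = 400)
  turb <- 90 / (1 + exp(-2 * (conc - 2)))
  expect_equal(minimal_complex_concentration(conc, turb), 2 - 2 / 2,
               tolerance = 0.02)
  expect_error(minimal_complex_concentration(conc, rev(turb)), "rising")
})

test_that("N_min fit is exact on collinear input and order-invariant", {
  f <- fit_nmin(c(4, 8), c(100, 250))
  expect_equal(f$slope, -1200)
  expect_equal(f$intercept, 400)
  expect_equal(f$n_min, 3)
  n <- c(4, 6, 8)
  csc <- -1200 / n + 400
  f3 <- fit_nmin(n, csc)
  expect_equal(f3$n_min, 3, tolerance = 1e-12)
  expect_equal(f3$r_squared, 1, tolerance = 1e-12)
  perm <- c(2, 3, 1)
  expect_equal(fit_nmin(n[perm], csc[perm])$n_min, f3$n_min,
               tolerance = 1e-12)
})

test_that("planted N_min is recovered from a noisy length series", {
  s <- gen_length_series(seed = 11)
  f <- fit_nmin(s$peptide_lengths, s$csc_values)
  expect_equal(f$n_min, s$truth$n_min, tolerance = 0.05)
})

test_that("non-physical N_min fits are flagged", {
  expect_warning(f <- fit_nmin(c(4, 8), c(400, 250)), "never crosses")
  expect_true(f$non_physical)
  expect_error(fit_nmin(c(4, 4), c(1, 2)), "distinct")
})
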