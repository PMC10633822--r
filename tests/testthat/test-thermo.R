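test_that("free energy <-> dissociation constant conversions reproduce printed values", {
  # (dG_d kJ/mol, T K) -> K_d mM pairs from the reference thermodynamic table
  expect_equal(kd_from_dG(20.71, 300), 0.249, tolerance = 0.01)
  expect_equal(kd_from_dG(19.50, 323), 0.705, tolerance = 0.01)
  expect_equal(kd_from_dG(18.23, 345), 1.741, tolerance = 0.01)
  expect_equal(kd_from_dG(17.17, 323), 1.677, tolerance = 0.01)
  # zero free energy gives the standard concentration
  expect_identical(kd_from_dG(0, 312), 1000)
  # round trip to 1e-12 relative
  for (dg in c(-5, 0.3, 18.2, 40)) {
    expect_equal(dG_from_kd(kd_from_dG(dg, 317), 317), dg,
                 tolerance = 1e-12)
  }
})

test_that("Van't Hoff fits reproduce the printed enthalpies and reference constants", {
  coh <- vant_hoff_fit(c(300, 323, 345), c(0.249, 0.705, 1.741), T0 = 298)
  expect_equal(coh$dH, 37.2, tolerance = 0.01)
  expect_equal(coh$K_d0, 0.225, tolerance = 0.01)
  co <- vant_hoff_fit(c(300, 323, 345), c(0.912, 1.677, 3.194), T0 = 298)
  expect_equal(co$dH, 24.0, tolerance = 0.01)
  expect_equal(co$K_d0, 0.855, tolerance = 0.01)
  # predicted K at T0 is K_d0 exactly
  expect_equal(predict(coh, 298), coh$K_d0, tolerance = 1e-12)
})

test_that("noiseless log-linear K(T) is recovered to machine precision", {
  Ts <- c(290, 310, 330)
  K <- temperature_adjust(1, 298, 50, Ts)
  for (method in c("lnK_regression", "global_nonlinear")) {
    for (k0m in c("extrapolate_from_nearest_T", "regression_intercept")) {
      fit <- vant_hoff_fit(Ts, K, T0 = 298, fit_method = method,
                           K_d0_method = k0m)
      expect_equal(fit$dH, 50, tolerance = 1e-7)
      expect_equal(fit$K_d0, 1, tolerance = 1e-7)
      expect_true(all(abs(fit$residuals) < 1e-8))
    }
  }
  expect_error(vant_hoff_fit(c(300, 300), c(1, 2)), "distinct")
  expect_error(vant_hoff_fit(c(300, 320), c(1, -2)), "positive")
})

test_that("for positive dissociation enthalpy K_d increases with temperature", {
  fit <- vant_hoff_fit(c(300, 323, 345), c(0.249, 0.705, 1.741))
  Ts <- seq(280, 360, by = 5)
  expect_true(all(diff(predict(fit, Ts)) > 0))
})

test_that("well integration matches closed forms and fine-grid quadrature", {
  kT <- 8.314e-3 * 300
  # W == 0: Q is the shell volume (4pi/3)(r1^3 - r0^3)
  flat <- pmf_profile(seq(3, 6, by = 0.002), rep(0, length(seq(3, 6, by = 0.002))),
                      temperature = 300)
  res0 <- integrate_association(flat, 3.9, 5.3)
  expect_equal(res0$Q, 4 * pi / 3 * (5.3^3 - 3.9^3), tolerance = 1e-6)
  expect_equal(res0$dG_dissociation,
               kT * log(4 * pi / 3 * (5.3^3 - 3.9^3) /
                          (1e27 / 6.02214076e23)),
               tolerance = 1e-6)
  # W == -eps shifts the association free energy by exactly eps
  eps <- 2.3
  shifted <- pmf_profile(flat$bin_centers,
                         rep(-eps, length(flat$bin_centers)), 300)
  rese <- integrate_association(shifted, 3.9, 5.3)
  expect_equal(rese$dG_dissociation, res0$dG_dissociation + eps,
               tolerance = 1e-10)
  # default model landscape vs adaptive quadrature of the same integrand
  pmf <- make_default_pmf()
  prof <- pmf_from_model(pmf, 3.2, 12, bin_width = 0.002)
  res <- integrate_association(prof)
  Qo <- stats::integrate(function(r) {
    4 * pi * r^2 * exp(-evaluate_pmf(pmf, r) / kT)
  }, 3.9, 5.3, rel.tol = 1e-11)$value
  dGo <- kT * log(Qo / (1e27 / 6.02214076e23))
  expect_equal(res$dG_dissociation, dGo, tolerance = 1e-3 / dGo)
  # exact round-trip identity under the 1 M molar convention
  expect_equal(res$K_d, kd_from_dG(res$dG_dissociation, 300),
               tolerance = 1e-12)
})

test_that("quadrature is stable under bin refinement and standard-state switches work", {
  pmf <- make_default_pmf()
  d1 <- integrate_association(pmf_from_model(pmf, 3.2, 12, 0.05))
  d2 <- integrate_association(pmf_from_model(pmf, 3.2, 12, 0.025))
  expect_lt(abs(d1$dG_dissociation - d2$dG_dissociation), 0.05)
  # solvent mole-fraction convention with the cyclohexane molecular volume
  vs <- solvent_molar_volume(814, 84.16)
  prof <- pmf_from_model(pmf, 3.2, 12, 0.01)
  rx <- integrate_association(prof, standard_state = "solvent_mole_fraction",
                              v_s = vs)
  rm_ <- integrate_association(prof)
  kT <- 8.314e-3 * 300
  # conventions differ by exactly kT ln(v_s / V_1M)
  expect_equal(rm_$dG_dissociation - rx$dG_dissociation,
               kT * log(vs / (1e27 / 6.02214076e23)), tolerance = 1e-10)
  expect_error(integrate_association(prof,
                                     standard_state = "solvent_mole_fraction"),
               "v_s")
})

test_that("minima are located with sub-bin accuracy", {
  pmf <- make_default_pmf()
  prof <- pmf_from_model(pmf, 3.2, 12, bin_width = 0.01)
  mins <- find_minima(prof)
  expect_equal(nrow(mins), 2)
  expect_equal(mins$r[1], 3.8, tolerance = 0.05 / 3.8)
  expect_equal(mins$r[2], 4.6, tolerance = 0.05 / 4.6)
  # single parabola: vertex within one bin width
  r <- seq(1, 3, by = 0.02)
  par <- pmf_profile(r, 5 * (r - 2.013)^2 - 1, 300)
  vtx <- find_minima(par)
  expect_equal(nrow(vtx), 1)
  expect_lt(abs(vtx$r - 2.013), 0.02)
  # monotone profile has no minima
  mono <- pmf_profile(r, 3 * r, 300)
  expect_error(find_minima(mono), "no local minima")
})

test_that("open/closed decomposition matches a fine-grid oracle and sums to one", {
  pmf <- make_default_pmf()
  prof <- pmf_from_model(pmf, 3.2, 12, bin_width = 0.002)
  oc <- open_closed_decomposition(prof, boundary = 4.2)
  kT <- 8.314e-3 * 300
  q <- function(a, b) stats::integrate(function(r) {
    4 * pi * r^2 * exp(-evaluate_pmf(pmf, r) / kT)
  }, a, b, rel.tol = 1e-11)$value
  expect_equal(oc$fraction_open, q(4.2, 5.3) / (q(3.9, 4.2) + q(4.2, 5.3)),
               tolerance = 1e-4)
  expect_equal(oc$fraction_closed + oc$fraction_open, 1, tolerance = 1e-12)
  # symmetric double well split at the midpoint: equal up to the r^2 weight
  r <- seq(1, 9, by = 0.002)
  W <- -10 * exp(-(r - 4)^2 / 0.08) - 10 * exp(-(r - 6)^2 / 0.08)
  sym <- pmf_profile(r, W, 300)
  ocs <- open_closed_decomposition(sym, boundary = 5, r0 = 3, r1 = 7)
  qs <- function(a, b) stats::integrate(function(x) {
    4 * pi * x^2 * exp((10 * exp(-(x - 4)^2 / 0.08) +
                          10 * exp(-(x - 6)^2 / 0.08)) / kT)
  }, a, b, rel.tol = 1e-10)$value
  expect_equal(ocs$fraction_open, qs(5, 7) / (qs(3, 5) + qs(5, 7)),
               tolerance = 1e-4)
  expect_error(open_closed_decomposition(prof, boundary = 5.4), "boundary")
})

test_that("secondary-minimum contribution is small, positive, and monotone in depth", {
  # tiny flat secondary range adds essentially nothing
  r <- seq(2, 8, by = 0.005)
  prof <- pmf_profile(r, -20 * exp(-(r - 2.7)^2 / 0.08), 300)
  tiny <- secondary_minimum_contribution(prof, c(2.3, 3.3), c(6.0, 6.01))
  expect_lt(abs(tiny), 0.05)
  # COH-water landscape: contribution within the expected 0-8% band
  coh <- pmf_from_model(make_water_pmf("COH"), 2.2, 8, 0.005)
  pct <- secondary_minimum_contribution(coh, c(2.3, 3.5), c(4.2, 5.8))
  expect_gte(pct, 0)
  expect_lte(pct, 8)
  # deepening the secondary well strictly increases the contribution
  pcts <- vapply(c(1, 2, 4, 6), function(d) {
    m <- make_water_pmf("COH", secondary_depth = d)
    secondary_minimum_contribution(pmf_from_model(m, 2.2, 8, 0.005),
                                   c(2.3, 3.5), c(4.2, 5.8))
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))
  expect_error(
    secondary_minimum_contribution(coh, c(2.3, 4.5), c(4.2, 5.8)),
    "disjoint")
})

test_that("solvent molecular volumes follow from density and molar mass", {
  expect_equal(solvent_molar_volume(814, 84.16), 171.7, tolerance = 0.001)
  expect_equal(solvent_molar_volume(1000, 18.015), 29.9, tolerance = 0.001)
  expect_equal(solvent_molar_volume(2 * 814, 84.16),
               solvent_molar_volume(814, 84.16) / 2, tolerance = 1e-12)
  expect_error(solvent_molar_volume(-1, 18), "positive")
})

test_that("integration guards reject unsampled bins and bad limits", {
  W <- c(0, 0, Inf, 0, 0, 0, 0, 0)
  prof <- pmf_profile(seq(4, 4.7, by = 0.1), W, 300)
  expect_error(integrate_association(prof, 4.0, 4.6), "Inf")
  expect_error(integrate_association(prof, 4.6, 4.0), "r0 < r1")
})
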