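test_that("single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(31)
  x <- 5 + abs(rnorm(5000, sd = 0.4))
  w <- umbrella_window(center = 5, spring = 0, temperature = 300,
                       samples = x)
  ds <- umbrella_dataset(list(w))
  cfg <- wham_config(bin_width = 0.05)
  prof <- suppressWarnings(solve_wham(ds, cfg, zero_region = c(5, 5.5)))
  kT <- 8.314e-3 * 300
  h <- oracle_histogram(x, 0.05)
  Wdir <- ifelse(h$counts > 0, -kT * log(h$counts / sum(h$counts)), Inf)
  m <- match_bins(prof$bin_centers, h$centers, 0.05)
  ok <- is.finite(prof$W) & is.finite(Wdir[m])
  expect_lt(max_gauge_free_diff(prof$W[ok], Wdir[m][ok]), 1e-9)
})

test_that("duplicating every window leaves the solution unchanged (counts scale out)", {
  ds <- small_dataset(seed = 41, n_samples = 800)
  h <- pmfassoc:::umbrella_histograms(ds, 0.05)
  b <- pmfassoc:::bias_matrix_kT(ds, h$centers)
  s1 <- pmfassoc:::wham_core(h$counts, b, 1e-9, 1e5)
  s2 <- pmfassoc:::wham_core(cbind(h$counts, h$counts), cbind(b, b),
                             1e-9, 1e5)
  expect_equal(s1$P, s2$P, tolerance = 1e-7)
})

test_that("adding per-window constants to the bias leaves the profile unchanged", {
  ds <- small_dataset(seed = 42, n_samples = 800)
  h <- pmfassoc:::umbrella_histograms(ds, 0.05)
  b <- pmfassoc:::bias_matrix_kT(ds, h$centers)
  shift <- seq_len(ncol(b)) * 0.7
  s1 <- pmfassoc:::wham_core(h$counts, b, 1e-10, 1e5)
  s2 <- pmfassoc:::wham_core(h$counts, sweep(b, 2, shift, "+"), 1e-10, 1e5)
  expect_equal(s1$P, s2$P, tolerance = 1e-7)
})

test_that("WHAM recovers the generating model PMF at the standard sampling density", {
  pmf <- make_default_pmf()
  ds <- run_schedule(pmf, 15, 3.5, config = sampler_config(seed = 3))
  prof <- suppressWarnings(solve_wham(ds))
  sel <- prof$bin_centers >= 3.6 & prof$bin_centers <= 9.0
  expect_true(all(is.finite(prof$W[sel])))
  W_true <- evaluate_pmf(pmf, prof$bin_centers[sel])
  expect_lt(max(abs(prof$W[sel] - W_true)), 0.5)
  # referencing invariant: mean over zero region is exactly zero
  zr <- prof$zero_region
  zsel <- prof$bin_centers >= zr[1] & prof$bin_centers <= zr[2] &
    is.finite(prof$W)
  expect_lt(abs(mean(prof$W[zsel])), 1e-9)
})

test_that("WHAM agrees with independent reweighting implementations on random datasets", {
  for (seed in c(11, 12, 13)) {
    ds <- small_dataset(seed = seed)
    prof <- suppressWarnings(solve_wham(ds, wham_config(),
                                        zero_region = c(5.5, 7.2)))
    # likelihood-maximization WHAM: same estimator, independent algorithm
    ref <- likelihood_wham(ds, 0.05)
    m <- match_bins(prof$bin_centers, ref$centers, 0.05)
    ok <- is.finite(prof$W) & is.finite(ref$W[m])
    expect_lt(max_gauge_free_diff(prof$W[ok], ref$W[m][ok]), 0.1)
    # sample-based MBAR: no histogram discretization of the bias; compare
    # on well-populated bins where the shared binning of P is benign
    mb <- mbar_pmf(ds, 0.05)
    m2 <- match_bins(prof$bin_centers, mb$centers, 0.05)
    heavy <- is.finite(prof$W) & mb$counts[m2] >= 200
    expect_lt(max_gauge_free_diff(prof$W[heavy], mb$W[m2][heavy]), 0.1)
  }
})

test_that("overlap of identical and disjoint windows hits the bounds", {
  pmf <- make_default_pmf()
  cfg <- sampler_config(n_samples = 1000, seed = 5)
  w1 <- sample_window(pmf, 11, 6, 300, cfg)
  w2 <- w1
  w2$center <- w1$center + 1e-9   # same samples, nominally distinct window
  ds_same <- umbrella_dataset(list(w1, w2))
  expect_equal(overlap_matrix(ds_same)$overlap, 1.0, tolerance = 1e-12)
  w3 <- sample_window(pmf, 14, 6, 300, sampler_config(n_samples = 1000,
                                                      seed = 6))
  ds_far <- umbrella_dataset(list(w1, w3))
  expect_equal(overlap_matrix(ds_far)$overlap, 0.0, tolerance = 1e-12)
})

test_that("flat-PMF overlap matches the closed-form normal overlap", {
  flat <- model_pmf(wells = data.frame(center = 100, depth = 1e-12,
                                       width = 1),
                    wall_position = 0.5, wall_steepness = 15)
  kT <- 8.314e-3 * 300
  sigma <- sqrt(kT / (6 * 4.184))
  delta <- 0.5
  ds <- umbrella_dataset(list(
    sample_window(flat, 30, 6, 300, sampler_config(seed = 21)),
    sample_window(flat, 30 + delta, 6, 300, sampler_config(seed = 22))))
  ov <- overlap_matrix(ds, wham_config(bin_width = 0.02))
  expect_equal(ov$overlap, 2 * pnorm(-delta / (2 * sigma)),
               tolerance = 0.02 / (2 * pnorm(-delta / (2 * sigma))))
})

test_that("bootstrap error vanishes when every window is concentrated in one bin", {
  w1 <- umbrella_window(5.0, 6, 300, rep(5.012, 400))
  w2 <- umbrella_window(5.1, 6, 300, rep(5.062, 400))
  ds <- umbrella_dataset(list(w1, w2))
  prof <- bootstrap_error(ds, wham_config(bootstrap_replicates = 20,
                                          seed = 4),
                          zero_region = c(4.9, 5.2))
  expect_true(all(prof$W_error[is.finite(prof$W)] == 0))
})

test_that("bootstrap error shrinks roughly as 1/sqrt(n)", {
  pmf <- make_default_pmf()
  err_for <- function(n, seed) {
    ds <- run_schedule(pmf, 5.5, 3.5, spacing = 0.5, spring = 6,
                       temperature = 300,
                       config = sampler_config(n_samples = n, seed = seed))
    prof <- suppressWarnings(
      bootstrap_error(ds, wham_config(bootstrap_replicates = 80, seed = 77),
                      zero_region = c(5.0, 5.6)))
    sel <- prof$bin_centers >= 3.7 & prof$bin_centers <= 5.0 &
      is.finite(prof$W)
    mean(prof$W_error[sel])
  }
  e1 <- err_for(2000, seed = 61)
  e2 <- err_for(8000, seed = 61)
  ratio <- e1 / e2   # expect ~2
  expect_gt(ratio, 2 / 1.5)
  expect_lt(ratio, 2 * 1.5)
})

test_that("convergence check is exact at fraction 1 and bounded at fraction 0.5", {
  pmf <- make_default_pmf()
  ds <- run_schedule(pmf, 15, 3.5, config = sampler_config(seed = 3))
  drift <- suppressWarnings(convergence_check(ds, c(0.5, 1)))
  expect_identical(drift$max_drift[drift$fraction == 1], 0)
  expect_lt(drift$max_drift[drift$fraction == 0.5], 1.0)
})

test_that("half-trajectory single-window check equals Boltzmann inversion of the half", {
  set.seed(91)
  x <- 6 + abs(rnorm(4000, sd = 0.3))
  w <- umbrella_window(6, 0, 300, x)
  ds <- umbrella_dataset(list(w))
  cfg <- wham_config(bin_width = 0.05)
  half <- suppressWarnings(
    solve_wham(umbrella_dataset(list(umbrella_window(6, 0, 300,
                                                     x[1:2000]))),
               cfg, zero_region = c(6, 6.4)))
  kT <- 8.314e-3 * 300
  h <- oracle_histogram(x[1:2000], 0.05)
  Wdir <- ifelse(h$counts > 0, -kT * log(h$counts / sum(h$counts)), Inf)
  m <- match_bins(half$bin_centers, h$centers, 0.05)
  ok <- is.finite(half$W) & is.finite(Wdir[m])
  expect_lt(max_gauge_free_diff(half$W[ok], Wdir[m][ok]), 1e-9)
})

test_that("solver guards: non-convergence and fraction validation", {
  ds <- small_dataset(seed = 51, n_samples = 300)
  expect_error(
    suppressWarnings(solve_wham(ds, wham_config(max_iterations = 2),
                                zero_region = c(5.5, 7))),
    "did not converge")
  expect_error(convergence_check(ds, c(1, 0.5)), "ascending")
  expect_error(convergence_check(ds, c(0.5, 0.9)), "ending at 1")
})
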