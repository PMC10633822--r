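# Independent oracles used across the suite. These deliberately do not call
# into the package's own estimators beyond reading raw sample data.

KT300 <- 8.314e-3 * 300

# Histogram binning with the same floor-aligned edge convention as the
# package, rebuilt independently so grid alignment itself is exercised.
oracle_histogram <- function(samples, bin_width) {
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  list(edges = edges,
       centers = edges[-length(edges)] + bin_width / 2,
       counts = tabulate(idx, nbins = length(edges) - 1L))
}

# Reference WHAM by direct maximization of the WHAM log-likelihood in the
# window shifts f (BFGS), instead of self-consistent iteration.
likelihood_wham <- function(dataset, bin_width) {
  kT <- 8.314e-3 * dataset$temperature
  x <- unlist(lapply(dataset$windows, function(w) w$samples))
  h <- oracle_histogram(x, bin_width)
  counts <- vapply(dataset$windows, function(w) {
    idx <- findInterval(w$samples, h$edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = length(h$centers))
  }, integer(length(h$centers)))
  b <- vapply(dataset$windows, function(w) {
    0.5 * w$spring * 4.184 * (h$centers - w$center)^2 / kT
  }, numeric(length(h$centers)))
  N <- colSums(counts)
  M <- rowSums(counts)
  E <- exp(-b)
  negll <- function(f) {
    den <- as.vector(E %*% (N * exp(f)))
    -(sum(N * f) + sum(M[M > 0] * log(M[M > 0] / den[M > 0])))
  }
  opt <- stats::optim(numeric(length(N)), negll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  den <- as.vector(E %*% (N * exp(opt$par)))
  P <- ifelse(M > 0, M / den, 0)
  P <- P / sum(P)
  list(centers = h$centers,
       W = ifelse(P > 0, -kT * log(P), Inf),
       counts = M)
}

# Sample-based multistate reweighting (MBAR): self-consistent window free
# energies from per-sample bias energies, then bin the per-sample weights.
# No histogram discretization of the bias enters the estimator.
mbar_pmf <- function(dataset, bin_width, tol = 1e-11, maxit = 1e5) {
  kT <- 8.314e-3 * dataset$temperature
  x <- unlist(lapply(dataset$windows, function(w) w$samples))
  N <- vapply(dataset$windows, function(w) length(w$samples), integer(1))
  U <- vapply(dataset$windows, function(w) {
    0.5 * w$spring * 4.184 * (x - w$center)^2 / kT
  }, numeric(length(x)))
  E <- exp(-U)
  f <- numeric(length(N))
  for (it in seq_len(maxit)) {
    den <- as.vector(E %*% (N * exp(f)))
    f_new <- -log(as.vector(crossprod(E, 1 / den)))
    f_new <- f_new - f_new[1]
    done <- max(abs(f_new - f)) < tol
    f <- f_new
    if (done) break
  }
  wgt <- 1 / as.vector(E %*% (N * exp(f)))
  h <- oracle_histogram(x, bin_width)
  idx <- findInterval(x, h$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  P <- vapply(seq_along(h$centers),
              function(j) sum(wgt[idx == j]), numeric(1))
  P <- P / sum(P)
  list(centers = h$centers,
       W = ifelse(P > 0, -kT * log(P), Inf),
       counts = h$counts)
}

# Match two floor-aligned grids of the same bin width (centers are odd
# multiples of bin_width/2).
match_bins <- function(centers_a, centers_b, bin_width) {
  match(round(centers_a / (bin_width / 2)), round(centers_b / (bin_width / 2)))
}

# Max |a - b| after removing the free additive gauge (mean over compared bins).
max_gauge_free_diff <- function(a, b) {
  d <- a - b
  max(abs(d - mean(d)))
}

# Quadrature CDF of the biased Boltzmann density exp(-(W + bias)/kT).
biased_cdf <- function(model, center, spring_kcal, temperature, lo, hi,
                       n_grid = 40001) {
  kT <- 8.314e-3 * temperature
  k <- spring_kcal * 4.184
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- exp(-(evaluate_pmf(model, grid) +
                  0.5 * k * (grid - center)^2) / kT)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(grid, cdf, yleft = 0, yright = 1)
}

# Brute-force speciation oracle: outer bisection on the monomer M of the
# acid-balance residual, with the free-water concentration found by inner
# bisection of the water balance at each trial M.
speciation_oracle <- function(C, W_tot, K_d, K_h, a = 1, tol = 1e-12) {
  water_free <- function(M) {
    if (W_tot == 0 || is.infinite(K_h)) return(W_tot)
    g <- function(Wf) Wf + M * Wf / K_h - W_tot
    stats::uniroot(g, c(0, W_tot), tol = tol * max(W_tot, 1))$root
  }
  acid_resid <- function(M) {
    Wf <- water_free(M)
    MW <- if (is.infinite(K_h)) 0 else M * Wf / K_h
    M + a * M^2 / K_d + MW - C
  }
  if (C == 0) return(list(M = 0, D = 0, MW = 0, W_free = W_tot))
  M <- stats::uniroot(acid_resid, c(0, C), tol = tol * max(C, 1))$root
  Wf <- water_free(M)
  list(M = M, D = M^2 / K_d,
       MW = if (is.infinite(K_h)) 0 else M * Wf / K_h,
       W_free = Wf)
}

# Small umbrella dataset used by oracle-equivalence tests.
small_dataset <- function(seed, n_samples = 2000, r_start = 7, r_end = 4.5,
                          temperature = 300) {
  run_schedule(make_default_pmf(), r_start, r_end, spacing = 0.5,
               spring = 6, temperature = temperature,
               config = sampler_config(n_samples = n_samples, seed = seed))
}
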