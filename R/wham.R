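#' WHAM configuration
#'
#' Controls for the weighted histogram analysis method solver. The default
#' bin width of 0.05 A resolves the 0.8 A spacing between the closed- and
#' open-dimer minima (ten bins per 0.5 A window spacing); the convergence
#' tolerance is on the maximum change of the window free-energy shifts in
#' kT units, iterated directly (no acceleration) for auditability.
#'
#' @param bin_width histogram bin width, A.
#' @param tolerance convergence tolerance on max |change in f_i|, kT units.
#' @param max_iterations iteration cap for the self-consistent cycle.
#' @param bootstrap_replicates number of Monte Carlo bootstrap replicates.
#' @param seed integer seed for bootstrap resampling.
#' @return an object of class `wham_config`.
#' @export
wham_config <- function(bin_width = 0.05, tolerance = 1e-7,
                        max_iterations = 1e5, bootstrap_replicates = 200,
                        seed = 1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (tolerance <= 0) stop("tolerance must be positive")
  if (bootstrap_replicates < 0) stop("bootstrap_replicates must be >= 0")
  structure(list(bin_width = bin_width, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed)),
            class = "wham_config")
}

#' Binned free-energy profile
#'
#' @param bin_centers strictly increasing, uniformly spaced bin centers, A.
#' @param W free energy per bin, kJ/mol; `Inf` marks unsampled bins.
#' @param temperature temperature, K.
#' @param W_error optional per-bin standard error, kJ/mol.
#' @param zero_region optional `(r_lo, r_hi)` over which W was referenced
#'   to zero.
#' @return an object of class `pmf_profile`.
#' @export
pmf_profile <- function(bin_centers, W, temperature, W_error = NULL,
                        zero_region = NULL) {
  stopifnot(length(bin_centers) == length(W), length(bin_centers) >= 2L)
  dr <- diff(bin_centers)
  if (any(dr <= 0)) stop("bin_centers must be strictly increasing")
  if (max(dr) - min(dr) > 1e-8 * mean(dr))
    stop("bin_centers must be uniformly spaced")
  if (temperature <= 0) stop("temperature must be positive")
  if (!is.null(W_error)) stopifnot(length(W_error) == length(W))
  structure(list(bin_centers = as.numeric(bin_centers),
                 W = as.numeric(W),
                 W_error = if (is.null(W_error)) NULL else as.numeric(W_error),
                 temperature = temperature,
                 zero_region = zero_region,
                 bin_width = mean(dr)),
            class = "pmf_profile")
}

#' Rasterize a model PMF onto a uniform grid
#'
#' Convenience for ground-truth comparisons and quadrature on analytic
#' landscapes.
#'
#' @param model a [model_pmf()].
#' @param r_min,r_max grid limits, A.
#' @param bin_width grid spacing, A.
#' @param temperature temperature attached to the profile, K.
#' @return a [pmf_profile()].
#' @export
pmf_from_model <- function(model, r_min, r_max, bin_width = 0.05,
                           temperature = 300) {
  r <- seq(r_min, r_max, by = bin_width)
  pmf_profile(r, evaluate_pmf(model, r), temperature)
}

#' Reference a profile to zero over a coordinate region
#'
#' Subtracts the mean of W over the bins falling in `region`, so the mean
#' over the region is exactly zero afterwards.
#'
#' @param profile a [pmf_profile()].
#' @param region `(r_lo, r_hi)`, A.
#' @return the referenced profile.
#' @export
zero_reference <- function(profile, region) {
  stopifnot(inherits(profile, "pmf_profile"), length(region) == 2L)
  sel <- profile$bin_centers >= region[1] & profile$bin_centers <= region[2] &
    is.finite(profile$W)
  if (!any(sel))
    stop("zero_region [", region[1], ", ", region[2],
         "] contains no sampled bins; supply zero_region explicitly")
  profile$W <- profile$W - mean(profile$W[sel])
  profile$zero_region <- as.numeric(region)
  profile
}

# Shared binning: bin edges are aligned to multiples of bin_width so that
# grids built from different subsets of the same data coincide bin-by-bin.
umbrella_histograms <- function(dataset, bin_width) {
  all_min <- min(vapply(dataset$windows, function(w) min(w$samples), 0))
  all_max <- max(vapply(dataset$windows, function(w) max(w$samples), 0))
  lo <- floor(all_min / bin_width) * bin_width
  hi <- ceiling(all_max / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  nb <- length(edges) - 1L
  centers <- edges[-length(edges)] + bin_width / 2
  counts <- vapply(dataset$windows, function(w) {
    idx <- findInterval(w$samples, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = nb)
  }, integer(nb))
  list(centers = centers, edges = edges, counts = counts)
}

# Bias energies of every window at every bin center, in kT units.
bias_matrix_kT <- function(dataset, centers) {
  kT <- kT_kj(dataset$temperature)
  vapply(dataset$windows, function(w) {
    0.5 * spring_kj(w) * (centers - w$center)^2 / kT
  }, numeric(length(centers)))
}

# Core WHAM self-consistent cycle on a counts matrix (bins x windows) and a
# bias matrix in kT units. Standard pair of equations: unbiased bin
# probability from count-weighted, bias-reweighted sums over windows, and
# window shifts f_i from the normalization of each biased density.
wham_core <- function(counts, bias_kT, tolerance = 1e-7,
                      max_iterations = 1e5, f_init = NULL) {
  counts <- as.matrix(counts)
  N <- colSums(counts)
  M <- rowSums(counts)
  E <- exp(-bias_kT)                       # bins x windows
  f <- if (is.null(f_init)) numeric(ncol(counts)) else f_init
  resid <- Inf
  iter <- 0L
  P <- numeric(length(M))
  while (iter < max_iterations) {
    iter <- iter + 1L
    denom <- as.vector(E %*% (N * exp(f)))
    P <- ifelse(M > 0, M / denom, 0)
    P <- P / sum(P)
    f_new <- -log(as.vector(crossprod(E, P)))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tolerance) break
  }
  list(P = P, f = f, iterations = iter, residual = resid,
       converged = resid < tolerance)
}

#' Solve WHAM for an umbrella dataset
#'
#' Reconstructs the unbiased free-energy profile W(r) = -kT ln P(r) from the
#' biased window histograms by iterating the WHAM equations to
#' self-consistency, then references the profile to zero over the bulk
#' plateau (default `zero_region = c(10, r_max)`, where the profile is
#' essentially constant). Bins with zero aggregate counts are flagged with
#' `W = Inf` and never interpolated; a warning is raised if such bins lie
#' strictly inside the sampled range.
#'
#' @param dataset an [umbrella_dataset()].
#' @param config a [wham_config()].
#' @param zero_region `(r_lo, r_hi)` for the zero reference; default
#'   `c(10, max(bin centers))`.
#' @return a [pmf_profile()] with attributes `iterations` and `residual`.
#' @export
solve_wham <- function(dataset, config = wham_config(), zero_region = NULL) {
  stopifnot(inherits(dataset, "umbrella_dataset"),
            inherits(config, "wham_config"))
  h <- umbrella_histograms(dataset, config$bin_width)
  b <- bias_matrix_kT(dataset, h$centers)
  sol <- wham_core(h$counts, b, config$tolerance, config$max_iterations)
  if (!sol$converged)
    stop(sprintf(
      "WHAM did not converge in %d iterations (final residual %.3g kT)",
      config$max_iterations, sol$residual))
  prof <- profile_from_counts(sol$P, h, dataset$temperature, zero_region)
  attr(prof, "iterations") <- sol$iterations
  attr(prof, "residual") <- sol$residual
  attr(prof, "f") <- sol$f
  prof
}

profile_from_counts <- function(P, h, temperature, zero_region,
                                warn_empty = TRUE) {
  kT <- kT_kj(temperature)
  W <- ifelse(P > 0, -kT * log(P), Inf)
  sampled <- which(is.finite(W))
  if (warn_empty && length(sampled) > 1L) {
    interior_empty <- which(!is.finite(W))
    interior_empty <- interior_empty[interior_empty > min(sampled) &
                                       interior_empty < max(sampled)]
    if (length(interior_empty) > 0L)
      warning(length(interior_empty),
              " empty bin(s) inside the sampled range; flagged as Inf")
  }
  if (is.null(zero_region)) zero_region <- c(10, max(h$centers))
  prof <- pmf_profile(h$centers, W, temperature)
  zero_reference(prof, zero_region)
}

#' Histogram overlap between neighboring windows
#'
#' For each adjacent pair of windows (sorted by center) the overlap is the
#' summed bin-wise minimum of the two normalized histograms, a number in
#' [0, 1]: 1 for identical sample distributions, 0 for disjoint ones. Good
#' overlap between neighbors is the standard diagnostic that the window
#' ladder is dense enough for WHAM.
#'
#' @param dataset an [umbrella_dataset()].
#' @param config a [wham_config()] (its `bin_width` is used).
#' @return data.frame with columns `center_1`, `center_2`, `overlap`.
#' @export
overlap_matrix <- function(dataset, config = wham_config()) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (length(dataset$windows) < 2L) stop("need at least two windows")
  h <- umbrella_histograms(dataset, config$bin_width)
  centers <- vapply(dataset$windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  res <- data.frame(center_1 = numeric(0), center_2 = numeric(0),
                    overlap = numeric(0))
  for (k in seq_len(length(ord) - 1L)) {
    i <- ord[k]; j <- ord[k + 1L]
    hi <- h$counts[, i] / sum(h$counts[, i])
    hj <- h$counts[, j] / sum(h$counts[, j])
    res[k, ] <- c(centers[i], centers[j], sum(pmin(hi, hj)))
  }
  res
}

#' Monte Carlo bootstrap uncertainty of the WHAM profile
#'
#' For each replicate the histogram counts of every window are re-drawn from
#' a multinomial with that window's sample size and empirical bin
#' probabilities, WHAM is re-solved (warm-started from the full-data
#' solution), and the per-bin standard deviation of the referenced profiles
#' across replicates is reported as `W_error`. Resampling histogram counts
#' rather than the raw time series is appropriate because stored samples
#' are decorrelated by construction (coarse storage stride).
#'
#' @param dataset an [umbrella_dataset()].
#' @param config a [wham_config()]; needs `bootstrap_replicates >= 2`.
#' @param zero_region as in [solve_wham()].
#' @return the full-data [pmf_profile()] with `W_error` filled; attribute
#'   `failed_replicates` counts replicates dropped for non-convergence.
#' @export
bootstrap_error <- function(dataset, config = wham_config(),
                            zero_region = NULL) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (config$bootstrap_replicates < 2L)
    stop("bootstrap_replicates must be at least 2")
  h <- umbrella_histograms(dataset, config$bin_width)
  b <- bias_matrix_kT(dataset, h$centers)
  base <- wham_core(h$counts, b, config$tolerance, config$max_iterations)
  if (!base$converged)
    stop(sprintf("WHAM did not converge (residual %.3g kT)", base$residual))
  prof <- profile_from_counts(base$P, h, dataset$temperature, zero_region)
  N <- colSums(h$counts)
  phat <- sweep(h$counts, 2, N, "/")
  set.seed(config$seed)
  reps <- matrix(NA_real_, nrow = length(h$centers),
                 ncol = config$bootstrap_replicates)
  failed <- 0L
  for (rpl in seq_len(config$bootstrap_replicates)) {
    cb <- vapply(seq_along(N),
                 function(i) as.vector(rmultinom(1, N[i], phat[, i])),
                 numeric(length(h$centers)))
    sol <- wham_core(cb, b, config$tolerance, config$max_iterations,
                     f_init = base$f)
    if (!sol$converged) { failed <- failed + 1L; next }
    pr <- suppressWarnings(
      profile_from_counts(sol$P, h, dataset$temperature,
                          prof$zero_region, warn_empty = FALSE))
    reps[, rpl] <- ifelse(is.finite(pr$W), pr$W, NA_real_)
  }
  prof$W_error <- apply(reps, 1, stats::sd, na.rm = TRUE)
  prof$W_error[!is.finite(prof$W)] <- NA_real_
  attr(prof, "failed_replicates") <- failed
  attr(prof, "f") <- base$f
  prof
}

#' Statistical convergence check by trajectory truncation
#'
#' Re-solves WHAM using only the leading fraction of every window's samples
#' and reports the maximum absolute drift of the referenced profile relative
#' to the full-data solution, over bins sampled in both. Bins holding fewer
#' than `min_count` aggregate counts in the truncated data are excluded:
#' the per-bin statistical floor is roughly \eqn{k_B T/\sqrt{n}}, so below
#' about 25 counts the apparent drift reflects shot noise rather than
#' convergence of the profile.
#'
#' @param dataset an [umbrella_dataset()].
#' @param fractions ascending fractions in (0, 1]; the last must be 1.
#' @param config a [wham_config()].
#' @param zero_region as in [solve_wham()].
#' @param min_count minimum aggregate counts for a bin to enter the drift.
#' @return data.frame with columns `fraction` and `max_drift` (kJ/mol).
#' @export
convergence_check <- function(dataset, fractions = c(0.5, 1),
                              config = wham_config(), zero_region = NULL,
                              min_count = 25) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (is.unsorted(fractions, strictly = TRUE) ||
      any(fractions <= 0) || abs(fractions[length(fractions)] - 1) > 1e-12)
    stop("fractions must be strictly ascending in (0, 1] ending at 1")
  full <- solve_wham(dataset, config, zero_region)
  drift <- numeric(length(fractions))
  for (k in seq_along(fractions)) {
    fr <- fractions[k]
    if (fr == 1) { drift[k] <- 0; next }
    wins <- lapply(dataset$windows, function(w) {
      n <- max(1L, as.integer(ceiling(fr * length(w$samples))))
      umbrella_window(w$center, w$spring, w$temperature,
                      w$samples[seq_len(n)], w$sample_interval)
    })
    part_ds <- umbrella_dataset(wins, dataset$coordinate_label)
    part <- solve_wham(part_ds, config, full$zero_region)
    hp <- umbrella_histograms(part_ds, config$bin_width)
    # centers are odd multiples of bin_width/2; match on that integer grid
    common_full <- match(round(part$bin_centers / (config$bin_width / 2)),
                         round(full$bin_centers / (config$bin_width / 2)))
    ok <- !is.na(common_full) & is.finite(part$W) &
      rowSums(hp$counts) >= min_count
    ok[ok] <- is.finite(full$W[common_full[ok]])
    drift[k] <- max(abs(part$W[ok] - full$W[common_full[ok]]))
  }
  data.frame(fraction = fractions, max_drift = drift)
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$W)
  cat("PMF profile:", length(x$bin_centers), "bins of",
      format(x$bin_width), "A at", format(x$temperature), "K; W in [",
      format(min(x$W[fin]), digits = 4), ",",
      format(max(x$W[fin]), digits = 4), "] kJ/mol\n")
  if (!is.null(x$zero_region))
    cat("  zero-referenced over [", x$zero_region[1], ",",
        x$zero_region[2], "] A\n")
  invisible(x)
}
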