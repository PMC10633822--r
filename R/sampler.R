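#' Sampler configuration
#'
#' Controls for the Metropolis Monte Carlo sampler that emulates one biased
#' umbrella window. Defaults emulate a 2 ns window stored every 0.1 ps:
#' 20,000 stored samples per window. `thin` sets how many Metropolis steps
#' separate consecutive stored samples so that stored configurations are
#' effectively decorrelated, matching the statistical structure of snapshots
#' saved on a coarse stride from molecular dynamics.
#'
#' @param n_samples number of stored samples per window.
#' @param n_equilibration stored-sample equivalents discarded before
#'   recording (burn-in).
#' @param proposal_step half-width of the uniform random-walk proposal, A.
#' @param thin Metropolis steps between stored samples.
#' @param seed integer seed; identical seed and inputs give an identical
#'   sample stream.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 20000, n_equilibration = 1000,
                           proposal_step = 0.5, thin = 20, seed = 42) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (n_equilibration < 0) stop("n_equilibration must be non-negative")
  if (proposal_step <= 0) stop("proposal_step must be positive")
  if (thin <= 0) stop("thin must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 n_equilibration = as.integer(n_equilibration),
                 proposal_step = proposal_step,
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Construct an umbrella window
#'
#' @param center restraint center, A.
#' @param spring harmonic spring constant in kcal/(mol A^2), the
#'   conventional input unit for umbrella restraints; converted to
#'   kJ/(mol A^2) internally where bias energies are computed.
#' @param temperature temperature, K.
#' @param samples numeric vector of coordinate samples, A.
#' @param sample_interval storage interval in ps (metadata only).
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring, temperature, samples,
                            sample_interval = 0.1) {
  if (spring < 0) stop("spring constant must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  if (length(samples) == 0L) stop("samples must be nonempty")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("samples must be finite positive separations")
  structure(list(center = center, spring = spring,
                 temperature = temperature,
                 samples = as.numeric(samples),
                 sample_interval = sample_interval),
            class = "umbrella_window")
}

spring_kj <- function(window) window$spring * .KCAL_TO_KJ

#' Sample one biased umbrella window
#'
#' Draws coordinate samples distributed proportional to
#' \eqn{\exp(-[W(r) + \frac{1}{2} k (r - c)^2]/k_B T)} by Metropolis Monte
#' Carlo along the scalar coordinate. The coordinate is sampled without a
#' geometric \eqn{r^2} weight: W(r) is by definition the PMF that WHAM
#' reconstructs, and the \eqn{4\pi r^2} volume element enters only when the
#' bound well is integrated into an association free energy (see
#' [integrate_association()]).
#'
#' @param model a [model_pmf()].
#' @param center restraint center, A.
#' @param spring spring constant, kcal/(mol A^2) (e.g. 6).
#' @param temperature temperature, K.
#' @param config a [sampler_config()].
#' @return an `umbrella_window`.
#' @export
sample_window <- function(model, center, spring = 6, temperature = 300,
                          config = sampler_config()) {
  stopifnot(inherits(model, "model_pmf"), inherits(config, "sampler_config"))
  if (spring <= 0) stop("spring constant must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  beta <- 1 / kT_kj(temperature)
  k_kj <- spring * .KCAL_TO_KJ
  set.seed(config$seed)
  x <- metropolis_window(config$n_samples, config$n_equilibration,
                         config$thin, center, config$proposal_step, beta,
                         k_kj, center,
                         model$wells$center, model$wells$depth,
                         model$wells$width,
                         model$wall_position, model$wall_steepness)
  umbrella_window(center = center, spring = spring,
                  temperature = temperature, samples = x)
}

#' Construct an umbrella dataset
#'
#' A set of biased windows at one temperature along one reaction coordinate.
#'
#' @param windows list of [umbrella_window()] objects; centers must be
#'   distinct. Windows are stored sorted by decreasing center.
#' @param coordinate_label text label for the coordinate.
#' @return an object of class `umbrella_dataset`.
#' @export
umbrella_dataset <- function(windows,
                             coordinate_label = "headgroup separation (A)") {
  if (length(windows) == 0L) stop("at least one window is required")
  if (!all(vapply(windows, inherits, logical(1), "umbrella_window")))
    stop("windows must be umbrella_window objects")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (length(unique(temps)) != 1L)
    stop("all windows must share one temperature; mixed-T datasets are not supported")
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (anyDuplicated(centers)) stop("window centers must be distinct")
  windows <- windows[order(centers, decreasing = TRUE)]
  structure(list(windows = windows, temperature = temps[1],
                 coordinate_label = coordinate_label),
            class = "umbrella_dataset")
}

#' Run an umbrella-sampling schedule
#'
#' Generates windows at centers `r_start, r_start - spacing, ..., >= r_end`
#' (pulling the pair together from the bulk), each sampled with
#' [sample_window()] under a per-window seed `config$seed + window index - 1`
#' so windows are decorrelated but the whole schedule is reproducible.
#' Defaults follow the standard protocol: 0.5 A spacing, 6 kcal/(mol A^2)
#' bias, 20,000 stored samples per window.
#'
#' @param model a [model_pmf()].
#' @param r_start,r_end first and last restraint centers, A
#'   (`r_start > r_end > 0`).
#' @param spacing window spacing, A.
#' @param spring spring constant, kcal/(mol A^2).
#' @param temperature temperature, K.
#' @param config a [sampler_config()].
#' @return an `umbrella_dataset`.
#' @export
#' @examples
#' cfg <- sampler_config(n_samples = 500, seed = 1)
#' ds <- run_schedule(make_default_pmf(), 15, 3.5, config = cfg)
#' length(ds$windows)
run_schedule <- function(model, r_start = 15, r_end = 3.5, spacing = 0.5,
                         spring = 6, temperature = 300,
                         config = sampler_config()) {
  if (!(r_start > r_end && r_end > 0)) stop("need r_start > r_end > 0")
  if (spacing <= 0) stop("spacing must be positive")
  centers <- seq(r_start, r_end, by = -spacing)
  if (length(centers) == 0L) stop("schedule is empty")
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    windows[[i]] <- sample_window(model, centers[i], spring, temperature, cfg)
  }
  umbrella_dataset(windows)
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  centers <- vapply(x$windows, `[[`, numeric(1), "center")
  n <- vapply(x$windows, function(w) length(w$samples), integer(1))
  cat("Umbrella dataset:", length(x$windows), "windows at",
      format(x$temperature), "K,",
      "centers", format(max(centers)), "to", format(min(centers)), "A,",
      sum(n), "samples total\n")
  invisible(x)
}
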