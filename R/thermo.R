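#' Locate local minima of a free-energy profile
#'
#' Finds discrete local minima of W(r) and refines each position with a
#' three-point quadratic (parabolic vertex through the minimum bin and its
#' neighbors). Minima shallower than `depth_threshold` relative to the
#' lower of the two flanking maxima (the prominence) are suppressed as
#' noise.
#'
#' @param pmf a [pmf_profile()] with at least 3 finite bins.
#' @param depth_threshold minimum prominence in kJ/mol.
#' @return data.frame with columns `r` (A) and `W` (kJ/mol), sorted by `r`.
#' @export
find_minima <- function(pmf, depth_threshold = 0.5) {
  stopifnot(inherits(pmf, "pmf_profile"))
  W <- pmf$W
  r <- pmf$bin_centers
  fin <- which(is.finite(W))
  if (length(fin) < 3L) stop("need at least 3 finite bins")
  # work on the contiguous finite stretch containing most bins
  W <- W[fin]; r <- r[fin]
  n <- length(W)
  cand <- which(W[2:(n - 1)] < W[1:(n - 2)] &
                  W[2:(n - 1)] <= W[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    left_max <- max(W[1:i])
    right_max <- max(W[i:n])
    keep[k] <- min(left_max, right_max) - W[i] >= depth_threshold
  }
  cand <- cand[keep]
  if (length(cand) == 0L) stop("no local minima found")
  out <- data.frame(r = numeric(length(cand)), W = numeric(length(cand)))
  h <- pmf$bin_width
  for (k in seq_along(cand)) {
    i <- cand[k]
    wm <- W[i - 1L]; w0 <- W[i]; wp <- W[i + 1L]
    denom <- wm - 2 * w0 + wp
    if (denom > 0) {
      delta <- 0.5 * (wm - wp) / denom
      out$r[k] <- r[i] + delta * h
      out$W[k] <- w0 - 0.125 * (wm - wp)^2 / denom
    } else {
      out$r[k] <- r[i]
      out$W[k] <- w0
    }
  }
  out[order(out$r), , drop = FALSE]
}

# Trapezoidal bound-state configurational integral
#   Q = int_{r0}^{r1} 4 pi r^2 exp(-W(r)/kT) dr     (A^3)
# on the profile's native bin grid; endpoints enter as extra nodes with W
# linearly interpolated between the flanking bins.
well_integral <- function(pmf, r0, r1, temperature, include_jacobian = TRUE) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (!(r0 < r1)) stop("need r0 < r1")
  r <- pmf$bin_centers
  W <- pmf$W
  if (r0 < min(r) - pmf$bin_width / 2 || r1 > max(r) + pmf$bin_width / 2)
    stop("integration limits outside the profile's support")
  inside <- r > r0 & r < r1
  sel <- which(inside)
  span <- which(r >= r0 - pmf$bin_width & r <= r1 + pmf$bin_width)
  if (any(!is.finite(W[span])))
    stop("integration window overlaps unsampled (Inf) bins")
  w_end <- stats::approx(r, W, xout = c(r0, r1), rule = 2)$y
  nodes <- c(r0, r[sel], r1)
  vals <- c(w_end[1], W[sel], w_end[2])
  kT <- kT_kj(temperature)
  g <- exp(-vals / kT)
  if (include_jacobian) g <- 4 * pi * nodes^2 * g
  sum(diff(nodes) * (g[-1] + g[-length(g)]) / 2)
}

#' Dissociation constant from a dissociation free energy
#'
#' \eqn{K_d = c^\circ \exp(-\Delta_d G / RT)}, reported in mM, with
#' \eqn{R = 8.314} J/(mol K) and standard concentration `c0` in mol/L.
#'
#' @param dG_d dissociation free energy, kJ/mol.
#' @param temperature temperature, K.
#' @param c0 standard concentration, mol/L (default 1 M).
#' @return K_d in mM.
#' @export
#' @examples
#' kd_from_dG(20.71, 300)  # ~0.25 mM
kd_from_dG <- function(dG_d, temperature, c0 = 1) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  1000 * c0 * exp(-dG_d * 1000 / (.R_GAS_J * temperature))
}

#' Dissociation free energy from a dissociation constant
#'
#' Inverse of [kd_from_dG()].
#'
#' @param K_d dissociation constant, mM.
#' @param temperature temperature, K.
#' @param c0 standard concentration, mol/L.
#' @return dissociation free energy, kJ/mol.
#' @export
dG_from_kd <- function(K_d, temperature, c0 = 1) {
  if (any(K_d <= 0)) stop("K_d must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  -.R_GAS_J * temperature * log(K_d / (1000 * c0)) / 1000
}

#' Integrate a PMF well into an association free energy
#'
#' Computes the bound-state configurational integral
#' \deqn{Q = \int_{r_0}^{r_1} 4\pi r^2 e^{-W(r)/k_B T}\,dr}
#' by composite trapezoidal quadrature on the profile's bin grid, then the
#' association free energy \eqn{\Delta_a G = -k_B T \ln(Q/V_{ref})} and the
#' dissociation free energy \eqn{\Delta_d G = -\Delta_a G}. Under the
#' `"molar_1M"` convention \eqn{V_{ref} = 1/(c^\circ N_A)} (1660.5 A^3 at
#' 1 M) and K_d in mM satisfies the exact round trip
#' `K_d = kd_from_dG(dG_d, T)`; under `"solvent_mole_fraction"` the
#' reference volume is the solvent molecular volume `v_s` (see
#' [solvent_molar_volume()]) and the attached constant `K_x` is on the
#' solvent mole-fraction scale. The default well limits r0 = 3.9 A and
#' r1 = 5.3 A bracket the closed- plus open-dimer well of the acid-acid
#' profile.
#'
#' @param pmf a [pmf_profile()].
#' @param r0,r1 lower and upper well limits, A.
#' @param temperature temperature, K; defaults to the profile temperature
#'   and must match it when both are given.
#' @param standard_state `"molar_1M"` or `"solvent_mole_fraction"`.
#' @param v_s solvent molecular volume, A^3 (required for the
#'   mole-fraction convention).
#' @param c0 standard concentration, mol/L, for the molar convention.
#' @param include_jacobian include the \eqn{4\pi r^2} volume element
#'   (default TRUE). With FALSE the integral is one-dimensional (A) and the
#'   reference volume is interpreted as a length.
#' @return an object of class `association_result`: a list with fields
#'   `temperature`, `dG_dissociation` (kJ/mol), `K_d` (mM, molar convention)
#'   or `K_x` (mole-fraction convention), `Q` (A^3), `r0`, `r1`,
#'   `standard_state`, `v_s`.
#' @export
integrate_association <- function(pmf, r0 = 3.9, r1 = 5.3,
                                  temperature = NULL,
                                  standard_state = c("molar_1M",
                                                     "solvent_mole_fraction"),
                                  v_s = NULL, c0 = 1,
                                  include_jacobian = TRUE) {
  standard_state <- match.arg(standard_state)
  if (is.null(temperature)) temperature <- pmf$temperature
  if (abs(temperature - pmf$temperature) > 1e-9)
    stop("temperature does not match the profile temperature")
  Q <- well_integral(pmf, r0, r1, temperature, include_jacobian)
  kT <- kT_kj(temperature)
  if (standard_state == "molar_1M") {
    v_ref <- .VREF_1M / c0
  } else {
    if (is.null(v_s) || v_s <= 0)
      stop("v_s (solvent molecular volume, A^3) is required for the ",
           "solvent_mole_fraction convention")
    v_ref <- v_s
  }
  dG_a <- -kT * log(Q / v_ref)
  dG_d <- -dG_a
  res <- list(temperature = temperature, dG_dissociation = dG_d,
              Q = Q, r0 = r0, r1 = r1, standard_state = standard_state,
              v_s = v_s)
  if (standard_state == "molar_1M") {
    res$K_d <- kd_from_dG(dG_d, temperature, c0)
  } else {
    res$K_x <- exp(-dG_d * 1000 / (.R_GAS_J * temperature))
  }
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Association over [%.2f, %.2f] A at %g K (%s):\n",
              x$r0, x$r1, x$temperature, x$standard_state))
  cat(sprintf("  dG_dissociation = %.3f kJ/mol", x$dG_dissociation))
  if (!is.null(x$K_d)) cat(sprintf(", K_d = %.4g mM", x$K_d))
  if (!is.null(x$K_x)) cat(sprintf(", K_x = %.4g", x$K_x))
  cat("\n")
  invisible(x)
}

#' Fit the integrated Van't Hoff equation to K(T) data
#'
#' Assuming a temperature-independent dissociation enthalpy, ln K is linear
#' in 1/T:
#' \deqn{K(T) = K_{0} \exp\!\left[-\frac{\Delta_d H}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_0}\right)\right].}
#' The default fit regresses ln K on 1/T and takes
#' \eqn{\Delta_d H = -R \cdot \mathrm{slope}}. The reference-temperature
#' constant K_d0 is, by default, obtained by extrapolating the data point
#' nearest T0 with the fitted enthalpy
#' (`K_d0_method = "extrapolate_from_nearest_T"`); the regression intercept
#' evaluated at T0 is available as `"regression_intercept"`. A
#' `"global_nonlinear"` fit (least squares in K space, started from the
#' log-linear fit) is provided for heteroscedastic data.
#'
#' @param temperature temperatures, K (>= 2 distinct values).
#' @param K_d dissociation constants, mM (positive).
#' @param T0 reference temperature, K (default 298, i.e. 25 C).
#' @param fit_method `"lnK_regression"` or `"global_nonlinear"`.
#' @param K_d0_method `"extrapolate_from_nearest_T"` or
#'   `"regression_intercept"`.
#' @return an object of class `vant_hoff_fit` with fields `K_d0` (mM),
#'   `T0`, `dH` (kJ/mol), `fit_method`, `K_d0_method`, `residuals`
#'   (ln-space, one per point), `data`.
#' @export
#' @examples
#' fit <- vant_hoff_fit(c(300, 323, 345), c(0.249, 0.705, 1.741))
#' fit$dH    # ~37 kJ/mol
#' fit$K_d0  # ~0.23 mM
vant_hoff_fit <- function(temperature, K_d, T0 = 298,
                          fit_method = c("lnK_regression",
                                         "global_nonlinear"),
                          K_d0_method = c("extrapolate_from_nearest_T",
                                          "regression_intercept")) {
  fit_method <- match.arg(fit_method)
  K_d0_method <- match.arg(K_d0_method)
  if (length(temperature) != length(K_d) || length(K_d) < 2L)
    stop("need at least two (T, K_d) points")
  if (anyDuplicated(temperature)) stop("temperatures must be distinct")
  if (any(K_d <= 0)) stop("K_d values must be positive")
  if (any(temperature <= 0) || T0 <= 0) stop("temperatures must be positive")
  x <- 1 / temperature
  y <- log(K_d)
  ls <- stats::lm(y ~ x)
  slope <- unname(stats::coef(ls)[2])
  intercept <- unname(stats::coef(ls)[1])
  dH <- -.R_GAS_J * slope / 1000  # kJ/mol
  if (fit_method == "global_nonlinear") {
    # least squares in K space, parameterized (ln K0, dH), started from the
    # log-linear fit; optim rather than nls so noiseless data converge too
    obj <- function(p) {
      sum((K_d - exp(p[1]) * exp(-(p[2] * 1000 / .R_GAS_J) *
                                   (1 / temperature - 1 / T0)))^2)
    }
    opt <- stats::optim(c(intercept + slope / T0, dH), obj,
                        method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 1000))
    dH <- opt$par[2]
    K_d0 <- exp(opt$par[1])
    if (K_d0_method == "extrapolate_from_nearest_T")
      K_d0 <- .extrapolate_nearest(temperature, K_d, T0, dH)
  } else if (K_d0_method == "extrapolate_from_nearest_T") {
    K_d0 <- .extrapolate_nearest(temperature, K_d, T0, dH)
  } else {
    K_d0 <- exp(intercept + slope / T0)
  }
  pred <- log(temperature_adjust(K_d0, T0, dH, temperature))
  structure(list(K_d0 = K_d0, T0 = T0, dH = dH,
                 fit_method = fit_method, K_d0_method = K_d0_method,
                 residuals = y - pred,
                 data = data.frame(temperature = temperature, K_d = K_d)),
            class = "vant_hoff_fit")
}

.extrapolate_nearest <- function(temperature, K_d, T0, dH) {
  i <- which.min(abs(temperature - T0))
  temperature_adjust(K_d[i], temperature[i], dH, T0)
}

#' Predict K_d(T) from a Van't Hoff fit
#'
#' @param object a `vant_hoff_fit`.
#' @param temperature temperatures, K.
#' @param ... unused.
#' @return predicted K_d in mM.
#' @export
predict.vant_hoff_fit <- function(object, temperature, ...) {
  temperature_adjust(object$K_d0, object$T0, object$dH, temperature)
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "Van't Hoff fit (%s, K_d0 by %s):\n  dH = %.2f kJ/mol, K_d0 = %.4g mM at T0 = %g K\n",
    x$fit_method, x$K_d0_method, x$dH, x$K_d0, x$T0))
  cat("  ln-space residuals:", format(x$residuals, digits = 3), "\n")
  invisible(x)
}

#' Open/closed dimer decomposition of a bound well
#'
#' Splits the bound-state configurational integral at `boundary` (typically
#' the barrier between the closed- and open-dimer minima, about 4.2 A) and
#' returns the Boltzmann-weighted fractions of the two sub-wells, which sum
#' to 1 exactly.
#'
#' @param pmf a [pmf_profile()].
#' @param boundary split point, A, with `r0 < boundary < r1`.
#' @param r0,r1 well limits, A.
#' @param temperature temperature, K (default: profile temperature).
#' @return list with `fraction_closed` (`[r0, boundary]`) and
#'   `fraction_open` (`[boundary, r1]`).
#' @export
open_closed_decomposition <- function(pmf, boundary, r0 = 3.9, r1 = 5.3,
                                      temperature = NULL) {
  if (is.null(temperature)) temperature <- pmf$temperature
  if (!(r0 < boundary && boundary < r1))
    stop("boundary must lie strictly inside [r0, r1]")
  Qc <- well_integral(pmf, r0, boundary, temperature)
  Qo <- well_integral(pmf, boundary, r1, temperature)
  list(fraction_closed = Qc / (Qc + Qo),
       fraction_open = Qo / (Qc + Qo))
}

#' Free-energy contribution of a secondary minimum
#'
#' Quantifies how much a detached secondary minimum (e.g. a long-range
#' interaction well) adds to the dissociation free energy: the relative
#' change, in percent, of \eqn{\Delta_d G} when the bound state is extended
#' from the primary well alone to the union of primary and secondary
#' ranges.
#'
#' @param pmf a [pmf_profile()].
#' @param primary_range,secondary_range disjoint, ordered `(lo, hi)`
#'   ranges in A (`primary_range[2] <= secondary_range[1]`).
#' @param temperature temperature, K (default: profile temperature).
#' @param standard_state,v_s,c0 as in [integrate_association()].
#' @return relative increase of the dissociation free energy, percent.
#' @export
secondary_minimum_contribution <- function(pmf, primary_range,
                                           secondary_range,
                                           temperature = NULL,
                                           standard_state = "molar_1M",
                                           v_s = NULL, c0 = 1) {
  if (is.null(temperature)) temperature <- pmf$temperature
  stopifnot(length(primary_range) == 2L, length(secondary_range) == 2L)
  if (!(primary_range[1] < primary_range[2] &&
        secondary_range[1] < secondary_range[2]))
    stop("ranges must be ordered (lo, hi)")
  if (primary_range[2] > secondary_range[1])
    stop("primary and secondary ranges must be disjoint and ordered")
  prim <- integrate_association(pmf, primary_range[1], primary_range[2],
                                temperature, standard_state, v_s, c0)
  Qs <- well_integral(pmf, secondary_range[1], secondary_range[2],
                      temperature)
  kT <- kT_kj(temperature)
  dG_union <- prim$dG_dissociation + kT * log1p(Qs / prim$Q)
  100 * (dG_union - prim$dG_dissociation) / prim$dG_dissociation
}

#' Solvent molecular volume from bulk density
#'
#' \eqn{v_s = M / (\rho N_A)}, converted to cubic Angstrom per molecule.
#'
#' @param density bulk density, g/L.
#' @param molar_mass molar mass, g/mol.
#' @return molecular volume in A^3.
#' @export
#' @examples
#' solvent_molar_volume(814, 84.16)  # cyclohexane, ~172 A^3
solvent_molar_volume <- function(density, molar_mass) {
  if (density <= 0 || molar_mass <= 0)
    stop("density and molar_mass must be positive")
  molar_mass / (density * .N_AVOGADRO) * 1e27
}
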