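#' Equilibrium constants for the coupled acid/water system
#'
#' @param K_d dimer dissociation constant, mM (`D <-> 2M` written as
#'   dissociation, `K_d = M^2/D`).
#' @param K_h hydrate (acid-water complex) heterodissociation constant, mM
#'   (`MW <-> M + W`, `K_h = M W_free / MW`); may be `Inf` for a dry system.
#' @param temperature temperature, K.
#' @return an object of class `equilibrium_constants`.
#' @export
equilibrium_constants <- function(K_d, K_h = Inf, temperature = 298) {
  if (K_d <= 0) stop("K_d must be positive")
  if (K_h <= 0) stop("K_h must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(K_d = K_d, K_h = K_h, temperature = temperature),
            class = "equilibrium_constants")
}

#' Monomer concentration from the total acid concentration
#'
#' Closed-form positive root of the quadratic implied by \eqn{K_d = M^2/D}
#' together with the acid mass balance. Two balance conventions are
#' offered: `"C_eq_M_plus_D"` counts the dimer once in the balance
#' (C = M + D), giving
#' \deqn{M = \frac{K_d}{2}\left(\sqrt{1 + 4C/K_d} - 1\right),}
#' while `"C_eq_M_plus_2D"` uses the stoichiometric
#' monomer-unit balance C = M + 2D, giving
#' \deqn{M = \frac{K_d}{4}\left(\sqrt{1 + 8C/K_d} - 1\right).}
#' The first is the convention in which the literature mass-balance formula
#' is usually quoted for dilute acids and is the default; both agree in the
#' dilute limit C << K_d.
#'
#' @param C total acid concentration, mM (vectorized).
#' @param K_d dimer dissociation constant, mM.
#' @param convention mass-balance convention, see Details.
#' @return monomer concentration M, mM.
#' @export
#' @examples
#' monomer_concentration(1, K_d = 1)  # (sqrt(5)-1)/2
monomer_concentration <- function(C, K_d,
                                  convention = c("C_eq_M_plus_D",
                                                 "C_eq_M_plus_2D")) {
  convention <- match.arg(convention)
  if (any(C < 0)) stop("C must be non-negative")
  if (K_d <= 0) stop("K_d must be positive")
  if (convention == "C_eq_M_plus_D") {
    K_d * (sqrt(1 + 4 * C / K_d) - 1) / 2
  } else {
    K_d * (sqrt(1 + 8 * C / K_d) - 1) / 4
  }
}

#' Solve the coupled monomer/dimer/hydrate speciation equilibria
#'
#' Solves the system
#' \deqn{K_d = M^2/D, \quad K_h = M\,W_{free}/MW,}
#' together with the acid balance (C = M + D + MW or C = M + 2D + MW,
#' depending on the convention) and the water balance
#' (W_total = W_free + MW), by damped Newton iteration on the acid residual
#' in M, with the water balance eliminated exactly
#' (\eqn{W_{free} = W_{total}/(1 + M/K_h)}). The initial guess is the
#' water-free closed form; steps that would drive M non-positive are damped
#' by a factor 0.5.
#'
#' @param C_total total acid concentration, mM.
#' @param W_total total water concentration, mM.
#' @param constants an [equilibrium_constants()].
#' @param convention acid mass-balance convention, as in
#'   [monomer_concentration()].
#' @param tol residual tolerance (relative to the totals).
#' @param max_iterations Newton iteration cap.
#' @return an object of class `speciation_state`: list with concentrations
#'   `M`, `D`, `MW`, `W_free` (mM), the inputs `C_total`, `W_total`, and
#'   the `convention`.
#' @export
solve_speciation <- function(C_total, W_total, constants,
                             convention = c("C_eq_M_plus_D",
                                            "C_eq_M_plus_2D"),
                             tol = 1e-10, max_iterations = 200) {
  convention <- match.arg(convention)
  stopifnot(inherits(constants, "equilibrium_constants"))
  if (C_total < 0 || W_total < 0) stop("totals must be non-negative")
  K_d <- constants$K_d
  K_h <- constants$K_h
  a <- if (convention == "C_eq_M_plus_D") 1 else 2
  mk_state <- function(M) {
    W_free <- if (is.infinite(K_h)) W_total else W_total / (1 + M / K_h)
    MW <- if (is.infinite(K_h)) 0 else M * W_free / K_h
    structure(list(M = M, D = M^2 / K_d, MW = MW, W_free = W_free,
                   C_total = C_total, W_total = W_total,
                   convention = convention),
              class = "speciation_state")
  }
  if (C_total == 0) return(mk_state(0))
  # acid residual in M with the water balance eliminated exactly
  g <- function(M) {
    hyd <- if (is.infinite(K_h)) 0 else M * W_total / (K_h + M)
    M + a * M^2 / K_d + hyd - C_total
  }
  gp <- function(M) {
    hyd <- if (is.infinite(K_h)) 0 else W_total * K_h / (K_h + M)^2
    1 + 2 * a * M / K_d + hyd
  }
  M <- monomer_concentration(C_total, K_d, convention)
  scale <- max(C_total, W_total)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    res <- g(M)
    if (abs(res) <= tol * scale) { converged <- TRUE; break }
    step <- res / gp(M)
    while (M - step <= 0) step <- step * 0.5  # damp on negativity violations
    M <- M - step
  }
  if (!converged && abs(g(M)) > tol * scale)
    stop(sprintf("speciation solver did not converge (residual %.3g mM)",
                 g(M)))
  mk_state(M)
}

#' Adjust an equilibrium constant to another temperature
#'
#' Integrated Van't Hoff relation with a temperature-independent enthalpy:
#' \deqn{K(T) = K_0 \exp\!\left[-\frac{\Delta_d H}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_0}\right)\right].}
#'
#' @param K0 constant at the reference temperature, mM.
#' @param T0 reference temperature, K (25 C = 298 K conventionally).
#' @param dH dissociation enthalpy, kJ/mol.
#' @param temperature target temperature(s), K.
#' @return K at `temperature`, mM.
#' @export
#' @examples
#' temperature_adjust(0.225, 298, 37.2, 300)  # ~0.249 mM
temperature_adjust <- function(K0, T0, dH, temperature) {
  if (any(K0 <= 0) || T0 <= 0 || any(temperature <= 0))
    stop("K0 and temperatures must be positive")
  K0 * exp(-(dH * 1000 / .R_GAS_J) * (1 / temperature - 1 / T0))
}

#' Speciation as a function of total acid concentration
#'
#' Sweeps [solve_speciation()] over a vector of total concentrations and
#' returns a tidy table of species concentrations, ready for writing with
#' [write_table()].
#'
#' @param C_total vector of total acid concentrations, mM.
#' @param W_total total water concentration, mM.
#' @param constants an [equilibrium_constants()].
#' @param convention as in [solve_speciation()].
#' @return data.frame with columns `C_total`, `M`, `D`, `MW`, `W_free`,
#'   `monomer_fraction`.
#' @export
speciation_curve <- function(C_total, W_total = 0, constants,
                             convention = "C_eq_M_plus_D") {
  rows <- lapply(C_total, function(C) {
    s <- solve_speciation(C, W_total, constants, convention)
    data.frame(C_total = C, M = s$M, D = s$D, MW = s$MW,
               W_free = s$W_free,
               monomer_fraction = if (C > 0) s$M / C else 1)
  })
  do.call(rbind, rows)
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf(
    "Speciation (%s): M = %.6g, D = %.6g, MW = %.6g, W_free = %.6g mM\n",
    x$convention, x$M, x$D, x$MW, x$W_free))
  invisible(x)
}
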