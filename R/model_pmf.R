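#' Parametric model potential of mean force
#'
#' A `model_pmf` is an analytic free-energy curve W(r) along a scalar
#' separation coordinate, used both as ground truth for synthetic
#' umbrella-sampling data and in recovery tests of the WHAM estimator. The
#' functional form is a sum of negative Gaussian wells plus an exponential
#' repulsive wall:
#'
#' \deqn{W(r) = e^{-s (r - r_w)} - \sum_k d_k \exp\left(-\frac{(r-c_k)^2}{2 w_k^2}\right)}
#'
#' so W(r) tends to a zero plateau at large r (the bulk reference), is
#' strongly repulsive below the wall position \eqn{r_w}, and has bound-state
#' minima near the well centers \eqn{c_k}.
#'
#' @param wells data.frame with numeric columns `center` (A), `depth`
#'   (kJ/mol, positive for attractive wells) and `width` (A, Gaussian sigma).
#' @param wall_position position of the repulsive wall in A; W equals
#'   1 kJ/mol from the wall term at this separation and grows steeply below.
#' @param wall_steepness exponential decay rate of the wall (1/A).
#' @return an object of class `model_pmf`.
#' @seealso [make_default_pmf()], [make_water_pmf()], [evaluate_pmf()]
#' @export
model_pmf <- function(wells, wall_position, wall_steepness) {
  stopifnot(is.data.frame(wells),
            all(c("center", "depth", "width") %in% names(wells)))
  if (nrow(wells) == 0L) stop("at least one well is required")
  if (any(wells$depth <= 0)) stop("well depths must be positive")
  if (any(wells$width <= 0)) stop("well widths must be positive")
  if (!is.numeric(wall_position) || wall_position <= 0)
    stop("wall_position must be a positive separation in A")
  if (!is.numeric(wall_steepness) || wall_steepness <= 0)
    stop("wall_steepness must be positive")
  structure(
    list(wells = wells[order(wells$center), , drop = FALSE],
         wall_position = wall_position,
         wall_steepness = wall_steepness,
         plateau_value = 0),
    class = "model_pmf")
}

#' Default two-well acid-acid model PMF
#'
#' The canonical landscape for carboxylic-acid pairing in a nonpolar solvent:
#' a deep minimum at 3.8 A (closed dimer, two hydrogen bonds), a shallower
#' minimum at 4.6 A (open dimer, one hydrogen bond), a repulsive wall below
#' about 3.5 A and a flat zero plateau beyond 10 A. Well depths and widths
#' are free parameters; the defaults give a closed-well depth of order
#' 20-30 kJ/mol and hence dissociation free energies of the magnitude
#' observed for long-chain fatty acids in alkanes (roughly 17-21 kJ/mol at
#' 300-345 K under a 1 M standard state).
#'
#' @param closed_depth,open_depth well depths in kJ/mol.
#' @param closed_width,open_width Gaussian widths in A.
#' @return a `model_pmf` with local minima at 3.8 A (global) and 4.6 A.
#' @export
#' @examples
#' pmf <- make_default_pmf()
#' evaluate_pmf(pmf, c(3.8, 4.6, 12))
make_default_pmf <- function(closed_depth = 28, open_depth = 24,
                             closed_width = 0.25, open_width = 0.30) {
  if (closed_depth <= open_depth)
    stop("the closed dimer (3.8 A) must be the deeper minimum")
  model_pmf(
    wells = data.frame(center = c(3.8, 4.6),
                       depth = c(closed_depth, open_depth),
                       width = c(closed_width, open_width)),
    wall_position = 3.5,
    wall_steepness = 15)
}

#' Acid-water heteroassociation model PMFs
#'
#' Landscapes for a water molecule hydrogen-bonding to a carboxylic-acid
#' headgroup, along the O-O separation. Both variants have a bound minimum
#' at 2.7 A (the hydrogen bond) and a zero plateau beyond 6 A. The
#' `"COH"` variant (water oxygen accepting from the acid O-H) carries an
#' additional shallow minimum at 5.0 A, mimicking a long-range interaction
#' of the carbonyl oxygen with a water hydrogen; the `"CO"` variant (water
#' hydrogen donating to the carbonyl oxygen) has no such secondary
#' structure because the water hydrogens sterically shield its oxygen.
#'
#' @param variant `"COH"` or `"CO"`.
#' @param primary_depth depth of the 2.7 A hydrogen-bond well, kJ/mol.
#' @param secondary_depth depth of the 5.0 A secondary well (COH only), kJ/mol.
#' @return a `model_pmf`.
#' @export
make_water_pmf <- function(variant = c("COH", "CO"),
                           primary_depth = 24, secondary_depth = 2.5) {
  variant <- match.arg(variant)
  wells <- data.frame(center = 2.7, depth = primary_depth, width = 0.20)
  if (variant == "COH") {
    wells <- rbind(wells,
                   data.frame(center = 5.0, depth = secondary_depth,
                              width = 0.30))
  }
  model_pmf(wells = wells, wall_position = 2.4, wall_steepness = 15)
}

#' Evaluate a model PMF
#'
#' @param model a `model_pmf`.
#' @param r separation(s) in A; must be positive.
#' @return W(r) in kJ/mol, vectorized over `r`.
#' @export
evaluate_pmf <- function(model, r) {
  stopifnot(inherits(model, "model_pmf"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("r must be positive and finite")
  w <- exp(-model$wall_steepness * (r - model$wall_position))
  for (k in seq_len(nrow(model$wells))) {
    dk <- r - model$wells$center[k]
    w <- w - model$wells$depth[k] *
      exp(-0.5 * dk^2 / model$wells$width[k]^2)
  }
  w + model$plateau_value
}

#' @export
print.model_pmf <- function(x, ...) {
  cat("Model PMF:", nrow(x$wells), "well(s), wall at",
      format(x$wall_position), "A\n")
  print(x$wells, row.names = FALSE)
  invisible(x)
}
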