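# Pluggable energy/force backends. A potential is a closure pair (energy,
# gradient) over a flat coordinate vector; molecular potentials carry the
# structure template used to flatten/unflatten coordinates.

#' Construct a potential object
#'
#' @param f Energy function of a flat numeric coordinate vector (kcal/mol for
#'   molecular potentials; model units for analytic 2-D surfaces).
#' @param g Gradient function (same argument), or `NULL` for numeric
#'   differentiation via [num_gradient()].
#' @param dim Dimension of the coordinate vector.
#' @param label Human-readable label.
#' @param masses Per-degree-of-freedom masses (amu) for mass-weighted
#'   frequency analysis; `NULL` means unit masses and no rigid-body
#'   projection (analytic model surfaces).
#' @return An object of class `mlpmf_potential`.
#' @export
new_potential <- function(f, g = NULL, dim, label = "potential",
                          masses = NULL) {
  if (is.null(g)) g <- function(x) num_gradient(f, x)
  structure(list(f = f, g = g, dim = dim, label = label, masses = masses),
            class = "mlpmf_potential")
}

#' Evaluate a potential
#'
#' @param x Flat coordinate vector (or n x 3 matrix for molecular potentials).
#' @param potential An `mlpmf_potential`.
#' @param forces Also return forces (the negative gradient)?
#' @return A list with `energy`, and if requested `forces` and `gradient`.
#' @export
evaluate_energy <- function(x, potential, forces = FALSE) {
  if (is.matrix(x)) x <- as.numeric(t(x))
  if (is.data.frame(x)) x <- as.numeric(t(coord_matrix(x)))
  if (length(x) != potential$dim) {
    stop("coordinate vector has length ", length(x), " but potential '",
         potential$label, "' expects ", potential$dim)
  }
  e <- potential$f(x)
  if (!is.finite(e)) {
    stop("non-finite energy from potential '", potential$label, "'")
  }
  out <- list(energy = e, label = potential$label)
  if (forces) {
    gr <- potential$g(x)
    out$gradient <- gr
    out$forces <- -gr
  }
  out
}

#' Central-difference gradient
#'
#' @param f Scalar function of a numeric vector.
#' @param x Point of evaluation.
#' @param h Step size (default 1e-5).
#' @return Numeric gradient vector.
#' @export
num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# ---- analytic benchmark surfaces -------------------------------------------

.mb <- list(A = c(-200, -100, -170, 15),
            a = c(-1, -1, -6.5, 0.7),
            b = c(0, 0, 11, 0.6),
            cc = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1))

#' The Mueller-Brown surface
#'
#' The standard four-Gaussian two-dimensional benchmark surface used to test
#' minimisers and saddle-point searches. Energies are in model units.
#'
#' @param point Length-2 numeric vector `(x, y)`.
#' @return Energy at `point`.
#' @export
#' @examples
#' muller_brown(c(-0.558, 1.442)) # deepest minimum, about -146.7
muller_brown <- function(point) {
  stopifnot(length(point) == 2, all(is.finite(point)))
  p <- .mb
  dx <- point[1] - p$x0
  dy <- point[2] - p$y0
  sum(p$A * exp(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2))
}

muller_brown_gradient <- function(point) {
  p <- .mb
  dx <- point[1] - p$x0
  dy <- point[2] - p$y0
  e <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2)
  c(sum(e * (2 * p$a * dx + p$b * dy)),
    sum(e * (p$b * dx + 2 * p$cc * dy)))
}

#' @describeIn muller_brown Potential object for the surface (analytic
#'   gradient).
#' @export
potential_muller_brown <- function() {
  new_potential(muller_brown, muller_brown_gradient, dim = 2,
                label = "Mueller-Brown")
}

#' One-dimensional symmetric double well
#'
#' `V(x) = x^4 - x^2`, with minima at `x = +/- 1/sqrt(2)` (V = -1/4) and a
#' saddle at `x = 0`; the barrier from either well is exactly 0.25 model
#' units.
#'
#' @return A potential object.
#' @export
potential_double_well <- function() {
  new_potential(function(x) x[1]^4 - x[1]^2,
                function(x) 4 * x[1]^3 - 2 * x[1],
                dim = 1, label = "double well")
}

#' Isotropic harmonic well
#'
#' `V(x) = 0.5 * k * |x - x0|^2` in any dimension.
#'
#' @param k Force constant (kcal/mol/A^2 for molecular coordinates).
#' @param x0 Minimum position (flat vector).
#' @param masses Optional per-dof masses (amu) for frequency analysis.
#' @return A potential object.
#' @export
potential_harmonic <- function(k, x0 = 0, masses = NULL) {
  x0 <- as.numeric(x0)
  new_potential(function(x) 0.5 * k * sum((x - x0)^2),
                function(x) k * (x - x0),
                dim = length(x0), label = "harmonic", masses = masses)
}
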