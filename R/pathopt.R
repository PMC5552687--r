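# Nudged-elastic-band path optimisation with improved (energy-upwinded)
# tangents, optional climbing image, FIRE relaxation of the perpendicular
# forces, and finite-difference frequency verification of stationary points.

#' Linear interpolation between two endpoint structures
#'
#' @param reactant,product Structure tibbles (same atom ordering) or flat
#'   numeric coordinate vectors.
#' @param n Number of beads including the endpoints (default 10).
#' @return A `reaction_path`: bead coordinate matrix (`n` rows), the structure
#'   template (if structures were given), per-bead energies (`NA` until
#'   relaxed) and cumulative arc length.
#' @export
#' @examples
#' p <- interpolate_path(c(-1, 0), c(1, 0), n = 3)
#' p$coords[2, ]  # midpoint is the coordinate average
interpolate_path <- function(reactant, product, n = 10) {
  template <- NULL
  to_vec <- function(s) {
    if (is.data.frame(s)) as.numeric(t(coord_matrix(s))) else as.numeric(s)
  }
  if (is.data.frame(reactant)) template <- reactant
  r <- to_vec(reactant)
  p <- to_vec(product)
  if (length(r) != length(p)) {
    stop("endpoint coordinate counts differ (", length(r), " vs ",
         length(p), ")")
  }
  if (n < 2) stop("a path needs at least 2 beads")
  if (max(abs(r - p)) < 1e-12) {
    warning("reactant and product are identical; all beads coincide")
  }
  w <- seq(0, 1, length.out = n)
  coords <- outer(1 - w, r) + outer(w, p)
  new_path(coords, template)
}

new_path <- function(coords, template = NULL, energies = NULL,
                     converged = NA, iterations = 0L, max_force = NA_real_) {
  structure(list(coords = coords,
                 template = template,
                 energies = energies,
                 arc_length = path_arc_length(coords),
                 converged = converged,
                 iterations = iterations,
                 max_force = max_force),
            class = "reaction_path")
}

path_arc_length <- function(coords) {
  n <- nrow(coords)
  if (n == 1) return(0)
  seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-n, , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' NEB configuration
#'
#' @param k_spring Spring constant between beads (kcal/mol/A^2).
#' @param climbing Turn the highest interior bead into a climbing image?
#' @param climb_after Iteration at which climbing is switched on.
#' @param maxiter Maximum relaxation iterations.
#' @param tol Convergence threshold on the per-bead max-norm of the projected
#'   NEB force (kcal/mol/A).
#' @param step_max Displacement cap per bead per iteration (A).
#' @param dt_init,dt_max FIRE time-step parameters.
#' @return A list of class `neb_config`.
#' @export
neb_config <- function(k_spring = 1.0, climbing = TRUE, climb_after = 50,
                       maxiter = 3000, tol = 0.05, step_max = 0.1,
                       dt_init = 0.03, dt_max = 0.12) {
  stopifnot(tol > 0, maxiter >= 1, k_spring > 0)
  structure(list(k_spring = k_spring, climbing = climbing,
                 climb_after = climb_after, maxiter = maxiter, tol = tol,
                 step_max = step_max, dt_init = dt_init, dt_max = dt_max),
            class = "neb_config")
}

# improved (energy-upwinded) tangent of Henkelman & Jonsson
neb_tangent <- function(coords, energies, i) {
  tp <- coords[i + 1, ] - coords[i, ]
  tm <- coords[i, ] - coords[i - 1, ]
  e0 <- energies[i - 1]; e1 <- energies[i]; e2 <- energies[i + 1]
  if (e2 > e1 && e1 > e0) {
    tau <- tp
  } else if (e2 < e1 && e1 < e0) {
    tau <- tm
  } else {
    dmax <- max(abs(e2 - e1), abs(e0 - e1))
    dmin <- min(abs(e2 - e1), abs(e0 - e1))
    tau <- if (e2 > e0) tp * dmax + tm * dmin else tp * dmin + tm * dmax
  }
  nt <- sqrt(sum(tau^2))
  if (nt < 1e-14) tau else tau / nt
}

#' Relax a path with the nudged elastic band
#'
#' Interior beads are relaxed with FIRE dynamics on the NEB force (true force
#' perpendicular to the tangent plus spring force along it); after
#' `climb_after` iterations the highest bead becomes a climbing image driven
#' uphill along the tangent, converging onto the saddle point. Endpoints are
#' never moved. Non-convergence returns the partial result flagged with
#' `converged = FALSE` and a warning, never silently.
#'
#' @param path A `reaction_path` (e.g. from [interpolate_path()]).
#' @param potential An `mlpmf_potential` supplying energies and forces.
#' @param config A [neb_config()].
#' @return The relaxed `reaction_path` with per-bead `energies`, arc length,
#'   `converged`, `iterations`, `max_force`, and attribute `climbing_bead`.
#' @export
neb_relax <- function(path, potential, config = neb_config()) {
  coords <- path$coords
  n <- nrow(coords)
  if (n < 3) stop("NEB needs at least 3 beads")
  d <- ncol(coords)
  energies <- apply(coords, 1, potential$f)
  grads <- do.call(rbind, lapply(seq_len(n), function(i)
    potential$g(coords[i, ])))

  # FIRE state over interior beads
  vel <- matrix(0, n, d)
  dt <- config$dt_init
  alpha <- 0.1
  n_pos <- 0L
  climb <- 0L
  max_f <- Inf
  it <- 0L

  neb_forces <- function(coords, energies, grads, climb) {
    Fn <- matrix(0, n, d)
    for (i in 2:(n - 1)) {
      tau <- neb_tangent(coords, energies, i)
      ftrue <- -grads[i, ]
      if (i == climb) {
        Fn[i, ] <- ftrue - 2 * sum(ftrue * tau) * tau
      } else {
        fperp <- ftrue - sum(ftrue * tau) * tau
        fspring <- config$k_spring *
          (sqrt(sum((coords[i + 1, ] - coords[i, ])^2)) -
             sqrt(sum((coords[i, ] - coords[i - 1, ])^2))) * tau
        Fn[i, ] <- fperp + fspring
      }
    }
    Fn
  }

  for (it in seq_len(config$maxiter)) {
    if (config$climbing && it > config$climb_after && climb == 0L) {
      climb <- which.max(energies[2:(n - 1)]) + 1L
      vel[] <- 0; dt <- config$dt_init; alpha <- 0.1; n_pos <- 0L
    }
    Fn <- neb_forces(coords, energies, grads, climb)
    max_f <- max(abs(Fn[2:(n - 1), , drop = FALSE]))
    # never declare convergence while a climbing phase is still pending
    if (max_f <= config$tol && (!config$climbing || climb > 0L)) break

    # FIRE update on the interior beads
    P <- sum(Fn * vel)
    fnorm <- sqrt(sum(Fn^2))
    vnorm_ <- sqrt(sum(vel^2))
    if (P > 0) {
      vel <- (1 - alpha) * vel + alpha * (Fn / max(fnorm, 1e-14)) * vnorm_
      n_pos <- n_pos + 1L
      if (n_pos > 5) {
        dt <- min(dt * 1.1, config$dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      vel[] <- 0
      dt <- dt * 0.5
      alpha <- 0.1
      n_pos <- 0L
    }
    vel <- vel + dt * Fn
    step <- dt * vel
    # cap per-bead displacement
    for (i in 2:(n - 1)) {
      sn <- sqrt(sum(step[i, ]^2))
      if (sn > config$step_max) step[i, ] <- step[i, ] * config$step_max / sn
    }
    coords[2:(n - 1), ] <- coords[2:(n - 1), ] + step[2:(n - 1), , drop = FALSE]
    for (i in 2:(n - 1)) {
      energies[i] <- potential$f(coords[i, ])
      grads[i, ] <- potential$g(coords[i, ])
    }
  }

  converged <- max_f <= config$tol
  if (!converged) {
    warning(sprintf(
      "NEB did not converge in %d iterations (max force %.4g > %.4g); %s",
      config$maxiter, max_f, config$tol, "returning partial result"))
  }
  out <- new_path(coords, path$template, energies = energies,
                  converged = converged, iterations = it, max_force = max_f)
  attr(out, "climbing_bead") <- if (climb > 0) climb else which.max(energies)
  out
}

#' @describeIn neb_relax Tidy per-bead summary: bead, arc length, energy and
#'   energy relative to the first bead.
#' @param x A `reaction_path`.
#' @param ... Unused.
#' @export
tidy.reaction_path <- function(x, ...) {
  tibble::tibble(
    bead = seq_len(nrow(x$coords)),
    arc_length = x$arc_length,
    energy = if (is.null(x$energies)) NA_real_ else x$energies,
    energy_rel = if (is.null(x$energies)) NA_real_ else
      x$energies - x$energies[1]
  )
}

#' @describeIn neb_relax One-row summary: barrier (highest bead relative to
#'   the first), reaction energy (last bead relative to the first),
#'   convergence state.
#' @export
glance.reaction_path <- function(x, ...) {
  e <- x$energies
  tibble::tibble(
    n_beads = nrow(x$coords),
    barrier = if (is.null(e)) NA_real_ else max(e) - e[1],
    ts_bead = if (is.null(e)) NA_integer_ else which.max(e),
    reaction_energy = if (is.null(e)) NA_real_ else e[length(e)] - e[1],
    converged = x$converged,
    iterations = x$iterations,
    max_force = x$max_force
  )
}

#' Extract one bead of a path as a structure
#'
#' @param path A `reaction_path` whose template is a structure tibble.
#' @param bead Bead index.
#' @return A structure tibble at the bead's coordinates.
#' @export
path_structure <- function(path, bead) {
  if (is.null(path$template)) {
    stop("path carries no structure template (built from raw vectors)")
  }
  set_coords(path$template, matrix(path$coords[bead, ], ncol = 3,
                                   byrow = TRUE))
}

#' Write a path as a multi-frame XYZ file
#'
#' @param path A `reaction_path` with a structure template.
#' @param file Output file.
#' @return `file`, invisibly.
#' @export
write_path_xyz <- function(path, file) {
  frames <- lapply(seq_len(nrow(path$coords)), function(b)
    path_structure(path, b))
  comments <- sprintf("bead %d energy %.6f", seq_along(frames),
                      if (is.null(path$energies)) rep(NA, length(frames))
                      else path$energies)
  write_xyz(frames, file, comment = comments)
}

# ---- frequencies ------------------------------------------------------------

#' Finite-difference normal-mode analysis
#'
#' Builds the Hessian by central differences of the analytic gradient
#' (default step 0.005 A), symmetrises it, mass-weights when the potential
#' carries atomic masses, projects out rigid translations and rotations (3N
#' case), and reports harmonic frequencies in 1/cm with imaginary modes as
#' negative numbers. Analytic model surfaces (no masses) are analysed with
#' unit masses and no projection. A non-stationary input (force norm above
#' ten times `tol`) annotates the result with a warning rather than failing.
#'
#' @param x Structure tibble or flat coordinate vector at a (near-)stationary
#'   point.
#' @param potential An `mlpmf_potential`.
#' @param step Finite-difference displacement (A).
#' @param tol Force threshold defining "stationary" (kcal/mol/A).
#' @return An object of class `freq_result`: `eigenvalues` (mass-weighted,
#'   after projection for molecular systems), `frequencies_cm` (negative =
#'   imaginary), `n_imaginary`, `stationary`.
#' @export
frequencies <- function(x, potential, step = 0.005, tol = 0.05) {
  if (is.data.frame(x)) x <- as.numeric(t(coord_matrix(x)))
  d <- length(x)
  g0 <- potential$g(x)
  stationary <- max(abs(g0)) <= 10 * tol
  if (!stationary) {
    warning(sprintf("input is not stationary (max |gradient| = %.4g)",
                    max(abs(g0))))
  }
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + step
    xm[i] <- xm[i] - step
    H[i, ] <- (potential$g(xp) - potential$g(xm)) / (2 * step)
  }
  H <- (H + t(H)) / 2

  masses <- potential$masses
  project <- !is.null(masses) && d %% 3 == 0 && d >= 6
  if (is.null(masses)) masses <- rep(1, d)
  Hm <- H / sqrt(outer(masses, masses))

  n_drop <- 0L
  if (project) {
    # rigid-body basis in mass-weighted coordinates
    n_at <- d / 3
    xm3 <- matrix(x, ncol = 3, byrow = TRUE)
    sm <- sqrt(masses[seq(1, d, by = 3)])
    com <- colSums(xm3 * sm^2) / sum(sm^2)
    xc <- sweep(xm3, 2, com)
    B <- matrix(0, d, 6)
    for (k in 1:3) B[seq(k, d, by = 3), k] <- sm            # translations
    for (a in seq_len(n_at)) {                              # rotations
      r <- xc[a, ]
      B[3 * (a - 1) + 1:3, 4] <- sm[a] * c(0, -r[3], r[2])
      B[3 * (a - 1) + 1:3, 5] <- sm[a] * c(r[3], 0, -r[1])
      B[3 * (a - 1) + 1:3, 6] <- sm[a] * c(-r[2], r[1], 0)
    }
    qr_ <- qr(B)
    rank <- qr_$rank
    Q <- qr.Q(qr_)[, seq_len(rank), drop = FALSE]
    P <- diag(d) - Q %*% t(Q)
    Hm <- P %*% Hm %*% P
    n_drop <- rank
  }
  ev <- eigen(Hm, symmetric = TRUE)$values
  if (n_drop > 0) {
    # discard the projected-out (numerically zero) rigid-body eigenvalues
    ord <- order(abs(ev))
    ev <- sort(ev[-ord[seq_len(n_drop)]], decreasing = TRUE)
  }
  freq <- ifelse(ev >= 0, 1, -1) *
    sqrt(abs(ev) * .consts$freq_conv) / (2 * pi * .consts$c_cm)
  structure(list(eigenvalues = ev,
                 frequencies_cm = freq,
                 n_imaginary = sum(ev < -1e-8),
                 stationary = stationary),
            class = "freq_result")
}

#' @export
print.freq_result <- function(x, ...) {
  cat("Normal-mode analysis:", length(x$eigenvalues), "modes,",
      x$n_imaginary, "imaginary\n")
  cat("frequencies (1/cm, negative = imaginary):\n")
  print(round(x$frequencies_cm, 1))
  if (!x$stationary) cat("note: input was not stationary\n")
  invisible(x)
}
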