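# The surrogate reactive solute. A small (7-atom) molecule with one breakable
# bond stands in for the quantum-mechanical solute: its internal energy is an
# analytic force field (harmonic bonds/angles/dihedrals plus a Morse term on
# the breakable bond), and the three electronic-structure tiers are emulated
# as ESP (cheap surface, base charge set), LOW (adds the product
# stabilisation well that makes the bond-breaking a double-well reaction) and
# HIGH (adds a bounded smooth perturbation along the bond coordinate, and a
# slightly larger charge scale). Atom names echo the ring-opening chemistry
# this emulates (C8-N9 is the breakable bond).

#' Surrogate solute parameter set
#'
#' Defaults give a reactant well near r(C8-N9) = 1.47 A, a product well near
#' 2.85 A, a LOW-tier barrier of roughly 30 kcal/mol, and a HIGH-tier
#' perturbation of amplitude 2.5 kcal/mol near the barrier top -- magnitudes
#' chosen to mirror a DFT-to-coupled-cluster tier shift on a ring-opening
#' reaction.
#'
#' @param De,a_morse,r0_morse Morse parameters of the breakable bond
#'   (kcal/mol, 1/A, A).
#' @param well_depth,well_center,well_width Product stabilisation well added
#'   at the LOW tier (kcal/mol, A, A).
#' @param pert_amp,pert_center,pert_width HIGH-tier additive Gaussian
#'   perturbation along the bond coordinate (kcal/mol, A, A).
#' @param charge_scale Named multipliers applied to the ESP charge set at
#'   each tier.
#' @return A named list of parameters.
#' @export
solute_params <- function(De = 60, a_morse = 2.0, r0_morse = 1.47,
                          well_depth = 38, well_center = 2.9,
                          well_width = 0.35,
                          pert_amp = 2.5, pert_center = 2.25,
                          pert_width = 0.35,
                          charge_scale = c(ESP = 1.0, LOW = 1.04,
                                           HIGH = 1.06)) {
  list(De = De, a_morse = a_morse, r0_morse = r0_morse,
       well_depth = well_depth, well_center = well_center,
       well_width = well_width,
       pert_amp = pert_amp, pert_center = pert_center,
       pert_width = pert_width, charge_scale = charge_scale)
}

# NeRF atom placement: position D bonded to C with bond length r, angle
# D-C-B = theta, dihedral D-C-B-A = phi (degrees)
place_atom <- function(C, B, A, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  bc <- C - B
  bc <- bc / vnorm(bc)
  n <- cross3(B - A, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Generate the surrogate reactive solute
#'
#' Builds the 7-atom solute (N7, C8, O10, H8, N9, H9, H10), sets every bonded
#' term's equilibrium value from the built geometry so the construction is a
#' consistent stationary point, then minimises the LOW-tier surface to obtain
#' the reactant geometry and, from a stretched start, the product geometry.
#' The construction is deterministic; `seed` is accepted for interface
#' symmetry with the other generators but no randomness is used.
#'
#' @param seed Unused (deterministic construction).
#' @param params Parameter list from [solute_params()].
#' @return An object of class `surrogate_solute`: atom table (with masses and
#'   Lennard-Jones parameters), bonded terms, tier parameters, reactant and
#'   product ESP charge sets, and minimised reactant/product geometries.
#' @export
#' @examples
#' sol <- generate_solute()
#' bond_length(sol$geometry$reactant, "C8", "N9")
generate_solute <- function(seed = NULL, params = solute_params()) {
  atoms <- tibble::tibble(
    name    = c("N7", "C8", "O10", "H8", "N9", "H9", "H10"),
    element = c("N", "C", "O", "H", "N", "H", "H"),
    sigma   = c(3.25, 3.40, 3.00, 1.00, 3.25, 1.00, 1.00),
    eps     = c(0.17, 0.086, 0.21, 0.016, 0.17, 0.016, 0.016)
  )
  atoms$mass <- element_mass(atoms$element)

  # indices: 1 N7, 2 C8, 3 O10, 4 H8, 5 N9, 6 H9, 7 H10
  xyz <- matrix(0, 7, 3)
  xyz[2, ] <- c(0, 0, 0)                               # C8
  xyz[1, ] <- c(1.38, 0, 0)                            # N7
  xyz[3, ] <- 1.40 * c(cos(115 * pi / 180), sin(115 * pi / 180), 0)  # O10
  xyz[4, ] <- place_atom(xyz[2, ], xyz[1, ], xyz[3, ], 1.09, 110, 120)   # H8
  xyz[5, ] <- place_atom(xyz[2, ], xyz[1, ], xyz[3, ], params$r0_morse,
                         108, -115)                                      # N9
  xyz[6, ] <- place_atom(xyz[5, ], xyz[2, ], xyz[1, ], 1.01, 110, 155)   # H9
  xyz[7, ] <- place_atom(xyz[3, ], xyz[2, ], xyz[1, ], 0.97, 107, 180)   # H10

  template <- mol_structure(atoms$name, xyz[, 1], xyz[, 2], xyz[, 3],
                            element = atoms$element, region = "QM")

  bonds <- tibble::tibble(
    ai = c(1, 2, 2, 5, 3), aj = c(2, 3, 4, 6, 7),
    kf = 500,
    r0 = c(1.38, 1.40, 1.09, 1.01, 0.97)
  )
  ang_def <- tibble::tibble(
    ai = c(1, 1, 3, 2, 2, 1, 3),
    aj = c(2, 2, 2, 3, 5, 2, 2),
    ak = c(3, 4, 4, 7, 6, 5, 5),
    kf = c(100, 100, 100, 100, 30, 30, 30)
  )
  dih_def <- tibble::tibble(
    ai = c(7, 6), aj = c(3, 5), ak = c(2, 2), al = c(1, 1),
    kf = c(15, 8)
  )
  # equilibrium values measured on the built geometry => exact consistency
  ang_def$th0 <- vapply(seq_len(nrow(ang_def)), function(r) {
    bond_angle(template, atoms$name[ang_def$ai[r]], atoms$name[ang_def$aj[r]],
               atoms$name[ang_def$ak[r]])
  }, numeric(1))
  dih_def$phi0 <- vapply(seq_len(nrow(dih_def)), function(r) {
    dihedral_angle(template, atoms$name[dih_def$ai[r]],
                   atoms$name[dih_def$aj[r]], atoms$name[dih_def$ak[r]],
                   atoms$name[dih_def$al[r]])
  }, numeric(1))

  sol <- structure(list(
    atoms = atoms, bonds = bonds, angles = ang_def, dihedrals = dih_def,
    morse = list(ai = 2, aj = 5, De = params$De, a = params$a_morse,
                 r0 = params$r0_morse),
    params = params,
    charges = list(
      reactant = c(N7 = -0.45, C8 = 0.55, O10 = -0.50, H8 = 0.10,
                   N9 = -0.55, H9 = 0.35, H10 = 0.50),
      product  = c(N7 = -0.50, C8 = 0.60, O10 = -0.45, H8 = 0.12,
                   N9 = -0.62, H9 = 0.40, H10 = 0.45)
    ),
    r_ref = c(reactant = params$r0_morse, product = params$well_center)
  ), class = "surrogate_solute")

  react <- minimize_solute(sol, xyz, level = "LOW")
  # stretch the breakable bond toward the product well and re-minimise
  xyz_p <- react
  dirn <- xyz_p[5, ] - xyz_p[2, ]
  dirn <- dirn / vnorm(dirn)
  shift <- (params$well_center - vnorm(xyz_p[5, ] - xyz_p[2, ])) * dirn
  xyz_p[5, ] <- xyz_p[5, ] + shift
  xyz_p[6, ] <- xyz_p[6, ] + shift
  prod <- minimize_solute(sol, xyz_p, level = "LOW")

  sol$r_ref <- c(reactant = vnorm(react[5, ] - react[2, ]),
                 product = vnorm(prod[5, ] - prod[2, ]))
  sol$geometry <- list(reactant = set_coords(template, react),
                       product = set_coords(template, prod))
  sol
}

minimize_solute <- function(sol, xyz, level = "LOW", maxit = 2000) {
  fn <- function(p) solute_internal(matrix(p, ncol = 3, byrow = TRUE),
                                    sol, level)$energy
  gr <- function(p) solute_internal(matrix(p, ncol = 3, byrow = TRUE),
                                    sol, level, gradient = TRUE)$gradient
  p0 <- as.numeric(t(xyz))
  opt <- stats::optim(p0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-16))
  # polish until the gradient norm is tight
  for (k in 1:5) {
    if (max(abs(gr(opt$par))) < 1e-6) break
    opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-16))
  }
  matrix(opt$par, ncol = 3, byrow = TRUE)
}

# internal (bonded) energy of the surrogate at a tier; x is an n x 3 matrix
solute_internal <- function(x, sol, level = c("ESP", "LOW", "HIGH"),
                            gradient = FALSE) {
  level <- match.arg(level)
  e <- 0
  g <- if (gradient) matrix(0, nrow(x), 3) else NULL

  for (r in seq_len(nrow(sol$bonds))) {
    i <- sol$bonds$ai[r]; j <- sol$bonds$aj[r]
    dv <- x[i, ] - x[j, ]
    rij <- vnorm(dv)
    dr <- rij - sol$bonds$r0[r]
    e <- e + 0.5 * sol$bonds$kf[r] * dr^2
    if (gradient) {
      f <- sol$bonds$kf[r] * dr * dv / rij
      g[i, ] <- g[i, ] + f
      g[j, ] <- g[j, ] - f
    }
  }

  # breakable-bond terms (all functions of r only)
  i <- sol$morse$ai; j <- sol$morse$aj
  dv <- x[i, ] - x[j, ]
  rij <- vnorm(dv)
  bt <- bond_profile(rij, sol, level, deriv = gradient)
  e <- e + bt$value
  if (gradient) {
    f <- bt$deriv * dv / rij
    g[i, ] <- g[i, ] + f
    g[j, ] <- g[j, ] - f
  }

  for (r in seq_len(nrow(sol$angles))) {
    i <- sol$angles$ai[r]; j <- sol$angles$aj[r]; k <- sol$angles$ak[r]
    u <- x[i, ] - x[j, ]
    v <- x[k, ] - x[j, ]
    nu <- vnorm(u); nv <- vnorm(v)
    ct <- min(1, max(-1, sum(u * v) / (nu * nv)))
    th <- acos(ct)
    dth <- th - sol$angles$th0[r] * pi / 180
    e <- e + 0.5 * sol$angles$kf[r] * dth^2
    if (gradient) {
      st <- sqrt(max(1e-12, 1 - ct^2))
      uh <- u / nu; vh <- v / nv
      dthi <- (ct * uh - vh) / (nu * st)
      dthk <- (ct * vh - uh) / (nv * st)
      dthj <- -(dthi + dthk)
      coef <- sol$angles$kf[r] * dth
      g[i, ] <- g[i, ] + coef * dthi
      g[j, ] <- g[j, ] + coef * dthj
      g[k, ] <- g[k, ] + coef * dthk
    }
  }

  for (r in seq_len(nrow(sol$dihedrals))) {
    i <- sol$dihedrals$ai[r]; j <- sol$dihedrals$aj[r]
    k <- sol$dihedrals$ak[r]; l <- sol$dihedrals$al[r]
    b1 <- x[j, ] - x[i, ]
    b2 <- x[k, ] - x[j, ]
    b3 <- x[l, ] - x[k, ]
    n1 <- cross3(b1, b2)
    n2 <- cross3(b2, b3)
    nb2 <- vnorm(b2)
    phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
    dphi <- phi - sol$dihedrals$phi0[r] * pi / 180
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))   # wrap to (-pi, pi]
    e <- e + 0.5 * sol$dihedrals$kf[r] * dphi^2
    if (gradient) {
      A <- -nb2 / sum(n1 * n1) * n1
      D <- nb2 / sum(n2 * n2) * n2
      p <- -sum(b1 * b2) / nb2^2
      q <- -sum(b3 * b2) / nb2^2
      coef <- sol$dihedrals$kf[r] * dphi
      g[i, ] <- g[i, ] + coef * A
      g[j, ] <- g[j, ] + coef * (-A + p * A - q * D)
      g[k, ] <- g[k, ] + coef * (-D - p * A + q * D)
      g[l, ] <- g[l, ] + coef * D
    }
  }

  list(energy = e, gradient = if (gradient) as.numeric(t(g)) else NULL)
}

# tier-dependent 1-D profile along the breakable-bond length
bond_profile <- function(r, sol, level, deriv = FALSE) {
  p <- sol$params
  ex <- exp(-p$a_morse * (r - p$r0_morse))
  v <- p$De * ((1 - ex)^2 - 1)
  d <- 2 * p$De * p$a_morse * ex * (1 - ex)
  if (level %in% c("LOW", "HIGH")) {
    gw <- exp(-(r - p$well_center)^2 / (2 * p$well_width^2))
    v <- v - p$well_depth * gw
    d <- d + p$well_depth * gw * (r - p$well_center) / p$well_width^2
  }
  if (level == "HIGH") {
    gp <- exp(-(r - p$pert_center)^2 / (2 * p$pert_width^2))
    v <- v + p$pert_amp * gp
    d <- d - p$pert_amp * gp * (r - p$pert_center) / p$pert_width^2
  }
  list(value = v, deriv = if (deriv) d else NULL)
}

#' Solute internal energy at a theory tier
#'
#' Evaluates the surrogate solute's internal (gas-phase) energy at the ESP,
#' LOW or HIGH tier, optionally with the analytic gradient. The HIGH tier is
#' the LOW tier plus a bounded additive perturbation along the breakable-bond
#' coordinate; at the perturbation centre `HIGH - LOW` equals the perturbation
#' amplitude by construction.
#'
#' @param structure A structure tibble (or an n x 3 coordinate matrix in the
#'   solute's atom order).
#' @param solute A `surrogate_solute`.
#' @param level `"ESP"`, `"LOW"` or `"HIGH"`.
#' @param gradient Also return the analytic gradient (flat 3n vector,
#'   kcal/mol/A)?
#' @return A list with `energy` (kcal/mol), `level`, and optionally
#'   `gradient` and `forces`.
#' @export
solute_energy <- function(structure, solute, level = c("ESP", "LOW", "HIGH"),
                          gradient = FALSE) {
  level <- match.arg(level)
  x <- if (is.data.frame(structure)) coord_matrix(structure) else structure
  if (nrow(x) != nrow(solute$atoms)) {
    stop("structure has ", nrow(x), " atoms but the solute defines ",
         nrow(solute$atoms))
  }
  res <- solute_internal(x, solute, level, gradient = gradient)
  out <- list(energy = res$energy, level = level)
  if (gradient) {
    out$gradient <- res$gradient
    out$forces <- -res$gradient
  }
  out
}

#' Conformation-dependent ESP charges of the surrogate solute
#'
#' The point-charge set interpolates linearly between the reactant-state and
#' product-state fits as a function of the breakable-bond length, clamped at
#' the reference end-point geometries; tiers scale the set by
#' `params$charge_scale`. Both end-point sets are neutral, so neutrality is
#' preserved along the whole path and at every tier scale.
#'
#' @param structure Structure tibble or coordinate matrix.
#' @param solute A `surrogate_solute`.
#' @param level Theory tier whose charge scale to apply.
#' @return Numeric vector of per-atom charges (e).
#' @export
solute_charges <- function(structure, solute,
                           level = c("ESP", "LOW", "HIGH")) {
  level <- match.arg(level)
  x <- if (is.data.frame(structure)) coord_matrix(structure) else structure
  r <- vnorm(x[solute$morse$ai, ] - x[solute$morse$aj, ])
  t <- (r - solute$r_ref["reactant"]) /
    (solute$r_ref["product"] - solute$r_ref["reactant"])
  t <- min(1, max(0, t))
  q <- (1 - t) * solute$charges$reactant + t * solute$charges$product
  unname(q * solute$params$charge_scale[[level]])
}

#' @describeIn solute_energy Potential object for the solute's internal
#'   energy at a tier (for NEB, minimisation and frequency analysis).
#' @export
potential_solute <- function(solute, level = c("ESP", "LOW", "HIGH")) {
  level <- match.arg(level)
  n <- nrow(solute$atoms)
  new_potential(
    f = function(x) solute_internal(matrix(x, ncol = 3, byrow = TRUE),
                                    solute, level)$energy,
    g = function(x) solute_internal(matrix(x, ncol = 3, byrow = TRUE),
                                    solute, level, gradient = TRUE)$gradient,
    dim = 3 * n,
    label = paste0("surrogate solute (", level, ")"),
    masses = rep(solute$atoms$mass, each = 3)
  )
}

#' One-dimensional scan of the breakable-bond profile
#'
#' Tier energy profile along the breakable-bond length with all other internal
#' coordinates held at their reactant values (pure bond-coordinate terms; the
#' remaining bonded terms are unchanged by the scan by construction, since
#' only the bond-profile terms depend on r). Used as the brute-force oracle
#' for barrier locations.
#'
#' @param solute A `surrogate_solute`.
#' @param level Theory tier.
#' @param r Vector of bond lengths to scan (A).
#' @return A tibble with columns `r` and `energy` (kcal/mol, absolute).
#' @export
scan_bond_profile <- function(solute, level = c("ESP", "LOW", "HIGH"),
                              r = seq(1.2, 3.4, by = 0.001)) {
  level <- match.arg(level)
  tibble::tibble(
    r = r,
    energy = vapply(r, function(ri) bond_profile(ri, solute, level)$value,
                    numeric(1))
  )
}
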