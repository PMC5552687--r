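# SPC/E-style rigid three-site water: parameters, seeded box generation, and
# the MM water-water potential (Lennard-Jones on oxygen pairs plus Coulomb on
# all sites, group-based truncation on the oxygen-oxygen distance).

#' SPC/E water model parameters
#'
#' The standard extended simple point charge constants: O charge -0.8476 e,
#' H charge +0.4238 e, O-O Lennard-Jones sigma 3.166 A and epsilon 0.1553
#' kcal/mol, rigid O-H bond 1.0 A and H-O-H angle 109.47 degrees. All
#' overridable.
#'
#' @param qO,qH Site charges (e); the molecule must be neutral.
#' @param sigma,eps O-O Lennard-Jones parameters (A, kcal/mol).
#' @param rOH Rigid O-H bond length (A).
#' @param theta_HOH Rigid H-O-H angle (degrees).
#' @return A named list of parameters.
#' @export
water_params <- function(qO = -0.8476, qH = 0.4238, sigma = 3.166,
                         eps = 0.1553, rOH = 1.0, theta_HOH = 109.47) {
  if (abs(qO + 2 * qH) > 1e-10) stop("water molecule must be neutral")
  if (sigma <= 0 || eps <= 0) stop("sigma and eps must be positive")
  list(qO = qO, qH = qH, sigma = sigma, eps = eps, rOH = rOH,
       theta_HOH = theta_HOH)
}

# rigid water site offsets (O at origin), molecule in a canonical plane
water_template <- function(params) {
  th <- params$theta_HOH * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = params$rOH * c(sin(th / 2), cos(th / 2), 0),
        H2 = params$rOH * c(-sin(th / 2), cos(th / 2), 0))
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a seeded cubic water box
#'
#' Places `n` rigid waters at random positions and orientations inside a
#' cubic box of edge `L`, rejecting any placement whose oxygen comes closer
#' than `min_dist` to an already-placed oxygen. At liquid-like packing
#' (where sequential rejection sampling jams) the oxygens are seeded from a
#' shuffled cubic lattice with a jitter bounded so the minimum distance
#' still holds exactly. Deterministic given `seed`.
#' The defaults reproduce the reference solvation setup: a 37.5 A cube of
#' 1752 waters (density 0.994 g/cm^3). A warning is issued when the implied
#' density falls outside 0.8--1.2 g/cm^3.
#'
#' @param n Number of water molecules.
#' @param L Cubic edge length (A).
#' @param min_dist Minimum O-O distance during placement (A); default 0.9
#'   sigma, which avoids catastrophic Lennard-Jones overlaps without
#'   equilibration.
#' @param seed Integer seed.
#' @param params Water parameters from [water_params()].
#' @param max_attempts Placement attempts per molecule before giving up.
#' @return An object of class `water_box`: site matrix (3n x 3, O/H1/H2 per
#'   molecule), `n`, `L`, parameters and the non-periodic flag.
#' @export
#' @examples
#' box <- generate_box(n = 8, L = 7, seed = 1)
#' box_density(box)
generate_box <- function(n = 1752, L = 37.5, min_dist = 0.9 * 3.166,
                         seed = 1, params = water_params(),
                         max_attempts = 20000) {
  stopifnot(n >= 1, L > 0, min_dist >= 0)
  set.seed(seed)
  tmpl <- water_template(params)
  sites <- matrix(NA_real_, 3 * n, 3)
  # random sequential addition jams near packing fraction 0.38; above 0.3 the
  # oxygens are seeded from a shuffled, jittered cubic lattice instead (the
  # jitter bound preserves the minimum distance exactly)
  packing <- n * (4 / 3) * pi * (min_dist / 2)^3 / L^3
  if (packing > 0.3) {
    # pick the cubic lattice (sc / bcc / fcc) that maximises the nearest-
    # neighbour distance while providing at least n sites
    offsets <- list(
      sc  = rbind(c(0, 0, 0)),
      bcc = rbind(c(0, 0, 0), c(0.5, 0.5, 0.5)),
      fcc = rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)))
    nn_factor <- c(sc = 1, bcc = sqrt(3) / 2, fcc = 1 / sqrt(2))
    best <- NULL
    for (lat in names(offsets)) {
      k <- nrow(offsets[[lat]])
      m <- ceiling((n / k)^(1 / 3))
      nn <- (L / m) * nn_factor[[lat]]
      if (is.null(best) || nn > best$nn) {
        best <- list(lat = lat, m = m, nn = nn)
      }
    }
    if (best$nn < min_dist) {
      stop("cannot place ", n, " waters at minimum distance ", min_dist,
           " A in an L = ", L, " A box; reduce n or min_dist")
    }
    cell <- offsets[[best$lat]]
    m <- best$m
    a <- L / m
    g <- as.matrix(expand.grid(seq_len(m) - 1, seq_len(m) - 1, seq_len(m) - 1))
    k <- nrow(cell)
    cells <- (g[rep(seq_len(nrow(g)), each = k), ] +
                cell[rep(seq_len(k), nrow(g)), ] + 0.25) * a
    cells <- cells[sample.int(nrow(cells), n), , drop = FALSE]
    jit <- (best$nn - min_dist) / (2 * sqrt(3))
    O <- cells + matrix(stats::runif(3 * n, -jit, jit), n, 3)
    O <- pmin(pmax(O, 1e-9), L - 1e-9)
  } else {
    O <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        pos <- stats::runif(3, 0, L)
        if (i > 1) {
          d2 <- colSums((t(O[seq_len(i - 1), , drop = FALSE]) - pos)^2)
          if (min(d2) < min_dist^2) next
        }
        O[i, ] <- pos
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("failed to place water ", i, " of ", n, " after ", max_attempts,
             " attempts; reduce n or min_dist")
      }
    }
  }
  for (i in seq_len(n)) {
    R <- random_rotation()
    sites[3 * (i - 1) + 1:3, ] <- sweep(tmpl %*% t(R), 2, O[i, ], "+")
  }
  box <- structure(list(sites = sites, n = n, L = L, params = params,
                        periodic = FALSE), class = "water_box")
  dens <- box_density(box)
  if (dens < 0.8 || dens > 1.2) {
    warning(sprintf("box density %.3f g/cm^3 is outside [0.8, 1.2]", dens))
  }
  box
}

#' Density of a water box
#'
#' @param box A `water_box`.
#' @return Density in g/cm^3 (`n * M_water / (N_A * L^3)`).
#' @export
box_density <- function(box) {
  m_water <- 18.0153                       # g/mol
  box$n * m_water / (.consts$N_A * (box$L * 1e-8)^3)
}

#' @describeIn generate_box Convert a box to a structure tibble (MM region,
#'   SPC/E charges attached).
#' @param x A `water_box`.
#' @param ... Unused.
#' @export
as_tibble.water_box <- function(x, ...) {
  n <- x$n
  mol <- rep(seq_len(n), each = 3)
  site <- rep(c("O", "H1", "H2"), n)
  s <- mol_structure(name = paste0(site, mol),
                     element = rep(c("O", "H", "H"), n),
                     x = x$sites[, 1], y = x$sites[, 2], z = x$sites[, 3],
                     charge = rep(c(x$params$qO, x$params$qH, x$params$qH), n),
                     region = "MM")
  s$resno <- mol
  s
}

#' Water-water molecular-mechanics energy
#'
#' Pairwise energy of the MM region: Lennard-Jones between oxygen sites plus
#' Coulomb between all site pairs, with group-based hard truncation on the
#' O-O distance (a molecular pair is included when strictly inside the
#' cutoff). Non-periodic by default; with `periodic = TRUE` the minimum-image
#' convention is applied per molecular pair.
#'
#' @param box A `water_box`.
#' @param cutoff Truncation radius in A (`Inf` disables truncation).
#' @param periodic Apply minimum-image wrapping at the box edge?
#' @return A list with `energy` (kcal/mol) and `n_molecules`. Overlapping
#'   sites (r < 0.1 A) raise an error.
#' @export
water_mm_energy <- function(box, cutoff = Inf, periodic = box$periodic) {
  p <- box$params
  e <- ww_energy_cpp(box$sites, p$qO, p$qH, p$sigma, p$eps, cutoff,
                     isTRUE(periodic), box$L)
  list(energy = e, n_molecules = box$n)
}

# replace the site matrix of a box (used by the sampler)
set_box_sites <- function(box, sites) {
  box$sites <- sites
  box
}

#' Remove waters clashing with an inserted solute
#'
#' Deletes every water whose oxygen lies within `clearance` of any solute
#' atom, making room for a solute placed into a pre-generated box.
#'
#' @param box A `water_box`.
#' @param structure Solute structure tibble or coordinate matrix.
#' @param clearance Minimum allowed O-to-solute-atom distance (A).
#' @return The carved `water_box` (with updated `n`).
#' @export
carve_box <- function(box, structure, clearance = 2.4) {
  x <- if (is.data.frame(structure)) coord_matrix(structure) else structure
  keep <- vapply(seq_len(box$n), function(i) {
    o <- box$sites[3 * (i - 1) + 1, ]
    min(sqrt(colSums((t(x) - o)^2))) >= clearance
  }, logical(1))
  idx <- rep(which(keep) - 1, each = 3) * 3 + rep(1:3, sum(keep))
  box$sites <- box$sites[idx, , drop = FALSE]
  box$n <- sum(keep)
  box
}
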