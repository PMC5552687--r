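# Canonical Metropolis Monte Carlo over rigid waters with the solute frozen.
# Randomness flows through R's RNG, so trajectories are bitwise reproducible
# from a seed across platforms.

#' Sampler configuration
#'
#' @param temperature Temperature in K (default 298.15).
#' @param equil Equilibration sweeps (one sweep = one attempted move per
#'   water).
#' @param prod Production sweeps.
#' @param stride Sweeps between stored frames.
#' @param dtrans Maximum translation per move (A).
#' @param drot Maximum rotation per move about the oxygen (radians).
#' @param seed Master seed; per-bead seeds are fanned out deterministically
#'   from it by the PMF drivers.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 298.15, equil = 300, prod = 1000,
                           stride = 10, dtrans = 0.14, drot = 0.40,
                           seed = 1) {
  stopifnot(temperature > 0, prod >= 1, stride >= 1, equil >= 0)
  structure(list(temperature = temperature, equil = equil, prod = prod,
                 stride = stride, dtrans = dtrans, drot = drot, seed = seed),
            class = "sampler_config")
}

#' Sample solvent configurations around a frozen solute
#'
#' Runs Metropolis Monte Carlo over the rigid waters of `box` at the
#' configured temperature, with the solute (if any) frozen at `geometry` and
#' coupled at the charge scale of `level`. Waters are confined to the box
#' cube by a hard wall. Frames are stored every `stride` production sweeps.
#'
#' @param box A `water_box` giving the starting configuration.
#' @param solute A `surrogate_solute`, or `NULL` for a pure-water run.
#' @param geometry Solute structure tibble or coordinate matrix (defaults to
#'   the solute's reactant geometry).
#' @param level Theory tier whose coupling the ensemble samples.
#' @param config A [sampler_config()].
#' @param scheme An [embedding_scheme()] for the coupling cutoff.
#' @param ww_cutoff Water-water truncation radius (A; default none).
#' @return An object of class `solvent_ensemble`: list of site-matrix
#'   `frames`, per-frame water-water `energies`, `acceptance` rate, and the
#'   inputs. An acceptance rate outside [0.1, 0.9] warns.
#' @export
sample_solvent <- function(box, solute = NULL, geometry = NULL,
                           level = c("ESP", "LOW", "HIGH"),
                           config = sampler_config(),
                           scheme = embedding_scheme(),
                           ww_cutoff = Inf) {
  level <- match.arg(level)
  if (config$prod < config$stride) {
    stop("zero production samples: prod < stride")
  }
  p <- box$params
  if (!is.null(solute)) {
    if (is.null(geometry)) geometry <- solute$geometry$reactant
    x <- if (is.data.frame(geometry)) coord_matrix(geometry) else geometry
    q <- solute_charges(x, solute, "ESP")
    qin <- q * solute$params$charge_scale[[level]]
    lj <- mix_lj(solute, p)
    sol_m <- x
  } else {
    sol_m <- matrix(0, 0, 3)
    q <- qin <- numeric(0)
    lj <- list(sigma = numeric(0), eps = numeric(0))
    x <- NULL
  }
  kT <- .consts$R_kcal * config$temperature
  set.seed(config$seed)
  sites <- box$sites
  if (config$equil > 0) {
    eq <- mc_run_cpp(sites, box$L, TRUE, sol_m, qin, q, lj$sigma, lj$eps,
                     scheme$cutoff, ww_cutoff, p$qO, p$qH, p$sigma, p$eps,
                     kT, config$dtrans, config$drot, config$equil)
    sites <- eq$sites
  }
  n_frames <- config$prod %/% config$stride
  frames <- vector("list", n_frames)
  energies <- numeric(n_frames)
  acc <- att <- 0
  for (k in seq_len(n_frames)) {
    blk <- mc_run_cpp(sites, box$L, TRUE, sol_m, qin, q, lj$sigma, lj$eps,
                      scheme$cutoff, ww_cutoff, p$qO, p$qH, p$sigma, p$eps,
                      kT, config$dtrans, config$drot, config$stride)
    sites <- blk$sites
    acc <- acc + blk$accepted
    att <- att + blk$attempted
    frames[[k]] <- sites
    energies[k] <- ww_energy_cpp(sites, p$qO, p$qH, p$sigma, p$eps,
                                 ww_cutoff, FALSE, box$L)
  }
  if (n_frames == 0) stop("zero production samples")
  rate <- acc / att
  if (rate < 0.1 || rate > 0.9) {
    warning(sprintf("Monte Carlo acceptance rate %.2f outside [0.1, 0.9]",
                    rate))
  }
  structure(list(frames = frames, energies = energies, acceptance = rate,
                 level = level, geometry = x, config = config,
                 scheme = scheme, box = set_box_sites(box, sites)),
            class = "solvent_ensemble")
}

# per-frame raw coupling terms (bare ESP charge scale) of `geometry` against
# every stored frame: matrix with columns coul_in, lj_in, coul_out
ensemble_coupling <- function(ensemble, geometry, solute) {
  x <- if (is.data.frame(geometry)) coord_matrix(geometry) else geometry
  box <- ensemble$box
  t(vapply(ensemble$frames, function(s) {
    coupling_parts(x, solute, s, ensemble$scheme, box$params)[1:3]
  }, numeric(3)))
}

#' Single-particle Metropolis sampler
#'
#' A minimal Metropolis chain for one particle on an arbitrary energy
#' function, used to calibrate estimators against closed forms (e.g. the
#' position variance kT/k of a harmonic tether).
#'
#' @param energy_fn Energy function of a numeric position vector (kcal/mol).
#' @param x0 Starting position.
#' @param step Maximum displacement per coordinate per move.
#' @param n Number of stored samples (one per move).
#' @param temperature Temperature (K).
#' @return A list with `samples` (n x d matrix) and `acceptance`.
#' @export
mc_particle <- function(energy_fn, x0, step, n, temperature = 298.15) {
  kT <- .consts$R_kcal * temperature
  d <- length(x0)
  out <- matrix(NA_real_, n, d)
  x <- x0
  e <- energy_fn(x)
  acc <- 0
  for (i in seq_len(n)) {
    xp <- x + stats::runif(d, -step, step)
    ep <- energy_fn(xp)
    if (ep - e <= 0 || stats::runif(1) < exp(-(ep - e) / kT)) {
      x <- xp; e <- ep; acc <- acc + 1
    }
    out[i, ] <- x
  }
  list(samples = out, acceptance = acc / n)
}
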