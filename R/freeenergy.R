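# Free-energy machinery: the Zwanzig (one-sided exponential) estimator with
# block-averaged standard errors, sampled PMFs along a path, fixed-
# configuration level shifts, multi-level composition, and the solvent /
# polarization decomposition of the composed profile.

#' Zwanzig free-energy perturbation estimator
#'
#' `dF = -kT * ln < exp(-dU/kT) >`, evaluated stably via log-sum-exp, with
#' standard errors from block averaging (default 10 contiguous blocks). A
#' zero perturbation returns exactly 0; a configuration-independent offset c
#' is recovered exactly. Poor phase-space overlap (variance of `dU` above
#' `overlap_tol` (kT)^2) raises an error advising a finer path.
#'
#' @param dU Per-configuration energy difference `U_to - U_from` (kcal/mol)
#'   over an ensemble sampled at the `from` state.
#' @param temperature Temperature (K).
#' @param n_blocks Number of blocks for the standard error.
#' @param overlap_tol Overlap guard on `var(dU) / (kT)^2`.
#' @return A one-row tibble: `dF`, `se`, `n`, `var_ratio`.
#' @export
#' @examples
#' fep_zwanzig(rep(1.5, 100))  # constant offset: dF = 1.5 exactly, se = 0
fep_zwanzig <- function(dU, temperature = 298.15, n_blocks = 10,
                        overlap_tol = 25) {
  stopifnot(length(dU) >= 1, all(is.finite(dU)))
  kT <- .consts$R_kcal * temperature
  vr <- if (length(dU) > 1) stats::var(dU) / kT^2 else 0
  if (vr > overlap_tol) {
    stop(sprintf(paste0("poor perturbation overlap: var(dU)/kT^2 = %.1f > ",
                        "%.0f; use more beads along the path"),
                 vr, overlap_tol))
  }
  est <- function(v) {
    z <- -v / kT
    m <- max(z)
    -kT * (m + log(mean(exp(z - m))))
  }
  dF <- est(dU)
  nb <- min(n_blocks, length(dU))
  se <- 0
  if (nb >= 2 && vr > 0) {
    idx <- cut(seq_along(dU), nb, labels = FALSE)
    bf <- vapply(split(dU, idx), est, numeric(1))
    se <- stats::sd(bf) / sqrt(nb)
  }
  tibble::tibble(dF = dF, se = se, n = length(dU), var_ratio = vr)
}

# deterministic fan-out of per-bead sampler seeds from one master seed
fanout_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sampled potential of mean force along a path
#'
#' For each bead, samples the solvent around the frozen solute at `level`,
#' then estimates the free-energy increment to the next bead by exponential
#' averaging of the perturbation `U(next bead) - U(this bead)` (coupling plus
#' the solute's internal energy change at `level`) within this bead's
#' ensemble. Increments are accumulated into a profile anchored at 0 on the
#' first (reactant) bead. With the coupling decoupled (zero charges and LJ)
#' the profile reduces exactly to the tier's gas-phase energy differences.
#'
#' @param path A relaxed `reaction_path` with a solute structure template.
#' @param box A `water_box` starting configuration.
#' @param solute A `surrogate_solute`.
#' @param level Theory tier sampled and perturbed (`"ESP"` for the cheap-tier
#'   PMF; `"HIGH"` gives the directly sampled high-tier PMF used as the
#'   composition oracle).
#' @param sampler A [sampler_config()]; per-bead seeds are fanned out from
#'   `sampler$seed`.
#' @param scheme An [embedding_scheme()].
#' @return An object of class `sampled_pmf`: tibble `profile` (bead,
#'   arc_length, dW cumulative, se), tibble `increments`, the per-bead
#'   ensembles, per-bead internal energies, and the inputs.
#' @export
sampled_pmf <- function(path, box, solute, level = c("ESP", "LOW", "HIGH"),
                        sampler = sampler_config(),
                        scheme = embedding_scheme()) {
  level <- match.arg(level)
  n <- nrow(path$coords)
  seeds <- fanout_seeds(sampler$seed, n)
  geoms <- lapply(seq_len(n), function(b)
    matrix(path$coords[b, ], ncol = 3, byrow = TRUE))
  e_int <- vapply(geoms, function(g)
    solute_energy(g, solute, level)$energy, numeric(1))
  scale <- solute$params$charge_scale[[level]]

  ensembles <- vector("list", n)
  self_parts <- vector("list", n)
  inc <- vector("list", n - 1)
  start_box <- box
  for (b in seq_len(n)) {
    cfg <- sampler
    cfg$seed <- seeds[b]
    ensembles[[b]] <- sample_solvent(start_box, solute, geoms[[b]], level,
                                     cfg, scheme)
    # warm-start the next bead from this bead's final configuration; the
    # solute moves little between adjacent beads, so equilibration is short
    start_box <- ensembles[[b]]$box
    self_parts[[b]] <- ensemble_coupling(ensembles[[b]], geoms[[b]], solute)
    if (b < n) {
      next_parts <- ensemble_coupling(ensembles[[b]], geoms[[b + 1]], solute)
      dU <- (coupling_cols(next_parts, scale) -
               coupling_cols(self_parts[[b]], scale)) +
        (e_int[b + 1] - e_int[b])
      z <- fep_zwanzig(dU, sampler$temperature)
      inc[[b]] <- tibble::tibble(from = b, to = b + 1, dW = z$dF, se = z$se,
                                 var_ratio = z$var_ratio)
    }
  }
  increments <- dplyr::bind_rows(inc)
  profile <- tibble::tibble(
    bead = seq_len(n),
    arc_length = path$arc_length,
    dW = c(0, cumsum(increments$dW)),
    se = c(0, sqrt(cumsum(increments$se^2)))
  )
  structure(list(profile = profile, increments = increments,
                 ensembles = ensembles, self_parts = self_parts,
                 internal = e_int, level = level, path = path,
                 solute = solute, sampler = sampler, scheme = scheme),
            class = "sampled_pmf")
}

coupling_cols <- function(parts, scale) {
  scale * parts[, 1] + parts[, 2] + parts[, 3]
}

#' Fixed-configuration free energy of shifting the theory tier
#'
#' Zwanzig estimate of the free-energy cost of switching the solute's tier
#' from `from` to `to` at a frozen solute configuration, over an ensemble
#' sampled at the `from` tier's coupling. The perturbation has a
#' configuration-independent part (the internal tier energy difference,
#' recovered exactly) and an ensemble-dependent part from the tier charge
#' scales.
#'
#' @param ensemble A `solvent_ensemble` sampled at the `from` tier around the
#'   same frozen geometry.
#' @param solute A `surrogate_solute`.
#' @param from,to Theory tiers.
#' @param geometry Solute geometry (defaults to the ensemble's).
#' @param parts Optional precomputed [ensemble_coupling] matrix.
#' @return A one-row tibble: `from`, `to`, `dW`, `se`, `var_ratio`.
#' @export
level_shift <- function(ensemble, solute, from = "ESP", to = "LOW",
                        geometry = NULL, parts = NULL) {
  lv <- c("ESP", "LOW", "HIGH")
  from <- match.arg(from, lv)
  to <- match.arg(to, lv)
  if (is.null(geometry)) geometry <- ensemble$geometry
  if (is.null(parts)) parts <- ensemble_coupling(ensemble, geometry, solute)
  s_from <- solute$params$charge_scale[[from]]
  s_to <- solute$params$charge_scale[[to]]
  d_int <- solute_energy(geometry, solute, to)$energy -
    solute_energy(geometry, solute, from)$energy
  dU <- d_int + (s_to - s_from) * parts[, 1]
  z <- fep_zwanzig(dU, ensemble$config$temperature)
  tibble::tibble(from = from, to = to, dW = z$dF, se = z$se,
                 var_ratio = z$var_ratio)
}

#' Compose a multi-level PMF from the cheap-tier profile and level shifts
#'
#' Implements the multi-level composition: the free-energy difference between
#' the reactant bead A and any bead B at the high tier equals the cheap-tier
#' (ESP) profile plus the differences, relative to the reactant bead, of the
#' fixed-configuration tier shifts ESP->LOW and LOW->HIGH. Shifts must be
#' available at every bead. With all shifts zero the composed profile equals
#' the ESP profile; bead-independent shifts cancel and leave the barrier
#' unchanged.
#'
#' @param esp A `sampled_pmf` at the ESP tier.
#' @param shifts_low Data frame of per-bead ESP->LOW shifts (columns `bead`,
#'   `dW`, `se`).
#' @param shifts_high Data frame of per-bead LOW->HIGH shifts.
#' @return An object of class `ml_pmf` whose `profile` tibble holds per-bead
#'   `dW_esp`, `shift_low`, `shift_high`, `dW_low`, `dW_high` and propagated
#'   standard errors.
#' @export
compose_pmf <- function(esp, shifts_low, shifts_high) {
  n <- nrow(esp$profile)
  for (nm in c("shifts_low", "shifts_high")) {
    sh <- get(nm)
    missing <- setdiff(seq_len(n), sh$bead)
    if (length(missing) > 0) {
      stop("missing ", nm, " at bead(s): ", paste(missing, collapse = ", "))
    }
  }
  sl <- shifts_low[match(seq_len(n), shifts_low$bead), ]
  sh <- shifts_high[match(seq_len(n), shifts_high$bead), ]
  prof <- esp$profile
  profile <- tibble::tibble(
    bead = prof$bead,
    arc_length = prof$arc_length,
    dW_esp = prof$dW,
    shift_low = sl$dW,
    shift_high = sh$dW,
    dW_low = prof$dW + (sl$dW - sl$dW[1]),
    dW_high = prof$dW + (sl$dW - sl$dW[1]) + (sh$dW - sh$dW[1]),
    se_esp = prof$se,
    se_low = sqrt(prof$se^2 + sl$se^2 + ifelse(prof$bead == 1, 0, sl$se[1]^2)),
    se_high = sqrt(prof$se^2 + sl$se^2 + sh$se^2 +
                     ifelse(prof$bead == 1, 0, sl$se[1]^2 + sh$se[1]^2))
  )
  structure(list(profile = profile, esp = esp,
                 shifts_low = sl, shifts_high = sh),
            class = "ml_pmf")
}

#' @describeIn compose_pmf Tidy per-bead profile table.
#' @param x An `ml_pmf`.
#' @param ... Unused.
#' @export
tidy.ml_pmf <- function(x, ...) x$profile

#' @describeIn compose_pmf Barrier (maximum bead relative to the reactant
#'   bead) and reaction free energy (product bead) per tier, with combined
#'   standard errors.
#' @export
glance.ml_pmf <- function(x, ...) {
  p <- x$profile
  per_level <- function(w, se, level) {
    ts <- which.max(w)
    tibble::tibble(level = level, barrier = w[ts], ts_bead = ts,
                   barrier_se = se[ts],
                   reaction_free_energy = w[length(w)],
                   reaction_se = se[length(w)])
  }
  dplyr::bind_rows(per_level(p$dW_esp, p$se_esp, "ESP"),
                   per_level(p$dW_low, p$se_low, "LOW"),
                   per_level(p$dW_high, p$se_high, "HIGH"))
}

#' Full multi-level PMF along a path
#'
#' Convenience driver: samples the ESP-tier PMF along the path, computes
#' ESP->LOW shifts in the ESP ensembles, samples LOW-tier ensembles for the
#' LOW->HIGH shifts, and composes the high-tier profile.
#'
#' @inheritParams sampled_pmf
#' @return An `ml_pmf` (see [compose_pmf()]); the LOW-tier ensembles are
#'   attached as `$low_ensembles` for reuse by [decompose_solvent()].
#' @export
multi_level_pmf <- function(path, box, solute, sampler = sampler_config(),
                            scheme = embedding_scheme()) {
  esp <- sampled_pmf(path, box, solute, "ESP", sampler, scheme)
  n <- nrow(path$coords)
  geoms <- lapply(seq_len(n), function(b)
    matrix(path$coords[b, ], ncol = 3, byrow = TRUE))

  shifts_low <- dplyr::bind_rows(lapply(seq_len(n), function(b) {
    dplyr::mutate(level_shift(esp$ensembles[[b]], solute, "ESP", "LOW",
                              geometry = geoms[[b]],
                              parts = esp$self_parts[[b]]),
                  bead = b)
  }))

  seeds <- fanout_seeds(sampler$seed + 1L, n)
  low_ens <- vector("list", n)
  low_parts <- vector("list", n)
  start_box <- box
  shifts_high <- dplyr::bind_rows(lapply(seq_len(n), function(b) {
    cfg <- sampler
    cfg$seed <- seeds[b]
    low_ens[[b]] <<- sample_solvent(start_box, solute, geoms[[b]], "LOW",
                                    cfg, scheme)
    start_box <<- low_ens[[b]]$box
    low_parts[[b]] <<- ensemble_coupling(low_ens[[b]], geoms[[b]], solute)
    dplyr::mutate(level_shift(low_ens[[b]], solute, "LOW", "HIGH",
                              geometry = geoms[[b]],
                              parts = low_parts[[b]]),
                  bead = b)
  }))

  out <- compose_pmf(esp, shifts_low, shifts_high)
  out$low_ensembles <- low_ens
  out$low_parts <- low_parts
  out
}

#' Solvent-energy / polarization decomposition of a composed PMF
#'
#' Per bead: the gas-phase profile is the solute's high-tier internal energy
#' on the same beads, referenced to the reactant bead; the polarization term
#' is the ensemble-average solute-solvent interaction energy (the internal
#' QM/MM energy minus the gas-phase energy); the aqueous contribution is the
#' composed PMF minus the gas-phase profile; and the solvent (free-)energy
#' contribution is defined by the bookkeeping identity
#' `aqueous = solvent_energy + net_polarization`, which therefore holds to
#' machine precision.
#'
#' @param pmf An `ml_pmf` from [multi_level_pmf()] (its LOW-tier ensembles
#'   supply the averages, evaluated at the HIGH charge scale).
#' @param solute A `surrogate_solute`.
#' @return A tibble of class `solvent_decomposition` with per-bead columns
#'   `gas`, `internal`, `polarization`, `net_polarization`, `aqueous`,
#'   `solvent_energy` (kcal/mol); use `glance()` for the totals at the
#'   transition-state and product beads.
#' @export
decompose_solvent <- function(pmf, solute) {
  if (is.null(pmf$low_ensembles)) {
    stop("pmf carries no sampled ensembles; build it with multi_level_pmf()")
  }
  p <- pmf$profile
  n <- nrow(p)
  path <- pmf$esp$path
  geoms <- lapply(seq_len(n), function(b)
    matrix(path$coords[b, ], ncol = 3, byrow = TRUE))
  e_gas <- vapply(geoms, function(g)
    solute_energy(g, solute, "HIGH")$energy, numeric(1))
  gas <- e_gas - e_gas[1]
  s_high <- solute$params$charge_scale[["HIGH"]]
  pol <- vapply(seq_len(n), function(b)
    mean(coupling_cols(pmf$low_parts[[b]], s_high)), numeric(1))
  out <- tibble::tibble(
    bead = p$bead,
    arc_length = p$arc_length,
    gas = gas,
    internal = gas + pol,
    polarization = pol,
    net_polarization = pol - pol[1],
    aqueous = p$dW_high - gas,
    solvent_energy = (p$dW_high - gas) - (pol - pol[1])
  )
  attr(out, "ts_bead") <- which.max(p$dW_high)
  class(out) <- c("solvent_decomposition", class(out))
  out
}

#' @describeIn decompose_solvent Net contributions at the transition-state
#'   and product beads.
#' @param x A `solvent_decomposition`.
#' @param ... Unused.
#' @export
glance.solvent_decomposition <- function(x, ...) {
  ts <- attr(x, "ts_bead")
  n <- nrow(x)
  tibble::tibble(
    state = c("transition_state", "product"),
    bead = c(ts, n),
    solvent_energy = x$solvent_energy[c(ts, n)],
    net_polarization = x$net_polarization[c(ts, n)],
    aqueous = x$aqueous[c(ts, n)]
  )
}

#' Aqueous contribution from solvent energy and polarization
#'
#' The bookkeeping sum used to report net solvation effects on a profile:
#' solvent-energy contribution plus net polarization (polarization at the
#' state minus polarization at the reactant).
#'
#' @param solvent_energy Solvent-energy contribution (kcal/mol).
#' @param polarization Polarization at the state of interest (kcal/mol).
#' @param polarization_reactant Polarization at the reactant (kcal/mol).
#' @return Net aqueous contribution (kcal/mol).
#' @export
#' @examples
#' aqueous_contribution(6.0, 8.7, 9.4)   # 5.3: barrier-height contribution
#' aqueous_contribution(27.9, 8.6, 9.4)  # 27.1: reaction-energy contribution
aqueous_contribution <- function(solvent_energy, polarization,
                                 polarization_reactant) {
  solvent_energy + (polarization - polarization_reactant)
}
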