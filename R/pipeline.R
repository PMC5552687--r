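# End-to-end pipeline: surrogate solute + water box -> NEB path -> sampled
# multi-level PMF -> solvent decomposition -> thermodynamic cycle -> TST
# rates, with recorded provenance.

#' Pipeline configuration
#'
#' Single configuration object for [run_pipeline()]; all randomness flows
#' from `seed`. The demo-scale defaults (64 waters in a 12.4 A cube, the
#' density of the reference 37.5 A / 1752-water setup) keep a full run in
#' minutes.
#'
#' @param seed Master seed.
#' @param n_waters,box_length Water count and cubic edge (A).
#' @param n_beads Path beads including endpoints.
#' @param cutoff QM/MM coupling cutoff (A).
#' @param neb A [neb_config()].
#' @param sampler A [sampler_config()] (its seed is overridden by `seed`).
#' @param solute_params A [solute_params()] list.
#' @param solvated_path Relax the path with waters frozen at an equilibrated
#'   snapshot (`TRUE`) or in the gas phase (`FALSE`).
#' @param cycle_inputs Named list or `NULL`: gas-phase barrier/reaction
#'   energy and the three solvation free energies for the thermodynamic
#'   cycle; defaults to the published reference values (continuum solvation
#'   energies are inputs, not computed here).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_waters = 64, box_length = 12.4,
                            n_beads = 10, cutoff = 15,
                            neb = neb_config(),
                            sampler = sampler_config(),
                            solute_params = mlpmf::solute_params(),
                            solvated_path = TRUE,
                            cycle_inputs = NULL) {
  if (is.null(cycle_inputs)) {
    cycle_inputs <- list(
      gas_barrier = reference_value("gas_barrier_high"),
      gas_reaction = reference_value("gas_reaction_high"),
      gsolv_reactant = reference_value("gsolv_reactant"),
      gsolv_ts = reference_value("gsolv_ts"),
      gsolv_product = reference_value("gsolv_product")
    )
  }
  structure(list(seed = seed, n_waters = n_waters, box_length = box_length,
                 n_beads = n_beads, cutoff = cutoff, neb = neb,
                 sampler = sampler, solute_params = solute_params,
                 solvated_path = solvated_path, cycle_inputs = cycle_inputs),
            class = "pipeline_config")
}

#' Run the full multi-level PMF pipeline
#'
#' Executes, in order: surrogate solute construction; seeded water-box
#' generation; a brief solvent pre-equilibration around the reactant;
#' NEB path relaxation (frozen-solvent by default); ESP-tier PMF sampling
#' with tier shifts and composition to the HIGH tier; solvent/polarization
#' decomposition; thermodynamic-cycle composition on the configured inputs;
#' and TST rate constants for the gas and solution barriers. Deterministic
#' given the seed -- a rerun reproduces the report bitwise.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: the fitted objects plus tidy
#'   summary tibbles and a provenance block (seed, config hash, package
#'   version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  # validate the configuration before any computation starts
  ci <- config$cycle_inputs
  if (!all(vapply(ci, function(v) is.numeric(v) && is.finite(v), TRUE))) {
    stop("invalid pipeline config: cycle inputs must all be finite numbers")
  }
  if (config$n_beads < 3) stop("invalid pipeline config: n_beads must be >= 3")

  stages <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  solute <- stages("solute", generate_solute(params = config$solute_params))
  box <- stages("box", generate_box(n = config$n_waters,
                                    L = config$box_length,
                                    seed = config$seed))
  scheme <- embedding_scheme(cutoff = config$cutoff)
  sampler <- config$sampler
  sampler$seed <- config$seed

  # center the solute in the box
  ctr <- colMeans(coord_matrix(solute$geometry$reactant))
  shift <- rep(config$box_length / 2, 3) - ctr
  geom_r <- sweep(coord_matrix(solute$geometry$reactant), 2, -shift)
  geom_p <- sweep(coord_matrix(solute$geometry$product), 2, -shift)

  path0 <- interpolate_path(
    set_coords(solute$geometry$reactant, geom_r),
    set_coords(solute$geometry$product, geom_p),
    n = config$n_beads)
  # clear solvent along the whole swept path, not just the endpoints
  box <- carve_box(box, matrix(as.numeric(t(path0$coords)), ncol = 3,
                               byrow = TRUE))

  path <- stages("neb", {
    if (config$solvated_path) {
      pre_cfg <- sampler
      pre_cfg$prod <- pre_cfg$stride  # single snapshot
      pre <- sample_solvent(box, solute, geom_r, "LOW", pre_cfg, scheme)
      snapshot <- pre$box
      neb_relax(path0, potential_qmmm(solute, "LOW", snapshot, scheme),
                config$neb)
    } else {
      neb_relax(path0, potential_solute(solute, "LOW"), config$neb)
    }
  })

  pmf <- stages("pmf", multi_level_pmf(path, box, solute, sampler, scheme))
  decomp <- stages("decompose", decompose_solvent(pmf, solute))
  cyc <- stages("cycle", do.call(cycle_compose, config$cycle_inputs))
  rates <- stages("rate", dplyr::bind_rows(
    dplyr::mutate(tst_rate(cyc$gas_barrier), phase = "gas"),
    dplyr::mutate(tst_rate(cyc$solution_barrier), phase = "solution")
  ))
  ratio <- rate_ratio_orders(cyc$gas_barrier, cyc$solution_barrier)

  report <- structure(list(
    solute = solute,
    path = path,
    pmf = pmf,
    decomposition = decomp,
    cycle = cyc,
    rates = rates,
    rate_ratio = ratio,
    path_summary = glance(path),
    pmf_summary = glance(pmf),
    decomposition_summary = glance(decomp),
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(config),
                      n_waters = config$n_waters,
                      n_beads = config$n_beads,
                      package_version = as.character(
                        utils::packageVersion("mlpmf")))
  ), class = "run_report")
  report
}

#' Write the report artifacts of a pipeline run
#'
#' Writes the per-bead PMF profile and decomposition as CSV, the relaxed
#' path as multi-frame XYZ, and a JSON summary (barriers, reaction free
#' energies, cycle, rates, provenance) into a directory.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tidy(report$pmf), file.path(dir, "pmf_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(tibble::as_tibble(report$decomposition),
                   file.path(dir, "solvent_decomposition.csv"),
                   row.names = FALSE)
  write_path_xyz(report$path, file.path(dir, "path.xyz"))
  summary <- list(
    pmf = report$pmf_summary,
    decomposition = report$decomposition_summary,
    cycle = report$cycle,
    rates = report$rates,
    rate_ratio = report$rate_ratio,
    units = list(energy = "kcal/mol", length = "A",
                 rate = "cm^3/molecule/s"),
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Multi-level PMF pipeline run (seed", x$provenance$seed, ")\n\n")
  cat("Path:", x$path_summary$n_beads, "beads, barrier",
      sprintf("%.2f", x$path_summary$barrier), "kcal/mol on the relaxed",
      "path,", ifelse(isTRUE(x$path_summary$converged), "converged",
                      "NOT converged"), "\n")
  cat("\nPMF (kcal/mol):\n")
  print(x$pmf_summary)
  cat("\nSolvent decomposition (kcal/mol):\n")
  print(x$decomposition_summary)
  cat("\nThermodynamic cycle (kcal/mol):\n")
  print(tibble::as_tibble(x$cycle))
  cat("\nTST rates (cm^3/molecule/s):\n")
  print(x$rates[, c("phase", "barrier", "rate", "order_of_magnitude")])
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()], with optional `sampler` and `neb` sections passed to
#' [sampler_config()] and [neb_config()] and an optional `cycle_inputs`
#' section. Unknown keys raise an error so typos fail fast.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "n_waters", "box_length", "n_beads", "cutoff",
             "sampler", "neb", "solute_params", "solvated_path",
             "cycle_inputs")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$sampler)) y$sampler <- do.call(sampler_config, y$sampler)
  if (!is.null(y$neb)) y$neb <- do.call(neb_config, y$neb)
  if (!is.null(y$solute_params)) {
    y$solute_params <- do.call(solute_params, y$solute_params)
  }
  do.call(pipeline_config, y)
}
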