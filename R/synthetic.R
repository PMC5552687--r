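# Fixture generators and reference tables: perturbed geometries for
# comparison statistics, and the published reference values for the
# 8-hydroxyguanine-radical ring opening used as worked-example inputs.

#' Perturb a structure with Gaussian coordinate noise
#'
#' Adds independent normal noise of standard deviation `magnitude` to every
#' Cartesian coordinate. Deterministic given `seed`; magnitude 0 is the
#' identity. Per-atom displacements follow a chi distribution with 3 degrees
#' of freedom, so the expected RMSD is close to `magnitude * sqrt(3)`.
#'
#' @param structure A structure tibble.
#' @param magnitude Noise standard deviation per coordinate (A).
#' @param seed Integer seed.
#' @return The perturbed structure tibble.
#' @export
perturb_structure <- function(structure, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(structure)
  set.seed(seed)
  m <- coord_matrix(structure)
  set_coords(structure, m + matrix(stats::rnorm(length(m), 0, magnitude),
                                   nrow(m), 3))
}

#' Published reference tables for the ring-opening worked examples
#'
#' Small versioned tables of published reference values for the ring opening
#' of the 8-hydroxyguanine radical (8-OHGrad) to the formimidic acid radical:
#' transition-state internal coordinates under two basis sets, stationary-
#' point internal coordinates in gas and solution phase, and the reported
#' energies, solvation free energies and decomposition terms. These are
#' inputs to the worked examples (the package does not recompute electronic
#' structure); every entry carries a non-empty `source` label describing the
#' state and conditions it was reported for.
#'
#' @param name One of `"ts_basis_coords"`, `"stationary_coords"`,
#'   `"energies"`.
#' @return A tibble.
#' @export
#' @examples
#' reference_table("energies")
reference_table <- function(name = c("ts_basis_coords", "stationary_coords",
                                     "energies")) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0(name, ".csv"), package = "mlpmf",
                      mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
  stopifnot(all(nzchar(out$source)))
  out
}

#' Reference energy value by name
#'
#' @param quantity Quantity name in the `"energies"` reference table.
#' @return The value (kcal/mol unless the table's unit column says
#'   otherwise).
#' @export
reference_value <- function(quantity) {
  tab <- reference_table("energies")
  i <- match(quantity, tab$quantity)
  if (is.na(i)) {
    stop("unknown reference quantity: ", quantity, "; available: ",
         paste(tab$quantity, collapse = ", "))
  }
  tab$value[i]
}
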