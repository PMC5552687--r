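# QM/MM energy composition with electrostatic embedding:
#   V_potential = V_qm + V_qm/mm + V_mm
# The coupling term uses the full electrostatics plus Lennard-Jones inside a
# hard cutoff around the QM region and ESP-charge-only Coulomb outside it.
# The cutoff is group-based: a water molecule is inside when its oxygen lies
# strictly within the cutoff of the nearest QM atom, so molecules are never
# split across the boundary.

#' Embedding scheme for the QM/MM coupling
#'
#' @param cutoff Coupling cutoff radius around the QM region (A, default 15).
#'   Inside: Coulomb + van der Waals; outside: Coulomb between the MM charges
#'   and the QM ESP charges only. The boundary tie-break is strict
#'   (`r < cutoff` is inside).
#' @return A list of class `embedding_scheme`.
#' @export
embedding_scheme <- function(cutoff = 15) {
  if (!is.finite(cutoff) && !identical(cutoff, Inf)) {
    stop("cutoff must be positive (possibly Inf)")
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff), class = "embedding_scheme")
}

# mixed solute-water(O) Lennard-Jones parameters (Lorentz-Berthelot)
mix_lj <- function(solute, params) {
  if (anyNA(solute$atoms$sigma) || anyNA(solute$atoms$eps)) {
    bad <- solute$atoms$name[is.na(solute$atoms$sigma) |
                               is.na(solute$atoms$eps)]
    stop("missing Lennard-Jones parameters for QM atom(s): ",
         paste(bad, collapse = ", "))
  }
  list(sigma = (solute$atoms$sigma + params$sigma) / 2,
       eps = sqrt(solute$atoms$eps * params$eps))
}

# raw coupling terms at the bare (unit-scale) interpolated ESP charge set;
# callers apply the tier charge scale to the inside Coulomb part
coupling_parts <- function(x, solute, sites, scheme,
                           params = water_params()) {
  lj <- mix_lj(solute, params)
  q <- solute_charges(x, solute, level = "ESP")
  coupling_parts_cpp(x, q, lj$sigma, lj$eps, sites,
                     params$qO, params$qH, scheme$cutoff)
}

coupling_from_parts <- function(parts, scale) {
  unname(scale * parts["coul_in"] + parts["lj_in"] + parts["coul_out"])
}

#' QM/MM coupling energy
#'
#' Energy of interaction between the QM solute and the MM waters under an
#' embedding scheme: inside the cutoff, Coulomb (tier-scaled conformational
#' ESP charges) plus Lennard-Jones with Lorentz-Berthelot mixing against the
#' water oxygen; outside, Coulomb with the bare ESP charges only.
#'
#' @param structure Solute structure tibble or coordinate matrix (solute atom
#'   order).
#' @param solute A `surrogate_solute` (carries charges and LJ parameters).
#' @param box A `water_box`.
#' @param scheme An [embedding_scheme()].
#' @param level Theory tier whose charge scale applies inside the cutoff.
#' @return A list with `energy` and the split `coul_in`, `lj_in`, `coul_out`
#'   (all kcal/mol) and `n_inside` (molecules inside the cutoff).
#' @export
coupling_energy <- function(structure, solute, box, scheme = embedding_scheme(),
                            level = c("ESP", "LOW", "HIGH")) {
  level <- match.arg(level)
  x <- if (is.data.frame(structure)) coord_matrix(structure) else structure
  parts <- coupling_parts(x, solute, box$sites, scheme, box$params)
  s <- solute$params$charge_scale[[level]]
  list(energy = coupling_from_parts(parts, s),
       coul_in = unname(s * parts["coul_in"]),
       lj_in = unname(parts["lj_in"]),
       coul_out = unname(parts["coul_out"]),
       n_inside = unname(parts["n_in"]),
       level = level)
}

#' Compose the QM/MM energy decomposition
#'
#' Evaluates the three terms of the embedded QM/MM potential at a theory
#' tier and returns them with their sum; the additivity
#' `V_total = V_qm + V_qmmm + V_mm` holds to machine precision by
#' construction and is the tested invariant.
#'
#' @param structure Solute structure tibble or coordinate matrix.
#' @param solute A `surrogate_solute`.
#' @param box A `water_box`.
#' @param scheme An [embedding_scheme()].
#' @param level Theory tier (`"ESP"`, `"LOW"`, `"HIGH"`).
#' @param mm_cutoff Truncation for the water-water sum (A; default none).
#' @return A one-row tibble of class `energy_decomposition` with columns
#'   `level`, `V_qm`, `V_qmmm`, `V_mm`, `V_total` (kcal/mol).
#' @export
#' @examples
#' sol <- generate_solute()
#' box <- generate_box(n = 8, L = 8, seed = 2)
#' compose_energy(sol$geometry$reactant, sol, box)
compose_energy <- function(structure, solute, box,
                           scheme = embedding_scheme(),
                           level = c("ESP", "LOW", "HIGH"),
                           mm_cutoff = Inf) {
  level <- match.arg(level)
  v_qm <- solute_energy(structure, solute, level)$energy
  v_qmmm <- coupling_energy(structure, solute, box, scheme, level)$energy
  v_mm <- water_mm_energy(box, cutoff = mm_cutoff)$energy
  out <- tibble::tibble(level = level, V_qm = v_qm, V_qmmm = v_qmmm,
                        V_mm = v_mm, V_total = v_qm + v_qmmm + v_mm)
  class(out) <- c("energy_decomposition", class(out))
  out
}

#' @describeIn solute_energy Potential for the solute coupled to a frozen
#'   water snapshot (internal tier energy plus QM/MM coupling); the coupling
#'   gradient is obtained by central differences on the solute coordinates.
#' @param box A `water_box` snapshot (waters held fixed).
#' @param scheme An [embedding_scheme()].
#' @export
potential_qmmm <- function(solute, level = c("ESP", "LOW", "HIGH"),
                           box, scheme = embedding_scheme()) {
  level <- match.arg(level)
  n <- nrow(solute$atoms)
  s <- solute$params$charge_scale[[level]]
  couple <- function(x) {
    parts <- coupling_parts(matrix(x, ncol = 3, byrow = TRUE), solute,
                            box$sites, scheme, box$params)
    coupling_from_parts(parts, s)
  }
  f <- function(x) {
    solute_internal(matrix(x, ncol = 3, byrow = TRUE), solute, level)$energy +
      couple(x)
  }
  g <- function(x) {
    solute_internal(matrix(x, ncol = 3, byrow = TRUE), solute, level,
                    gradient = TRUE)$gradient + num_gradient(couple, x)
  }
  new_potential(f, g, dim = 3 * n,
                label = paste0("QM/MM frozen-solvent (", level, ")"),
                masses = rep(solute$atoms$mass, each = 3))
}
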