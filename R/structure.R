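#' Build a molecular structure table
#'
#' A structure is an ordinary tibble with one row per atom and columns
#' `name` (site label, e.g. `"C8"`), `element`, Cartesian coordinates
#' `x`, `y`, `z` in Angstrom, an optional partial `charge` in units of the
#' elementary charge, and a `region` tag (`"QM"` or `"MM"`). All package
#' functions that consume structures take such a data frame as their first
#' argument, so they compose with dplyr verbs and the pipe.
#'
#' @param name Character vector of site labels. If `element` is missing it is
#'   derived from the leading letters of `name`.
#' @param x,y,z Numeric coordinate vectors (Angstrom).
#' @param element Character vector of element symbols (optional).
#' @param charge Numeric partial charges in e (optional, default `NA`).
#' @param region Region tag per atom, `"QM"` or `"MM"`.
#' @return A tibble with columns `name`, `element`, `x`, `y`, `z`, `charge`,
#'   `region`.
#' @export
#' @examples
#' mol_structure(c("O1", "H1", "H2"),
#'               x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0)
mol_structure <- function(name, x, y, z, element = NULL, charge = NA_real_,
                          region = "QM") {
  if (is.null(element)) {
    element <- sub("^([A-Za-z]+).*$", "\\1", name)
    # two-letter symbols keep their case; single letters are upper-cased
    element <- ifelse(nchar(element) > 2, substr(element, 1, 2), element)
    element <- paste0(toupper(substr(element, 1, 1)),
                      tolower(substr(element, 2, nchar(element))))
  }
  out <- tibble::tibble(name = as.character(name),
                        element = as.character(element),
                        x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                        charge = as.numeric(charge),
                        region = as.character(region))
  validate_structure(out)
  out
}

#' Validate a structure table
#'
#' Checks the structure invariants: required columns present, finite
#' coordinates, and a region tag (`"QM"`/`"MM"`) on every atom.
#'
#' @param structure A structure tibble (see [mol_structure()]).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_structure <- function(structure) {
  req <- c("name", "element", "x", "y", "z")
  missing <- setdiff(req, names(structure))
  if (length(missing) > 0) {
    stop("structure is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(structure) == 0) stop("structure has no atoms")
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("structure has non-finite coordinates")
  if ("region" %in% names(structure)) {
    bad <- !structure$region %in% c("QM", "MM")
    if (any(bad)) {
      stop("atoms with invalid region tag: ",
           paste(structure$name[bad], collapse = ", "))
    }
  }
  invisible(structure)
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure A structure tibble.
#' @return An n x 3 numeric matrix of Cartesian coordinates (Angstrom), with
#'   row names taken from the atom names.
#' @export
coord_matrix <- function(structure) {
  m <- as.matrix(structure[, c("x", "y", "z")])
  rownames(m) <- structure$name
  m
}

#' Replace the coordinates of a structure
#'
#' @param structure A structure tibble.
#' @param coords An n x 3 matrix, or a length-3n numeric vector in atom order.
#' @return The structure with updated `x`, `y`, `z`.
#' @export
set_coords <- function(structure, coords) {
  if (is.numeric(coords) && is.null(dim(coords))) {
    coords <- matrix(coords, ncol = 3, byrow = TRUE)
  }
  stopifnot(nrow(coords) == nrow(structure))
  structure$x <- unname(coords[, 1])
  structure$y <- unname(coords[, 2])
  structure$z <- unname(coords[, 3])
  structure
}

#' Partition a system into its QM and MM subsets
#'
#' Splits a tagged structure into the quantum (solute) and molecular-mechanics
#' (solvent) regions. The two subsets are disjoint and exhaustive.
#'
#' @param structure A structure tibble with a `region` column.
#' @return A list with elements `qm` and `mm`, each a structure tibble.
#' @export
#' @examples
#' s <- mol_structure(c("C1", "O1"), x = c(0, 1.2), y = 0, z = 0,
#'                    region = c("QM", "MM"))
#' partition_system(s)
partition_system <- function(structure) {
  if (nrow(structure) == 0) stop("cannot partition an empty system")
  if (!"region" %in% names(structure) || anyNA(structure$region)) {
    stop("all atoms must carry a region tag (\"QM\" or \"MM\")")
  }
  validate_structure(structure)
  list(qm = structure[structure$region == "QM", ],
       mm = structure[structure$region == "MM", ])
}

atom_index <- function(structure, names) {
  i <- match(names, structure$name)
  if (anyNA(i)) {
    stop("unknown atom site name(s): ",
         paste(names[is.na(i)], collapse = ", "))
  }
  i
}
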