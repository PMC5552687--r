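# Internal-coordinate measurement, hydrogen-bond detection, and
# geometry-comparison statistics.

vnorm <- function(v) sqrt(sum(v * v))

#' Measure a bond length
#'
#' @param structure A structure tibble.
#' @param a,b Atom site names.
#' @return Euclidean distance in Angstrom.
#' @export
bond_length <- function(structure, a, b) {
  i <- atom_index(structure, c(a, b))
  if (i[1] == i[2]) stop("bond requires two distinct atoms")
  m <- coord_matrix(structure)
  vnorm(m[i[1], ] - m[i[2], ])
}

#' Measure a bond angle
#'
#' Interior angle at the middle atom `b`, in degrees within `[0, 180]`.
#'
#' @param structure A structure tibble.
#' @param a,b,c Atom site names; `b` is the vertex.
#' @return Angle in degrees.
#' @export
bond_angle <- function(structure, a, b, c) {
  i <- atom_index(structure, c(a, b, c))
  if (anyDuplicated(i)) stop("angle requires three distinct atoms")
  m <- coord_matrix(structure)
  u <- m[i[1], ] - m[i[2], ]
  v <- m[i[3], ] - m[i[2], ]
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Measure a torsion (dihedral) angle
#'
#' Signed torsion about the `b`--`c` axis with the IUPAC sign convention
#' (positive for a clockwise rotation of `c`--`d` relative to `a`--`b` when
#' viewed from `b` toward `c`); range `(-180, 180]`, with cis = 0 and
#' trans = 180. Collinear inner atoms make the torsion undefined and raise an
#' error.
#'
#' @param structure A structure tibble.
#' @param a,b,c,d Atom site names defining the torsion.
#' @return Dihedral angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(structure, a, b, c, d) {
  i <- atom_index(structure, c(a, b, c, d))
  if (anyDuplicated(i)) stop("dihedral requires four distinct atoms")
  m <- coord_matrix(structure)
  b1 <- m[i[2], ] - m[i[1], ]
  b2 <- m[i[3], ] - m[i[2], ]
  b3 <- m[i[4], ] - m[i[3], ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate dihedral: three collinear atoms among ",
         paste(c(a, b, c, d), collapse = "-"))
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  phi <- atan2(y, x) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Measure a set of internal coordinates
#'
#' Vectorised driver over a coordinate specification table. Bond values are in
#' Angstrom; angles and dihedrals in degrees.
#'
#' @param structure A structure tibble.
#' @param specs A data frame with columns `kind` (`"bond"`, `"angle"` or
#'   `"dihedral"`), `a1`..`a4` (site names; unused slots `NA`), and optionally
#'   `label`. A missing `label` is built by pasting the site names.
#' @return The spec tibble with added columns `value` and `unit`.
#' @export
#' @examples
#' s <- mol_structure(c("A", "B", "C"), x = c(1, 0, 0), y = c(0, 0, 1), z = 0)
#' measure_internal(s, tibble::tibble(kind = "angle",
#'                                    a1 = "A", a2 = "B", a3 = "C", a4 = NA))
measure_internal <- function(structure, specs) {
  specs <- tibble::as_tibble(specs)
  if (!"a4" %in% names(specs)) specs$a4 <- NA_character_
  if (!"label" %in% names(specs)) {
    specs$label <- apply(specs[, c("a1", "a2", "a3", "a4")], 1, function(r) {
      paste(stats::na.omit(r), collapse = "-")
    })
  }
  specs$value <- purrr::pmap_dbl(
    specs[, c("kind", "a1", "a2", "a3", "a4")],
    function(kind, a1, a2, a3, a4) {
      switch(kind,
        bond = bond_length(structure, a1, a2),
        angle = bond_angle(structure, a1, a2, a3),
        dihedral = dihedral_angle(structure, a1, a2, a3, a4),
        stop("unknown coordinate kind: ", kind)
      )
    }
  )
  specs$unit <- ifelse(specs$kind == "bond", "A", "deg")
  specs
}

#' Infer covalent connectivity from interatomic distances
#'
#' Two atoms are bonded when their distance is below `scale` times the sum of
#' their covalent radii. Used when no topology is supplied (e.g. hydrogen-bond
#' donor detection).
#'
#' @param structure A structure tibble.
#' @param scale Distance threshold multiplier (default 1.2).
#' @return A tibble with columns `i`, `j` (row indices, `i < j`), `name_i`,
#'   `name_j`, `distance`.
#' @export
infer_bonds <- function(structure, scale = 1.2) {
  m <- coord_matrix(structure)
  n <- nrow(m)
  r <- covalent_radius(structure$element)
  out <- list()
  if (n >= 2) {
    d <- as.matrix(stats::dist(m))
    thr <- outer(r, r, "+") * scale
    hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
    out <- tibble::tibble(i = hit[, 1], j = hit[, 2],
                          name_i = structure$name[hit[, 1]],
                          name_j = structure$name[hit[, 2]],
                          distance = d[hit])
  } else {
    out <- tibble::tibble(i = integer(), j = integer(),
                          name_i = character(), name_j = character(),
                          distance = numeric())
  }
  out
}

#' Detect hydrogen bonds by geometric criteria
#'
#' A hydrogen bond is reported for every donor--H / acceptor triple whose
#' H...acceptor distance is at most `d_max` and whose donor--H...acceptor
#' angle is at least `angle_min`. Donors are N--H and O--H groups (optionally
#' C--H) identified from inferred covalent connectivity; acceptors are N and O
#' atoms not covalently bound to the hydrogen. The mean H...acceptor distance
#' is attached as attribute `mean_distance`.
#'
#' @param structure A structure tibble.
#' @param d_max Maximum H...acceptor distance in Angstrom (default 3.0).
#' @param angle_min Minimum donor--H...acceptor angle in degrees (default 120).
#' @param include_ch Also treat C--H groups as donors (default `FALSE`).
#' @param bond_scale Covalent-connectivity threshold multiplier passed to
#'   [infer_bonds()].
#' @return A tibble with columns `donor`, `hydrogen`, `acceptor`, `distance`
#'   (H...A, Angstrom), `angle` (D-H...A, degrees), with attribute
#'   `mean_distance`. Missing hydrogens yield an empty result and a warning.
#' @export
detect_hbonds <- function(structure, d_max = 3.0, angle_min = 120,
                          include_ch = FALSE, bond_scale = 1.2) {
  empty <- tibble::tibble(donor = character(), hydrogen = character(),
                          acceptor = character(), distance = numeric(),
                          angle = numeric())
  if (!any(structure$element == "H")) {
    warning("structure contains no hydrogen atoms; no hydrogen bonds detected")
    attr(empty, "mean_distance") <- NaN
    return(empty)
  }
  bonds <- infer_bonds(structure, scale = bond_scale)
  donor_elems <- c("N", "O", if (include_ch) "C")
  # donor-H pairs from connectivity (either orientation in the bond table)
  el <- structure$element
  dh <- rbind(
    data.frame(d = bonds$i[el[bonds$i] %in% donor_elems & el[bonds$j] == "H"],
               h = bonds$j[el[bonds$i] %in% donor_elems & el[bonds$j] == "H"]),
    data.frame(d = bonds$j[el[bonds$j] %in% donor_elems & el[bonds$i] == "H"],
               h = bonds$i[el[bonds$j] %in% donor_elems & el[bonds$i] == "H"])
  )
  acceptors <- which(el %in% c("N", "O"))
  m <- coord_matrix(structure)
  res <- list()
  for (k in seq_len(nrow(dh))) {
    d <- dh$d[k]; h <- dh$h[k]
    # exclude the donor itself and anything covalently bound to this hydrogen
    bound_to_h <- c(bonds$i[bonds$j == h], bonds$j[bonds$i == h])
    for (a in setdiff(acceptors, c(d, bound_to_h))) {
      dist_ha <- vnorm(m[h, ] - m[a, ])
      if (dist_ha > d_max) next
      u <- m[d, ] - m[h, ]
      v <- m[a, ] - m[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
      if (ang < angle_min) next
      res[[length(res) + 1]] <- tibble::tibble(
        donor = structure$name[d], hydrogen = structure$name[h],
        acceptor = structure$name[a], distance = dist_ha, angle = ang)
    }
  }
  out <- if (length(res) > 0) dplyr::bind_rows(res) else empty
  attr(out, "mean_distance") <- if (nrow(out) > 0) mean(out$distance) else NaN
  out
}

# minimal angular distance for periodic quantities, degrees; never exceeds 180
wrap_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Compare two sets of internal coordinates
#'
#' Pairs coordinates by `(kind, label)`, takes per-pair absolute differences
#' (minimal wrapped angular distance for angles and dihedrals, so a difference
#' never exceeds 180 degrees), and summarises the unsigned mean difference per
#' coordinate kind. Use [generics::glance()] on the result for the per-kind
#' means.
#'
#' @param ref,alt Data frames with columns `kind`, `label`, `value` (e.g. from
#'   [measure_internal()] or a reference table). Unmatched entries raise an
#'   error listing them.
#' @return A tibble of class `geom_diff` with columns `kind`, `label`,
#'   `value_ref`, `value_alt`, `abs_diff`.
#' @export
#' @examples
#' ref <- tibble::tibble(kind = "bond", label = c("N7-C8", "C8-N9"),
#'                       value = c(1.358, 2.014))
#' alt <- tibble::tibble(kind = "bond", label = c("N7-C8", "C8-N9"),
#'                       value = c(1.336, 2.103))
#' glance(compare_geometries(ref, alt))
compare_geometries <- function(ref, alt) {
  ref <- tibble::as_tibble(ref)[, c("kind", "label", "value")]
  alt <- tibble::as_tibble(alt)[, c("kind", "label", "value")]
  key_r <- paste(ref$kind, ref$label)
  key_a <- paste(alt$kind, alt$label)
  unmatched <- c(setdiff(key_r, key_a), setdiff(key_a, key_r))
  if (length(unmatched) > 0) {
    stop("unmatched coordinate spec(s): ", paste(unmatched, collapse = "; "))
  }
  alt <- alt[match(key_r, key_a), ]
  out <- tibble::tibble(
    kind = ref$kind, label = ref$label,
    value_ref = ref$value, value_alt = alt$value,
    abs_diff = ifelse(ref$kind == "bond",
                      abs(ref$value - alt$value),
                      wrap_angle_diff(ref$value, alt$value))
  )
  class(out) <- c("geom_diff", class(out))
  out
}

#' @describeIn compare_geometries Unsigned mean difference per coordinate kind.
#' @param x A `geom_diff` tibble.
#' @param ... Unused.
#' @export
glance.geom_diff <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$kind),
                   n = dplyr::n(),
                   mean_abs_diff = mean(.data$abs_diff),
                   max_abs_diff = max(.data$abs_diff),
                   .groups = "drop")
}
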