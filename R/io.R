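# Readers and writers for XYZ and PDB structure files. XYZ is parsed directly
# (count / comment / element x y z records, with line-numbered errors); PDB
# records are handled by bio3d behind this interface after a light pre-scan
# that attributes malformed records to their line numbers.

#' Read an XYZ file
#'
#' Parses the plain XYZ format: an atom count line, a comment line, then one
#' `element x y z` record per atom (Angstrom). Multi-frame files are accepted;
#' by default the first frame is returned.
#'
#' @param path Path to the file.
#' @param frame Frame number to return (1-based).
#' @return A structure tibble; the comment line is attached as attribute
#'   `comment`. Atom names are `element + index`.
#' @export
read_xyz <- function(path, frame = 1) {
  frames <- read_xyz_frames(path)
  if (frame > length(frames)) {
    stop("requested frame ", frame, " but file has ", length(frames))
  }
  frames[[frame]]
}

#' @describeIn read_xyz Read every frame of a multi-frame XYZ file; returns a
#'   list of structure tibbles.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty XYZ file: ", path)
  }
  frames <- list()
  ln <- 1
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n <= 0) {
      stop("malformed XYZ atom count at line ", ln, ": '", lines[ln], "'")
    }
    if (ln + 1 + n > length(lines)) {
      stop("truncated XYZ frame starting at line ", ln,
           " (expected ", n, " atom records)")
    }
    comment <- lines[ln + 1]
    rec <- lines[ln + 2:(n + 1)]
    parts <- strsplit(trimws(rec), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad) > 0) {
      stop("malformed XYZ atom record at line ", ln + 1 + bad[1], ": '",
           rec[bad[1]], "'")
    }
    el <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                    numeric(3)))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1, any))[1]
      stop("non-numeric coordinate in XYZ record at line ", ln + 1 + bad)
    }
    s <- mol_structure(name = paste0(el, seq_len(n)), element = el,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    attr(s, "comment") <- comment
    frames[[length(frames) + 1]] <- s
    ln <- ln + 2 + n
  }
  frames
}

#' Write structures to an XYZ file
#'
#' @param structure A structure tibble, or a list of them (multi-frame).
#' @param path Output path.
#' @param comment Comment line(s); recycled over frames.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = "") {
  frames <- if (is.data.frame(structure)) list(structure) else structure
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    s <- frames[[k]]
    validate_structure(s)
    writeLines(c(as.character(nrow(s)), comment[k]), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                       s$element, s$x, s$y, s$z), con)
  }
  invisible(path)
}

#' Read a PDB file
#'
#' Reads `ATOM`/`HETATM` records into a structure tibble. When alternate
#' locations are present the first altloc is kept and a warning is issued.
#' Malformed coordinate fields are reported with their line number.
#'
#' @param path Path to the file.
#' @return A structure tibble with atom names taken from the PDB atom-name
#'   column; `region` defaults to `"MM"` for water residues (HOH/WAT/SPC) and
#'   `"QM"` otherwise.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty PDB file: ", path)
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in PDB file: ", path)
  for (ln in which(is_atom)) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
      substr(lines[ln], 47, 54))))
    if (anyNA(coords)) {
      stop("malformed PDB coordinate field at line ", ln, ": '", lines[ln], "'")
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    keep_alt <- sort(unique(at$alt[nzchar(at$alt) & !is.na(at$alt)]))[1]
    warning("alternate locations present; keeping altloc '", keep_alt, "'")
    at <- at[is.na(at$alt) | !nzchar(at$alt) | at$alt == keep_alt, ]
  }
  el <- at$elesy
  if (is.null(el) || all(!nzchar(trimws(el)))) {
    el <- sub("^[0-9]*([A-Za-z]).*$", "\\1", trimws(at$elety))
  }
  el <- trimws(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
  region <- ifelse(toupper(trimws(at$resid)) %in% c("HOH", "WAT", "SPC", "SOL"),
                   "MM", "QM")
  mol_structure(name = trimws(at$elety), element = el,
                x = at$x, y = at$y, z = at$z, region = region)
}

#' Write a structure to a PDB file
#'
#' Fixed-column `ATOM` records via bio3d. Atoms are written as a single
#' residue unless a `resno` column is present in the structure.
#'
#' @param structure A structure tibble.
#' @param path Output path.
#' @param resid Residue name to use (default `"MOL"`; `"HOH"` is conventional
#'   for water).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, resid = "MOL") {
  validate_structure(structure)
  n <- nrow(structure)
  resno <- if ("resno" %in% names(structure)) structure$resno else rep(1L, n)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coord_matrix(structure))),
                   resno = resno,
                   resid = rep_len(resid, n),
                   eleno = seq_len(n),
                   elety = structure$name,
                   elesy = structure$element)
  invisible(path)
}
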