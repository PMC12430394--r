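# Molecular geometries: construction, XYZ I/O, fragment detection.

#' Create a molecular geometry
#'
#' A geometry holds element symbols, Cartesian coordinates in bohr, the
#' total charge and (optionally) a fragment label per atom.  All package
#' functions operate in atomic units; use [read_xyz()] to convert from
#' Angstrom files.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, three columns (bohr).
#' @param charge integer total charge of the system.
#' @param fragment_of optional integer vector mapping each atom to a
#'   fragment index; must form a contiguous 1-based range covering all
#'   fragments.
#' @return an object of class `ita_geometry`.
#' @export
geometry <- function(elements, coords, charge = 0L, fragment_of = NULL) {
  if (length(elements) == 0L) stop("geometry needs at least one atom")
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != length(elements)) {
    stop("coords must have one row per element")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  element_data(elements)  # validates symbols
  if (!is.null(fragment_of)) {
    fragment_of <- as.integer(fragment_of)
    if (length(fragment_of) != length(elements)) {
      stop("fragment_of must have one entry per atom")
    }
    if (!setequal(unique(fragment_of), seq_len(max(fragment_of)))) {
      stop("fragment indices must form a contiguous range 1..n_fragments")
    }
  }
  structure(
    list(elements = elements, coords = coords, charge = as.integer(charge),
         fragment_of = fragment_of),
    class = "ita_geometry"
  )
}

#' @export
print.ita_geometry <- function(x, ...) {
  cat(sprintf("<ita_geometry: %d atoms (%s), charge %+d%s>\n",
              length(x$elements),
              paste(utils::head(unique(x$elements), 6), collapse = ","),
              x$charge,
              if (is.null(x$fragment_of)) "" else
                sprintf(", %d fragments", max(x$fragment_of))))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom an `ita_geometry`.
#' @return integer atom count.
#' @export
n_atoms <- function(geom) length(geom$elements)

#' Read a geometry from an XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom.
#' Coordinates are converted to bohr on read.
#'
#' @param path path to the XYZ file.
#' @param charge total charge assigned to the geometry.
#' @return an [geometry()] object (coordinates in bohr).
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: bad atom count '", lines[1], "'")
  }
  if (length(lines) < n + 2L) {
    stop("XYZ parse error at line ", length(lines) + 1L,
         ": expected ", n, " atom lines, found ", max(0L, length(lines) - 2L))
  }
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  geometry(elements, coords * BOHR_PER_ANGSTROM, charge = charge)
}

#' Write a geometry to an XYZ file
#'
#' Inverse of [read_xyz()]: coordinates are converted from bohr back to
#' Angstrom and written with enough digits to round-trip.
#'
#' @param geom an `ita_geometry`.
#' @param path output file path.
#' @param comment comment placed on the second line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path, comment = "") {
  ang <- geom$coords / BOHR_PER_ANGSTROM
  lines <- c(
    as.character(n_atoms(geom)),
    comment,
    sprintf("%-3s %20.12f %20.12f %20.12f",
            geom$elements, ang[, 1], ang[, 2], ang[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Assign atoms to fragments by bond connectivity
#'
#' Two atoms are bonded when their distance is below 1.2 times the sum of
#' their covalent radii; fragments are the connected components of the
#' resulting bond graph, numbered deterministically by the lowest atom
#' index they contain.
#'
#' @param geom an `ita_geometry`.
#' @return the geometry with `fragment_of` filled in.
#' @export
detect_fragments <- function(geom) {
  n <- n_atoms(geom)
  rad <- element_data(geom$elements)$covalent_radius * BOHR_PER_ANGSTROM
  d <- as.matrix(stats::dist(geom$coords))
  cutoff <- .bond_factor * outer(rad, rad, `+`)
  adj <- d < cutoff & upper.tri(d)
  # union-find over bonds
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in which(adj)) {
    i <- (e - 1L) %% n + 1L
    j <- (e - 1L) %/% n + 1L
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, integer(1))
  geom$fragment_of <- as.integer(factor(root, levels = unique(root)))
  geom
}
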