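# Physical constants and element data.  All internal math is in Hartree
# atomic units; XYZ files are Angstrom and converted on read.

#' Bohr per Angstrom conversion factor
#'
#' CODATA value used for all coordinate conversions (1 Angstrom =
#' 1.8897261254578281 bohr).
#'
#' @export
BOHR_PER_ANGSTROM <- 1.8897261254578281

# Elements known to the package.  Covalent radii (Angstrom, Cordero-style
# single-bond values) drive bond detection; becke_radius (bohr) scales the
# radial quadrature map per atom.
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  number = 1:18,
  covalent_radius = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57,
                      0.58, 1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06),
  becke_radius = c(1.0, 0.6, 3.1, 2.0, 1.6, 1.3, 1.2, 1.1, 1.0, 0.9,
                   3.4, 2.8, 2.4, 2.1, 1.9, 1.9, 1.8, 1.7),
  stringsAsFactors = FALSE
)

# Factor multiplying the sum of covalent radii in the bond criterion.
.bond_factor <- 1.2

#' Look up element data
#'
#' @param symbols character vector of element symbols (case sensitive,
#'   e.g. `"Mg"`).
#' @return data frame with columns `symbol`, `number`, `covalent_radius`
#'   (Angstrom) and `becke_radius` (bohr), one row per input symbol.
#' @export
element_data <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  .element_table[idx, , drop = FALSE]
}
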