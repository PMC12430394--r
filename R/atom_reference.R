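# Promolecular reference atoms: spherically averaged neutral-atom
# densities expanded in s-type Gaussians,
#   rho0(r) = sum_k c_k (a_k/pi)^{3/2} exp(-a_k r^2),   sum_k c_k = n_elec.
# The packaged table was fitted (nonnegative least squares, so rho0 > 0
# everywhere) to single-zeta Slater-shell atoms; see
# inst/scripts/make_atom_refs.R.

#' Construct an atomic reference density
#'
#' @param element element symbol.
#' @param coefficients Gaussian coefficients `c_k` (electrons); must sum
#'   to `n_elec` (renormalized internally if within 1e-6, rejected
#'   otherwise).
#' @param exponents Gaussian exponents `a_k` (bohr^-2).
#' @param n_elec electron count of the neutral atom.
#' @return an object of class `ita_atom_reference`.
#' @export
atom_reference <- function(element, coefficients, exponents, n_elec) {
  stopifnot(length(coefficients) == length(exponents),
            all(exponents > 0), all(coefficients >= 0))
  s <- sum(coefficients)
  if (abs(s - n_elec) > 1e-6 * max(1, n_elec)) {
    stop("coefficients of ", element, " sum to ", s, ", expected ", n_elec)
  }
  coefficients <- coefficients * (n_elec / s)
  structure(
    list(element = element, coefficients = coefficients,
         exponents = exponents, n_elec = n_elec),
    class = "ita_atom_reference"
  )
}

#' Load the packaged atomic reference table
#'
#' @param path optional path to an alternative CSV with columns
#'   `element`, `coefficient`, `exponent`, `n_elec`.
#' @return named list of [atom_reference()] objects keyed by element
#'   symbol.
#' @export
load_atom_references <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atom_refs.csv", package = "itacorr",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  refs <- lapply(split(tab, tab$element), function(d) {
    atom_reference(d$element[1], d$coefficient, d$exponent, d$n_elec[1])
  })
  refs[order(names(refs))]
}

# Evaluate rho0, and optionally its radial pieces, for one reference atom
# at squared distances r2 from its center.  Returns a list of vectors.
.ref_radial <- function(ref, r2, derivatives = FALSE) {
  pref <- ref$coefficients * (ref$exponents / pi)^1.5
  rho <- numeric(length(r2))
  drho_over_r <- if (derivatives) numeric(length(r2)) else NULL
  lap <- if (derivatives) numeric(length(r2)) else NULL
  for (k in seq_along(pref)) {
    g <- pref[k] * exp(-ref$exponents[k] * r2)
    rho <- rho + g
    if (derivatives) {
      a <- ref$exponents[k]
      drho_over_r <- drho_over_r - 2 * a * g          # (1/r) d rho/d r
      lap <- lap + g * (4 * a^2 * r2 - 6 * a)
    }
  }
  list(rho = rho, drho_over_r = drho_over_r, lap = lap)
}
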