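# DensityField contract: an object exposing the total electron density,
# its gradient and Laplacian at arbitrary points, plus the electron
# count.  Orbital-backed fields additionally expose orbital densities and
# the positive-definite kinetic-energy density t(r) used by the
# Ghosh-Berkowitz-Parr entropy.

#' Create a density field
#'
#' Low-level constructor wrapping evaluator closures.  Most users will
#' call [promolecular_field()] or [wavefunction_field()] instead.
#'
#' @param n_electrons electron count the density integrates to.
#' @param rho function(points) -> density vector; `points` is an n x 3
#'   matrix in bohr.  Must be non-negative.
#' @param grad function(points) -> n x 3 matrix of density gradients.
#' @param lap function(points) -> Laplacian vector.
#' @param kinetic_density optional function(points) -> positive-definite
#'   kinetic-energy density t(r); present on orbital-backed fields.
#' @param orbitals optional list describing the orbital set (see
#'   [wavefunction_field()]).
#' @return an object of class `ita_field`.
#' @export
density_field <- function(n_electrons, rho, grad, lap,
                          kinetic_density = NULL, orbitals = NULL) {
  stopifnot(is.function(rho), is.function(grad), is.function(lap))
  structure(
    list(n_electrons = n_electrons, rho = rho, grad = grad, lap = lap,
         kinetic_density = kinetic_density, orbitals = orbitals,
         has_orbitals = !is.null(orbitals) || !is.null(kinetic_density)),
    class = "ita_field"
  )
}

#' @export
print.ita_field <- function(x, ...) {
  cat(sprintf("<ita_field: N = %g electron(s)%s>\n", x$n_electrons,
              if (x$has_orbitals) ", orbital-backed" else ""))
  invisible(x)
}

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  points
}

# Sum of analytic Gaussian atomic densities for a geometry; shared by the
# promolecular field and the Hirshfeld reference atoms.
.promolecule_eval <- function(geom, refs, points, derivatives = FALSE) {
  points <- .as_points(points)
  n <- nrow(points)
  rho <- numeric(n)
  grad <- if (derivatives) matrix(0, n, 3) else NULL
  lap <- if (derivatives) numeric(n) else NULL
  for (a in seq_len(n_atoms(geom))) {
    ref <- refs[[geom$elements[a]]]
    dx <- points[, 1] - geom$coords[a, 1]
    dy <- points[, 2] - geom$coords[a, 2]
    dz <- points[, 3] - geom$coords[a, 3]
    r2 <- dx * dx + dy * dy + dz * dz
    rad <- .ref_radial(ref, r2, derivatives = derivatives)
    rho <- rho + rad$rho
    if (derivatives) {
      grad <- grad + cbind(dx * rad$drho_over_r, dy * rad$drho_over_r,
                           dz * rad$drho_over_r)
      lap <- lap + rad$lap
    }
  }
  list(rho = rho, grad = grad, lap = lap)
}

#' Promolecular density field
#'
#' Superposition of neutral free-atom reference densities placed at the
#' molecular geometry: `rho(r) = sum_B rho0_B(|r - R_B|)`.  Gradients and
#' Laplacians are analytic from the Gaussian expansion.  The promolecule
#' is always the neutral-atom superposition; the geometry's charge does
#' not alter it.
#'
#' @param geom an `ita_geometry`.
#' @param refs named list of [atom_reference()] objects; defaults to the
#'   packaged table.
#' @return an `ita_field` with `n_electrons` equal to the summed
#'   neutral-atom electron counts.
#' @export
promolecular_field <- function(geom, refs = load_atom_references()) {
  missing <- setdiff(unique(geom$elements), names(refs))
  if (length(missing) > 0) {
    stop("no atomic reference density for element(s): ",
         paste(missing, collapse = ", "))
  }
  nel <- sum(vapply(geom$elements, function(e) refs[[e]]$n_elec, numeric(1)))
  density_field(
    n_electrons = nel,
    rho = function(points) .promolecule_eval(geom, refs, points)$rho,
    grad = function(points)
      .promolecule_eval(geom, refs, points, derivatives = TRUE)$grad,
    lap = function(points)
      .promolecule_eval(geom, refs, points, derivatives = TRUE)$lap
  )
}

#' Single-Gaussian model field
#'
#' Analytic field `rho(r) = N (a/pi)^{3/2} exp(-a |r - center|^2)`: the
#' workhorse of the closed-form test suite (Shannon entropy, Fisher
#' information, Onicescu energies and the relative descriptors of a
#' Gaussian density all have closed forms).
#'
#' @param exponent Gaussian exponent `a` (bohr^-2).
#' @param n_electrons norm `N` of the density (electrons).
#' @param center 3-vector (bohr).
#' @return an `ita_field`.
#' @export
gaussian_field <- function(exponent, n_electrons = 1, center = c(0, 0, 0)) {
  a <- exponent
  pref <- n_electrons * (a / pi)^1.5
  evalrho <- function(points) {
    points <- .as_points(points)
    d <- sweep(points, 2, center)
    pref * exp(-a * rowSums(d * d))
  }
  density_field(
    n_electrons = n_electrons,
    rho = evalrho,
    grad = function(points) {
      points <- .as_points(points)
      d <- sweep(points, 2, center)
      -2 * a * evalrho(points) * d
    },
    lap = function(points) {
      points <- .as_points(points)
      d <- sweep(points, 2, center)
      evalrho(points) * (4 * a^2 * rowSums(d * d) - 6 * a)
    }
  )
}

#' Sum of density fields
#'
#' Pointwise superposition of independent fields (densities, gradients and
#' Laplacians add; electron counts add).  Used to build separated
#' multi-center model systems for extensivity checks.
#'
#' @param ... `ita_field` objects.
#' @return an `ita_field`.
#' @export
field_sum <- function(...) {
  fields <- list(...)
  stopifnot(length(fields) > 0)
  density_field(
    n_electrons = sum(vapply(fields, `[[`, numeric(1), "n_electrons")),
    rho = function(points)
      Reduce(`+`, lapply(fields, function(f) f$rho(points))),
    grad = function(points)
      Reduce(`+`, lapply(fields, function(f) f$grad(points))),
    lap = function(points)
      Reduce(`+`, lapply(fields, function(f) f$lap(points))),
    kinetic_density = if (all(vapply(fields, function(f)
      !is.null(f$kinetic_density), logical(1)))) {
      function(points)
        Reduce(`+`, lapply(fields, function(f) f$kinetic_density(points)))
    }
  )
}
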