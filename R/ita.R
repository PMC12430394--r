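# The eleven information-theoretic descriptors of the electron density
# and the Hirshfeld stockholder partition.
#
# All descriptors are plain 3-D integrals evaluated on a multicenter
# grid.  Logarithmic integrands (ln rho, ln(rho/rho0)) exclude points
# where the density falls below a floor of 1e-12: contributions there
# are below grid accuracy.

.density_floor <- 1e-12

#' Ghosh-Berkowitz-Parr entropy constants
#'
#' `k` is the Boltzmann constant in atomic units (1), `c_K =
#' (3/10)(3 pi^2)^(2/3)` is the Thomas-Fermi constant and `c = 5/3 +
#' ln(4 pi c_K / 3)`.
#'
#' @return named list with `k`, `c_K` and `c`.
#' @export
gbp_constants <- function() {
  c_K <- (3 / 10) * (3 * pi^2)^(2 / 3)
  list(k = 1, c_K = c_K, c = 5 / 3 + log(4 * pi * c_K / 3))
}

#' Shannon entropy of a density
#'
#' `S_S = -integral rho ln rho`: a global measure of how delocalized the
#' electron density is.
#'
#' @param field an `ita_field`.
#' @param grid an `ita_grid`.
#' @return scalar (a.u.).
#' @export
shannon_entropy <- function(field, grid) {
  rho <- field$rho(grid$points)
  keep <- rho > .density_floor
  -sum(grid$weights[keep] * rho[keep] * log(rho[keep]))
}

#' Fisher information of a density
#'
#' `I_F = integral |grad rho|^2 / rho`: a local measure of density
#' sharpness.
#'
#' @inheritParams shannon_entropy
#' @return scalar (a.u., non-negative).
#' @export
fisher_information <- function(field, grid) {
  rho <- field$rho(grid$points)
  g <- field$grad(grid$points)
  keep <- rho > .density_floor
  sum(grid$weights[keep] * rowSums(g[keep, , drop = FALSE]^2) / rho[keep])
}

#' Ghosh-Berkowitz-Parr entropy
#'
#' `S_GBP = integral (3/2) k rho [c + ln(t/t_TF)]` with the
#' positive-definite kinetic-energy density `t(r)` from the orbital set
#' and `t_TF = c_K rho^(5/3)`.  The positive overall sign follows the
#' original Ghosh-Berkowitz-Parr convention.  Points with `t <= 0` or
#' density below the floor are skipped; the number of skipped points is
#' attached as attribute `n_skipped`.
#'
#' @inheritParams shannon_entropy
#' @return scalar (a.u.) with attribute `n_skipped`.
#' @export
gbp_entropy <- function(field, grid) {
  if (is.null(field$kinetic_density)) {
    stop("S_GBP requires an orbital-backed field (kinetic-energy density)")
  }
  kc <- gbp_constants()
  rho <- field$rho(grid$points)
  tau <- field$kinetic_density(grid$points)
  t_tf <- kc$c_K * rho^(5 / 3)
  keep <- rho > .density_floor & tau > 0
  val <- sum(grid$weights[keep] * 1.5 * kc$k * rho[keep] *
               (kc$c + log(tau[keep] / t_tf[keep])))
  attr(val, "n_skipped") <- sum(!keep)
  val
}

#' Onicescu information energy of order n
#'
#' `E_n = 1/(n - 1) integral rho^n`: a dispersion measure finer than the
#' Shannon entropy.  Orders 2 and 3 are used by the regression protocol.
#'
#' @inheritParams shannon_entropy
#' @param n integer order, >= 2.
#' @return scalar (a.u., positive).
#' @export
onicescu <- function(field, grid, n) {
  if (n < 2) stop("Onicescu order must be >= 2")
  rho <- field$rho(grid$points)
  sum(grid$weights * rho^n) / (n - 1)
}

#' Relative Renyi integral of order n
#'
#' `Omega_n = integral rho^n / rho0^(n-1)`: the argument of the relative
#' Renyi entropy logarithm.  This is the quantity tabulated as R2r/R3r in
#' the packaged benchmark tables (for `rho = rho0` it collapses to the
#' electron count).
#'
#' @inheritParams shannon_entropy
#' @param ref_field reference-density `ita_field` (strictly positive on
#'   the grid).
#' @param n integer order, >= 2.
#' @return scalar (a.u.).
#' @export
relative_renyi_integral <- function(field, ref_field, grid, n) {
  if (n < 2) stop("Renyi order must be >= 2")
  rho <- field$rho(grid$points)
  rho0 <- ref_field$rho(grid$points)
  keep <- rho0 > .density_floor
  sum(grid$weights[keep] * rho[keep]^n / rho0[keep]^(n - 1))
}

#' Relative Renyi entropy of order n
#'
#' `R_n = 1/(1 - n) log10(Omega_n)`, the literal entropy form built on
#' [relative_renyi_integral()].
#'
#' @inheritParams relative_renyi_integral
#' @return scalar (dimensionless).
#' @export
relative_renyi_entropy <- function(field, ref_field, grid, n) {
  omega <- relative_renyi_integral(field, ref_field, grid, n)
  if (omega <= 0) stop("relative Renyi integral must be positive")
  log10(omega) / (1 - n)
}

#' Information gain (Kullback-Leibler divergence)
#'
#' `I_G = integral rho ln(rho/rho0)`; non-negative when both densities
#' carry the same norm (Gibbs inequality).
#'
#' @inheritParams relative_renyi_integral
#' @return scalar (a.u.).
#' @export
information_gain <- function(field, ref_field, grid) {
  rho <- field$rho(grid$points)
  rho0 <- ref_field$rho(grid$points)
  keep <- rho > .density_floor & rho0 > .density_floor
  sum(grid$weights[keep] * rho[keep] * log(rho[keep] / rho0[keep]))
}

#' Hirshfeld stockholder partition
#'
#' Shares the molecular density among atoms in proportion to free-atom
#' reference densities at each point: `w_A = rho0_A / sum_B rho0_B`,
#' `rho_A = w_A rho`.
#'
#' @param geom an `ita_geometry`.
#' @param refs named list of [atom_reference()] objects.
#' @param field molecular `ita_field`.
#' @param grid an `ita_grid`.
#' @return object of class `ita_hirshfeld` with the weight matrix
#'   (points x atoms), the molecular density on the grid and closures for
#'   per-atom reference densities.
#' @export
hirshfeld <- function(geom, refs, field, grid) {
  nat <- n_atoms(geom)
  rho0_atom <- matrix(0, nrow(grid$points), nat)
  for (a in seq_len(nat)) {
    ref <- refs[[geom$elements[a]]]
    if (is.null(ref)) {
      stop("no atomic reference density for element: ", geom$elements[a])
    }
    d <- sweep(grid$points, 2, geom$coords[a, ])
    rho0_atom[, a] <- .ref_radial(ref, rowSums(d * d))$rho
  }
  rho0 <- rowSums(rho0_atom)
  omega <- rho0_atom / pmax(rho0, .density_floor)
  # below the floor the stockholder ratio is numerically meaningless;
  # fall back to a uniform share so the partition of unity is exact
  omega[rho0 <= .density_floor, ] <- 1 / nat
  structure(
    list(geom = geom, refs = refs, weights = omega,
         rho = field$rho(grid$points), rho0_atom = rho0_atom,
         rho0 = rho0, grid = grid, field = field),
    class = "ita_hirshfeld"
  )
}

#' Relative Fisher information descriptors G1, G2, G3
#'
#' Atom-summed relative Fisher measures of the molecular density against
#' the promolecular reference, using Hirshfeld atomic densities `rho_A`
#' and reference atomic densities `rho0_A`:
#' \itemize{
#'   \item `G1 = sum_A integral lap(rho_A) ln(rho_A/rho0_A)`
#'   \item `G2 = sum_A integral rho_A [lap(rho_A)/rho_A -
#'      lap(rho0_A)/rho0_A]`
#'   \item `G3 = sum_A integral rho_A |grad ln(rho_A/rho0_A)|^2`
#' }
#' Under stockholder sharing `rho_A/rho0_A = rho/rho0` pointwise, and
#' `lap(rho_A)` is evaluated analytically from that identity.
#'
#' @param partition an `ita_hirshfeld` from [hirshfeld()].
#' @param which 1, 2 or 3.
#' @return scalar (a.u.).
#' @export
relative_fisher_g <- function(partition, which) {
  stopifnot(which %in% 1:3)
  p <- partition
  grid <- p$grid
  rho <- p$rho
  keep <- rho > .density_floor & p$rho0 > .density_floor
  w <- grid$weights[keep]
  rho <- rho[keep]
  rho0 <- p$rho0[keep]
  q <- rho / rho0         # common Hirshfeld ratio rho_A/rho0_A
  if (which == 3L) {
    # grad ln q is atom-independent; sum_A rho_A = rho
    g <- p$field$grad(grid$points)[keep, , drop = FALSE]
    pro <- .promolecule_eval(p$geom, p$refs, grid$points[keep, , drop = FALSE],
                             derivatives = TRUE)
    gln <- g / rho - pro$grad / rho0
    return(sum(w * rho * rowSums(gln^2)))
  }
  # G1/G2 need per-atom Laplacians: rho_A = rho0_A q, so
  # lap rho_A = q lap rho0_A + 2 grad rho0_A . grad q + rho0_A lap q
  g <- p$field$grad(grid$points)[keep, , drop = FALSE]
  lap <- p$field$lap(grid$points)[keep]
  pro <- .promolecule_eval(p$geom, p$refs, grid$points[keep, , drop = FALSE],
                           derivatives = TRUE)
  grad_q <- (g - q * pro$grad) / rho0
  lap_q <- (lap - 2 * rowSums(grad_q * pro$grad) - q * pro$lap) / rho0
  total <- 0
  for (a in seq_len(n_atoms(p$geom))) {
    ref <- p$refs[[p$geom$elements[a]]]
    d <- sweep(grid$points[keep, , drop = FALSE], 2, p$geom$coords[a, ])
    rad <- .ref_radial(ref, rowSums(d * d), derivatives = TRUE)
    grad0a <- d * rad$drho_over_r
    lap_rho_a <- q * rad$lap + 2 * rowSums(grad0a * grad_q) +
      rad$rho * lap_q
    total <- total + if (which == 1L) {
      sum(w * lap_rho_a * log(q))
    } else {
      # rho_A [lap rho_A / rho_A - lap rho0_A / rho0_A]
      sum(w * (lap_rho_a - q * rad$lap))
    }
  }
  total
}

#' Compute the full descriptor vector
#'
#' One call filling every slot of the eleven-descriptor vector: Shannon
#' entropy, Fisher information, Ghosh-Berkowitz-Parr entropy (orbital-
#' backed fields only, `NA` otherwise), Onicescu `E2`/`E3`, relative
#' Renyi integrals `R2r`/`R3r`, information gain `I_G` and the relative
#' Fisher measures `G1`-`G3`.  The reference density for the relative
#' descriptors is the promolecular superposition built from `refs`.
#'
#' @param geom an `ita_geometry`.
#' @param field molecular `ita_field`.
#' @param refs named list of [atom_reference()] objects; defaults to the
#'   packaged table.
#' @param grid an `ita_grid`; defaults to [build_grid()] on `geom`.
#' @return named numeric vector of class `ita_vector` with elements
#'   `S_S`, `I_F`, `S_GBP`, `E2`, `E3`, `R2r`, `R3r`, `I_G`, `G1`, `G2`,
#'   `G3` (a.u.).
#' @export
compute_all <- function(geom, field, refs = load_atom_references(),
                        grid = build_grid(geom)) {
  ref_field <- promolecular_field(geom, refs)
  part <- hirshfeld(geom, refs, field, grid)
  out <- c(
    S_S = shannon_entropy(field, grid),
    I_F = fisher_information(field, grid),
    S_GBP = if (is.null(field$kinetic_density)) NA_real_ else
      as.numeric(gbp_entropy(field, grid)),
    E2 = onicescu(field, grid, 2),
    E3 = onicescu(field, grid, 3),
    R2r = relative_renyi_integral(field, ref_field, grid, 2),
    R3r = relative_renyi_integral(field, ref_field, grid, 3),
    I_G = information_gain(field, ref_field, grid),
    G1 = relative_fisher_g(part, 1),
    G2 = relative_fisher_g(part, 2),
    G3 = relative_fisher_g(part, 3)
  )
  class(out) <- c("ita_vector", class(out))
  out
}

#' @export
print.ita_vector <- function(x, ...) {
  cat("ITA descriptor vector (a.u.):\n")
  print(round(unclass(x), 6), ...)
  invisible(x)
}
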