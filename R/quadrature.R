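# Multicenter numerical integration: per-atom radial (Gauss-Chebyshev
# nodes under a Becke radial map, element-dependent scale) x angular
# (Gauss-Legendre in cos(theta) x uniform phi) product grids, glued into
# a molecular grid by Becke partition-of-unity weights (three smoothing
# iterations, no radius adjustment).

# Supported angular point counts: 2*k^2 spherical product grids.
.supported_angular <- as.integer(2 * c(4L, 6L, 8L, 10L, 12L, 14L, 16L, 20L)^2)

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
.gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1, ]^2)[ord])
}

# Unit-sphere product grid: n_angular = 2*k^2 points with weights summing
# to 4*pi.
.angular_grid <- function(n_angular) {
  k <- sqrt(n_angular / 2)
  gl <- .gauss_legendre(as.integer(k))
  phi <- 2 * pi * (seq_len(2L * as.integer(k)) - 1) / (2 * k)
  ct <- rep(gl$x, each = length(phi))
  st <- sqrt(pmax(0, 1 - ct^2))
  list(
    xyz = cbind(st * cos(rep(phi, times = length(gl$x))),
                st * sin(rep(phi, times = length(gl$x))),
                ct),
    w = rep(gl$w, each = length(phi)) * (2 * pi / (2 * k))
  )
}

# Radial nodes/weights for integrating f(r) r^2 dr on (0, Inf):
# Gauss-Chebyshev angles mapped through Becke's r = R (1 + x)/(1 - x).
.radial_grid <- function(n_radial, scale) {
  i <- seq_len(n_radial)
  theta <- i * pi / (n_radial + 1)
  x <- cos(theta)
  r <- scale * (1 + x) / (1 - x)
  w <- (pi / (n_radial + 1)) * sin(theta) * 2 * scale / (1 - x)^2
  ord <- order(r)
  list(r = r[ord], w = (w * r^2)[ord])
}

# Becke smoothing function iterated three times.
.becke_s <- function(mu) {
  f <- mu
  for (it in 1:3) f <- 1.5 * f - 0.5 * f^3
  0.5 * (1 - f)
}

#' Becke partition-of-unity weights
#'
#' Cell weights `w_A(r)` assigning every point a share per atom; rows sum
#' to one.  Exposed mainly for testing and diagnostics.
#'
#' @param geom an `ita_geometry`.
#' @param points n x 3 matrix (bohr).
#' @return n x n_atoms matrix of weights in `[0, 1]`.
#' @export
becke_weights <- function(geom, points) {
  points <- .as_points(points)
  nat <- n_atoms(geom)
  if (nat == 1L) return(matrix(1, nrow(points), 1))
  datom <- matrix(vapply(seq_len(nat), function(a) {
    d <- sweep(points, 2, geom$coords[a, ])
    sqrt(rowSums(d * d))
  }, numeric(nrow(points))), nrow = nrow(points))
  Rab <- as.matrix(stats::dist(geom$coords))
  P <- matrix(1, nrow(points), nat)
  for (a in seq_len(nat)) {
    for (b in seq_len(nat)) {
      if (a == b) next
      mu <- (datom[, a] - datom[, b]) / Rab[a, b]
      P[, a] <- P[, a] * .becke_s(mu)
    }
  }
  P / rowSums(P)
}

#' Build a multicenter quadrature grid
#'
#' Atom-centered product grids (radial x angular) combined with Becke
#' partition weights so that weighted sums approximate 3-D integrals over
#' all space.  Points are ordered deterministically (atom-major,
#' radial-major, then angular) so sums are bit-stable run to run.
#'
#' @param geom an `ita_geometry`.
#' @param n_radial radial points per atom (>= 20); default 75.
#' @param n_angular angular points per shell; one of
#'   `r paste(.supported_angular, collapse = ", ")`; default 288.
#' @return an object of class `ita_grid` with fields `points` (n x 3,
#'   bohr), `weights` (bohr^3), `owner_atom` and `spec`.
#' @export
build_grid <- function(geom, n_radial = 75L, n_angular = 288L) {
  if (n_radial < 20L) stop("n_radial must be >= 20")
  if (!(n_angular %in% .supported_angular)) {
    stop("unsupported n_angular ", n_angular, "; supported orders: ",
         paste(.supported_angular, collapse = ", "))
  }
  ang <- .angular_grid(n_angular)
  nat <- n_atoms(geom)
  scales <- element_data(geom$elements)$becke_radius
  pts_list <- vector("list", nat)
  w_list <- vector("list", nat)
  for (a in seq_len(nat)) {
    rad <- .radial_grid(n_radial, scales[a])
    # radial-major: all angular points of shell 1, then shell 2, ...
    shell_pts <- ang$xyz[rep(seq_len(nrow(ang$xyz)), times = n_radial), ] *
      rep(rad$r, each = nrow(ang$xyz))
    pts_list[[a]] <- sweep(shell_pts, 2, geom$coords[a, ], `+`)
    w_list[[a]] <- rep(rad$w, each = nrow(ang$xyz)) *
      rep(ang$w, times = n_radial)
  }
  points <- do.call(rbind, pts_list)
  w <- unlist(w_list)
  owner <- rep(seq_len(nat), each = n_radial * n_angular)
  if (nat > 1L) {
    bw <- becke_weights(geom, points)
    w <- w * bw[cbind(seq_along(owner), owner)]
  }
  structure(
    list(points = points, weights = w, owner_atom = owner,
         spec = list(n_radial = as.integer(n_radial),
                     n_angular = as.integer(n_angular),
                     partition = "becke")),
    class = "ita_grid"
  )
}

#' @export
print.ita_grid <- function(x, ...) {
  cat(sprintf("<ita_grid: %d points (%d radial x %d angular, %s partition)>\n",
              length(x$weights), x$spec$n_radial, x$spec$n_angular,
              x$spec$partition))
  invisible(x)
}

#' Integrate point values over a grid
#'
#' Weighted sum `sum_i w_i v_i` in deterministic point order.
#'
#' @param grid an `ita_grid`.
#' @param values numeric vector aligned with `grid$points`.
#' @return scalar integral.
#' @export
integrate_grid <- function(grid, values) {
  if (length(values) != length(grid$weights)) {
    stop("values length (", length(values), ") does not match grid size (",
         length(grid$weights), ")")
  }
  sum(grid$weights * values)
}
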