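# Shared fixtures and independent oracles for the test suite.

# One H model atom at the origin with its default grid, reused across
# descriptor tests.
unit_system <- local({
  geom <- geometry("H", matrix(0, 1, 3))
  grid <- NULL
  function() {
    if (is.null(grid)) grid <<- build_grid(geom)
    list(geom = geom, grid = grid)
  }
})

# Independent 1-D radial quadrature for spherically symmetric integrands:
# composite Simpson on [0, rmax] with n panels, integral of
# f(r) * 4 pi r^2 dr.  Deliberately unrelated to the package's
# multicenter grids.
oracle_radial <- function(f, rmax = 40, n = 10000) {
  if (n %% 2 == 1) n <- n + 1
  r <- seq(0, rmax, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1) * (r[2] - r[1]) / 3
  v <- f(r) * 4 * pi * r^2
  v[!is.finite(v)] <- 0   # 0 * log(0)-type limits in the far tail
  sum(w * v)
}

# Brute-force inclusion-exclusion over a family of primitive fragment
# sets: coefficient of every distinct nonempty intersection from the
# alternating-sign subset expansion of the union indicator.  Exponential
# in the number of primitives; used only as an oracle on small cases.
oracle_inclusion_exclusion <- function(primitives) {
  np <- length(primitives)
  acc <- new.env(parent = emptyenv())
  for (mask in seq_len(2^np - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    s <- Reduce(intersect, primitives[members])
    if (length(s) == 0) next
    key <- paste(sort(s), collapse = ",")
    sign <- if (length(members) %% 2 == 1) 1L else -1L
    acc[[key]] <- (if (is.null(acc[[key]])) 0L else acc[[key]]) + sign
  }
  keys <- ls(acc)
  coefs <- vapply(keys, function(k) acc[[k]], integer(1))
  keep <- coefs != 0L
  list(subsystems = lapply(keys[keep], function(k)
         as.integer(strsplit(k, ",")[[1]])),
       coefficients = unname(coefs[keep]))
}

# Net counting coefficient per fragment under a plan-like object.
fragment_count <- function(subsystems, coefficients, n_fragments) {
  vapply(seq_len(n_fragments), function(f)
    sum(coefficients[vapply(subsystems, function(s) f %in% s, logical(1))]),
    numeric(1))
}

# Random planar cluster of single-atom fragments with a reproducible
# layout; spacing chosen so that neighbor overlaps force derivative
# subsystems for moderate zeta.
random_cluster_geometry <- function(n_fragments, seed, spread = 8) {
  set.seed(seed)
  coords <- cbind(stats::runif(n_fragments, 0, spread),
                  stats::runif(n_fragments, 0, spread), 0)
  geometry(rep("H", n_fragments), coords, fragment_of = seq_len(n_fragments))
}

# Doubly occupied single-s-orbital wavefunction on a given geometry's
# first atoms (one orbital per center).
s_orbital_wavefunction <- function(n_centers, exponent = 1,
                                   occupation = 2) {
  shells <- lapply(seq_len(n_centers), function(a)
    list(center = a, l = 0L, exponents = exponent, coefficients = 1))
  mo <- diag(n_centers)
  wavefunction_record(shells, mo, rep(occupation, n_centers))
}
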