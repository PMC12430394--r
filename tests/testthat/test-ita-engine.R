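# The eleven descriptors: closed forms on Gaussian systems, Hirshfeld
# partition, extensivity, oracle equivalence.

test_that("Shannon entropy matches the Gaussian closed form", {
  us <- unit_system()
  expect_equal(shannon_entropy(gaussian_field(1), us$grid),
               1.5 * (1 + log(pi)), tolerance = 1e-6)   # 3.217095
  expect_equal(shannon_entropy(gaussian_field(2), us$grid),
               1.5 * (1 + log(pi / 2)), tolerance = 1e-6)  # 2.177374
})

test_that("Fisher information matches 6 N alpha", {
  us <- unit_system()
  expect_equal(fisher_information(gaussian_field(1), us$grid), 6,
               tolerance = 1e-6)
  expect_equal(fisher_information(gaussian_field(2), us$grid), 12,
               tolerance = 1e-6)
})

test_that("Onicescu energies match closed forms and scale homogeneously", {
  us <- unit_system()
  expect_equal(onicescu(gaussian_field(1), us$grid, 2), (1 / (2 * pi))^1.5,
               tolerance = 1e-6)
  expect_equal(onicescu(gaussian_field(1), us$grid, 3),
               0.5 / (pi^3 * 3^1.5), tolerance = 1e-6)
  # doubling the norm at fixed shape multiplies E2 by 4
  expect_equal(onicescu(gaussian_field(1, n_electrons = 2), us$grid, 2),
               4 * onicescu(gaussian_field(1), us$grid, 2),
               tolerance = 1e-10)
  expect_error(onicescu(gaussian_field(1), us$grid, 1), ">= 2")
})

test_that("relative Renyi integral and entropy match their closed forms", {
  us <- unit_system()
  f2 <- gaussian_field(2); f1 <- gaussian_field(1)
  omega2 <- relative_renyi_integral(f2, f1, us$grid, 2)
  expect_equal(omega2, 8 / 3^1.5, tolerance = 1e-6)        # 1.539601
  expect_equal(relative_renyi_entropy(f2, f1, us$grid, 2),
               -log10(8 / 3^1.5), tolerance = 1e-5)        # -0.187408
  # rho = rho0 collapses the integral to N and the entropy to
  # log10(N)/(1-n)
  f10 <- gaussian_field(1, n_electrons = 10)
  expect_equal(relative_renyi_integral(f10, f10, us$grid, 2), 10,
               tolerance = 1e-6)
  expect_equal(relative_renyi_entropy(f10, f10, us$grid, 2), -1,
               tolerance = 1e-6)
  f1n <- gaussian_field(1)
  expect_equal(relative_renyi_entropy(f1n, f1n, us$grid, 2), 0,
               tolerance = 1e-8)
})

test_that("promolecule against itself returns the electron count", {
  refs <- load_atom_references()
  # acetylene-like C2H2 promolecule, N = 14
  g <- geometry(c("C", "C", "H", "H"),
                cbind(0, 0, c(-1.14, 1.14, -3.15, 3.15)))
  f <- promolecular_field(g, refs)
  grid <- build_grid(g)
  expect_equal(relative_renyi_integral(f, f, grid, 2), 14,
               tolerance = 1e-5)
  expect_equal(information_gain(f, f, grid), 0, tolerance = 1e-8)
})

test_that("information gain matches the closed form and Gibbs bound", {
  us <- unit_system()
  expect_equal(information_gain(gaussian_field(2), gaussian_field(1),
                                us$grid),
               1.5 * log(2) - 0.75, tolerance = 1e-6)     # 0.289721
  # equinormalized pairs are non-negative
  for (a in c(0.5, 1.7, 3)) {
    expect_gte(information_gain(gaussian_field(a), gaussian_field(1),
                                us$grid), -1e-8)
  }
})

test_that("GBP constants reproduce their defining expressions", {
  kc <- gbp_constants()
  expect_equal(kc$c_K, (3 / 10) * (3 * pi^2)^(2 / 3), tolerance = 1e-12)
  expect_equal(kc$c, 5 / 3 + log(4 * pi * kc$c_K / 3), tolerance = 1e-12)
  # commonly quoted decimal approximations
  expect_equal(kc$c_K, 2.871234, tolerance = 1e-6)
  expect_equal(kc$c, 4.153821, tolerance = 1e-6)
  expect_identical(kc$k, 1)
})

test_that("GBP entropy reduces to (3/2)c N when t equals t_TF", {
  us <- unit_system()
  kc <- gbp_constants()
  base <- gaussian_field(1, n_electrons = 2)
  mock <- density_field(2, rho = base$rho, grad = base$grad,
                        lap = base$lap,
                        kinetic_density = function(p)
                          kc$c_K * base$rho(p)^(5 / 3))
  expect_equal(as.numeric(gbp_entropy(mock, us$grid)), 1.5 * kc$c * 2,
               tolerance = 1e-6)                          # 12.461390
  expect_error(gbp_entropy(gaussian_field(1), us$grid), "orbital-backed")
})

test_that("orbital-backed GBP entropy matches an independent radial oracle", {
  us <- unit_system()
  wfn <- s_orbital_wavefunction(1, exponent = 1, occupation = 2)
  f <- wavefunction_field(wfn, us$geom)
  kc <- gbp_constants()
  # doubly occupied s orbital of exponent a: rho = 2 (2a/pi)^{3/2}
  # exp(-2ar^2), t = 2 a^2 r^2 rho (positive-definite form)
  rho_fn <- function(r) 2 * (2 / pi)^1.5 * exp(-2 * r^2)
  oracle <- oracle_radial(function(r) {
    rho <- rho_fn(r)
    tau <- 2 * r^2 * rho
    ratio <- tau / (kc$c_K * rho^(5 / 3))
    out <- 1.5 * rho * (kc$c + log(ratio))
    out[r == 0] <- 0                       # t -> 0 limit handled as skip
    out
  })
  expect_equal(as.numeric(gbp_entropy(f, us$grid)), oracle,
               tolerance = 1e-6)
})

test_that("Hirshfeld partition is a pointwise partition of unity", {
  refs <- load_atom_references()
  g <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0, 1.43, 1.11), c(0, -1.43, 1.11)))
  f <- promolecular_field(g, refs)
  grid <- build_grid(g, n_radial = 40L, n_angular = 72L)
  part <- hirshfeld(g, refs, f, grid)
  expect_true(all(part$weights >= 0 & part$weights <= 1))
  expect_equal(rowSums(part$weights), rep(1, nrow(grid$points)),
               tolerance = 1e-12)
  # summed atomic populations recover the total electron count
  pops <- colSums(part$weights * part$rho * grid$weights)
  expect_equal(sum(pops), integrate_grid(grid, f$rho(grid$points)),
               tolerance = 1e-10)
  # single atom: weight identically one; midpoint of a homonuclear
  # pair: half each
  g1 <- geometry("H", matrix(0, 1, 3))
  p1 <- hirshfeld(g1, refs, promolecular_field(g1, refs), build_grid(g1))
  expect_true(all(p1$weights == 1))
  g2 <- geometry(c("H", "H"), cbind(0, 0, c(-1, 1)))
  midpoint <- structure(list(points = matrix(0, 1, 3), weights = 1),
                        class = "ita_grid")
  p2 <- hirshfeld(g2, refs, promolecular_field(g2, refs), midpoint)
  expect_equal(unname(p2$weights[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(becke_weights(g2, matrix(0, 1, 3))[1, ]),
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("relative Fisher measures match one-center closed forms", {
  us <- unit_system()
  refs <- list(H = atom_reference("H", 1, 1, 1))
  part <- hirshfeld(us$geom, refs, gaussian_field(2), us$grid)
  # rho exponent a = 2 against reference exponent b = 1:
  # G1 = -6N(a-b), G2 = 6b^2/a... derived: integral[lap rho -
  # (rho/rho0) lap rho0] = 6b - 6b^2/a reversed sign; closed values:
  expect_equal(relative_fisher_g(part, 1), -6, tolerance = 1e-5)
  expect_equal(relative_fisher_g(part, 2), 3, tolerance = 1e-5)
  expect_equal(relative_fisher_g(part, 3), 3, tolerance = 1e-5)
  # identity case: all three vanish
  part0 <- hirshfeld(us$geom, refs, gaussian_field(1), us$grid)
  for (k in 1:3) {
    expect_equal(relative_fisher_g(part0, k), 0, tolerance = 1e-8)
  }
})

test_that("compute_all agrees with the individual operations", {
  sys <- make_gaussian_system(1, exponent = 2)
  # reference table has exponent 1 so the relative descriptors are
  # non-trivial
  refs <- list(H = atom_reference("H", 1, 1, 1))
  grid <- build_grid(sys$geometry)
  vec <- compute_all(sys$geometry, sys$field, refs, grid)
  ref_field <- promolecular_field(sys$geometry, refs)
  expect_equal(vec[["S_S"]], shannon_entropy(sys$field, grid))
  expect_equal(vec[["I_F"]], fisher_information(sys$field, grid))
  expect_equal(vec[["E2"]], onicescu(sys$field, grid, 2))
  expect_equal(vec[["E3"]], onicescu(sys$field, grid, 3))
  expect_equal(vec[["R2r"]],
               relative_renyi_integral(sys$field, ref_field, grid, 2))
  expect_equal(vec[["I_G"]],
               information_gain(sys$field, ref_field, grid))
  expect_true(is.na(vec[["S_GBP"]]))   # promolecular field: no orbitals
  # identity case: promolecule against itself
  sys1 <- make_gaussian_system(1)
  vec1 <- compute_all(sys1$geometry, sys1$field, sys1$refs,
                      build_grid(sys1$geometry))
  expect_equal(vec1[["I_G"]], 0, tolerance = 1e-8)
  expect_equal(vec1[["G1"]], 0, tolerance = 1e-8)
  expect_equal(vec1[["G2"]], 0, tolerance = 1e-8)
  expect_equal(vec1[["G3"]], 0, tolerance = 1e-8)
  expect_equal(vec1[["R2r"]], 1, tolerance = 1e-6)
})

test_that("descriptors match a dense radial oracle on one-center systems", {
  us <- unit_system()
  f <- gaussian_field(1.7, n_electrons = 3)
  rho_fn <- function(r) 3 * (1.7 / pi)^1.5 * exp(-1.7 * r^2)
  expect_equal(shannon_entropy(f, us$grid),
               oracle_radial(function(r) -rho_fn(r) * log(rho_fn(r))),
               tolerance = 1e-6)
  expect_equal(fisher_information(f, us$grid),
               oracle_radial(function(r) (2 * 1.7 * r)^2 * rho_fn(r)),
               tolerance = 1e-6)
  expect_equal(onicescu(f, us$grid, 3),
               oracle_radial(function(r) rho_fn(r)^3) / 2,
               tolerance = 1e-6)
})
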