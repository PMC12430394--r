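# GEBF: plan construction, inclusion-exclusion coefficients, energy
# assembly, LR combination.

test_that("the linear A-B-C-D chain yields the textbook plan", {
  # spacing d with d <= zeta < 2d, gamma_max 2
  g <- geometry(rep("H", 4), cbind(0, 0, c(0, 3, 6, 9)), fragment_of = 1:4)
  plan <- suppressWarnings(
    build_plan(g, zeta = 3.5 / BOHR_PER_ANGSTROM, gamma_max = 2))
  key <- vapply(plan$subsystems, paste, character(1), collapse = ",")
  got <- stats::setNames(plan$coefficients, key)
  expect_equal(got[c("1,2", "2,3", "3,4", "2", "3")],
               c(`1,2` = 1L, `2,3` = 1L, `3,4` = 1L, `2` = -1L, `3` = -1L))
  expect_length(plan$subsystems, 5)
  expect_equal(sort(unique(plan$kind)), c("derivative", "primitive"))
})

test_that("trivial fragmentations behave as expected", {
  g1 <- geometry("H", matrix(0, 1, 3), fragment_of = 1L)
  p1 <- build_plan(g1)
  expect_length(p1$subsystems, 1)
  expect_equal(p1$coefficients, 1L)
  expect_equal(p1$kind, "primitive")

  # two fragments beyond zeta: two primitives, no derivatives
  g2 <- geometry(c("H", "H"), cbind(0, 0, c(0, 20)), fragment_of = 1:2)
  p2 <- build_plan(g2, zeta = 2)
  expect_length(p2$subsystems, 2)
  expect_equal(p2$coefficients, c(1L, 1L))
  expect_error(build_plan(geometry("H", matrix(0, 1, 3))),
               "no fragment assignment")
})

test_that("energy assembly matches direct evaluation of the formula", {
  g <- geometry(rep("H", 4), cbind(0, 0, c(0, 3, 6, 9)), fragment_of = 1:4)
  plan <- suppressWarnings(
    build_plan(g, zeta = 3.5 / BOHR_PER_ANGSTROM, gamma_max = 2))
  # additive toy energies E(S) = sum of per-fragment e_f
  e_f <- c(-1, -2, -3, -4)
  energies <- vapply(plan$subsystems, function(s) sum(e_f[s]), numeric(1))
  expect_equal(assemble_energy(plan, energies, g), -10, tolerance = 1e-12)

  # two disjoint one-atom fragments with charges: the point-charge term
  # is double-counted once (sum C = 2) and subtracted
  g2 <- geometry(c("H", "H"), cbind(0, 0, c(0, 10)), fragment_of = 1:2)
  p2 <- build_plan(g2, zeta = 2)
  expect_equal(assemble_energy(p2, c(-1, -2), g2, charges = c(0.1, 0.1)),
               -3.001, tolerance = 1e-12)
  # single subsystem: charge term vanishes regardless of charges
  g1 <- geometry("H", matrix(0, 1, 3), fragment_of = 1L)
  expect_equal(assemble_energy(build_plan(g1), -5, g1, charges = 0.3), -5)
  expect_error(assemble_energy(p2, c(-1), g2), "one energy per subsystem")
})

test_that("coefficients single-count every fragment on random clusters", {
  zeta_bohr <- 4 * BOHR_PER_ANGSTROM
  for (seed in 1:200) {
    nfrag <- 3 + seed %% 6
    g <- random_cluster_geometry(nfrag, seed = seed)
    plan <- suppressWarnings(build_plan(g, zeta = 4, gamma_max = 4))
    counts <- fragment_count(plan$subsystems, plan$coefficients, nfrag)
    expect_equal(counts, rep(1, nfrag),
                 label = paste("plan counts, seed", seed))
    expect_true(all(plan$coefficients == round(plan$coefficients)))
    # brute-force oracle on the same primitive family
    prim <- plan$subsystems[plan$kind == "primitive"]
    oracle <- oracle_inclusion_exclusion(prim)
    ocounts <- fragment_count(oracle$subsystems, oracle$coefficients, nfrag)
    expect_equal(counts, ocounts,
                 label = paste("oracle counts, seed", seed))
    # the assembled additive energy agrees with the oracle's assembly
    e_f <- stats::rnorm(nfrag)
    e_plan <- sum(plan$coefficients *
                    vapply(plan$subsystems, function(s) sum(e_f[s]),
                           numeric(1)))
    e_oracle <- sum(oracle$coefficients *
                      vapply(oracle$subsystems, function(s) sum(e_f[s]),
                             numeric(1)))
    expect_equal(e_plan, e_oracle, tolerance = 1e-12)
    expect_equal(e_plan, sum(e_f), tolerance = 1e-12)
  }
})

test_that("pairwise-additive energies are recovered when pairs are covered", {
  set.seed(7)
  for (rep in 1:20) {
    nfrag <- 4 + rep %% 3
    g <- random_cluster_geometry(nfrag, seed = 1000 + rep, spread = 6)
    # gamma_max large enough that no primitive is truncated: every pair
    # within zeta co-occurs in a primitive subsystem
    plan <- build_plan(g, zeta = 4, gamma_max = nfrag)
    zeta_bohr <- 4 * BOHR_PER_ANGSTROM
    d <- as.matrix(stats::dist(g$coords))
    v <- matrix(stats::rnorm(nfrag^2, sd = 0.1), nfrag, nfrag)
    v <- (v + t(v)) / 2
    # interactions only between fragments within zeta (those co-occur)
    v[d > zeta_bohr] <- 0
    diag(v) <- 0
    e_f <- stats::rnorm(nfrag)
    esub <- vapply(plan$subsystems, function(s) {
      sum(e_f[s]) + sum(v[s, s][upper.tri(v[s, s])])
    }, numeric(1))
    exact <- sum(e_f) + sum(v[upper.tri(v)])
    expect_equal(assemble_energy(plan, esub, g), exact, tolerance = 1e-10,
                 label = paste("pairwise assembly, rep", rep))
  }
})

test_that("LR combination telescopes for additive descriptors", {
  g <- geometry(rep("H", 4), cbind(0, 0, c(0, 3, 6, 9)), fragment_of = 1:4)
  plan <- suppressWarnings(
    build_plan(g, zeta = 3.5 / BOHR_PER_ANGSTROM, gamma_max = 2))
  m <- fit_lr(c(10, 20, 30), c(-1, -2, -3), descriptor = "toy")
  x_f <- c(11, 13, 17, 19)   # per-fragment descriptor contributions
  x_sub <- vapply(plan$subsystems, function(s) sum(x_f[s]), numeric(1))
  # sum C_m = 1 makes the intercept count once: equals the whole-system
  # prediction
  expect_equal(gebf_lr_correlation(plan, x_sub, m),
               predict(m, sum(x_f)), tolerance = 1e-12)
  # single subsystem reduces to plain prediction
  g1 <- geometry("H", matrix(0, 1, 3), fragment_of = 1L)
  p1 <- build_plan(g1)
  expect_equal(gebf_lr_correlation(p1, 5, m), predict(m, 5))
  # disjoint fragments: predictions add
  g2 <- geometry(c("H", "H"), cbind(0, 0, c(0, 20)), fragment_of = 1:2)
  p2 <- build_plan(g2, zeta = 2)
  expect_equal(gebf_lr_correlation(p2, c(3, 4), m),
               predict(m, 3) + predict(m, 4))
})

test_that("plans survive a JSON round trip", {
  g <- random_cluster_geometry(6, seed = 11)
  plan <- suppressWarnings(build_plan(g, zeta = 4, gamma_max = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$subsystems, plan$subsystems, ignore_attr = TRUE)
  expect_equal(back$coefficients, plan$coefficients)
  expect_equal(back$kind, plan$kind)
  expect_equal(back$parameters$zeta, plan$parameters$zeta)
})

test_that("removing a distant fragment leaves other subsystems unchanged", {
  g <- random_cluster_geometry(5, seed = 3, spread = 5)
  far <- geometry(c(g$elements, "H"), rbind(g$coords, c(500, 500, 0)),
                  fragment_of = c(g$fragment_of, 6L))
  p_near <- suppressWarnings(build_plan(g, zeta = 4, gamma_max = 4))
  p_far <- suppressWarnings(build_plan(far, zeta = 4, gamma_max = 4))
  near_keys <- sort(vapply(p_near$subsystems, paste, character(1),
                           collapse = ","))
  far_keys <- sort(vapply(p_far$subsystems, paste, character(1),
                          collapse = ","))
  expect_equal(setdiff(far_keys, near_keys), "6")
})
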