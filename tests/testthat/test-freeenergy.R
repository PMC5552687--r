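test_that("the Zwanzig estimator is exact on zero and constant perturbations", {
  set.seed(1)
  expect_equal(fep_zwanzig(rep(0, 500))$dF, 0)
  z <- fep_zwanzig(rep(2.37, 500))
  expect_equal(z$dF, 2.37, tolerance = 1e-12)
  expect_equal(z$se, 0)
  expect_error(fep_zwanzig(rnorm(100, 0, 10)), "overlap")
})

test_that("the Zwanzig estimator recovers the harmonic closed form at 1e4 samples", {
  kT <- 1.987204258640832e-3 * 298.15
  k1 <- 12; k2 <- 18
  set.seed(8)
  x <- rnorm(1e4, 0, sqrt(kT / k1))
  dU <- 0.5 * (k2 - k1) * x^2
  z <- fep_zwanzig(dU)
  exact <- 0.5 * kT * log(k2 / k1)
  expect_lt(abs(z$dF - exact), 3 * z$se)
})

test_that("composition is the identity on zero shifts and invariant to constant shifts", {
  prof <- tibble::tibble(bead = 1:5, arc_length = 0:4,
                         dW = c(0, 2, 5, 3, 1), se = c(0, .1, .1, .1, .1))
  esp <- structure(list(profile = prof), class = "sampled_pmf")
  zero <- tibble::tibble(bead = 1:5, dW = 0, se = 0)
  c0 <- compose_pmf(esp, zero, zero)
  expect_equal(c0$profile$dW_high, prof$dW)
  cst <- tibble::tibble(bead = 1:5, dW = 7.7, se = 0)
  c1 <- compose_pmf(esp, cst, cst)
  expect_equal(c1$profile$dW_high, prof$dW)    # constants cancel
  expect_error(compose_pmf(esp, zero[-2, ], zero), "bead")
})

test_that("level shifts vanish for the identity perturbation and profiles are invariant to water relabeling", {
  sol <- cached_solute()
  box <- generate_box(n = 16, L = 7.9, seed = 33)
  g <- coord_matrix(sol$geometry$reactant)
  g <- sweep(g, 2, colMeans(g) - 3.95)
  box <- carve_box(box, g)
  ens <- sample_solvent(box, sol, g, "ESP",
                        sampler_config(seed = 3, equil = 30, prod = 100,
                                       stride = 10))
  z <- level_shift(ens, sol, "ESP", "ESP", geometry = g)
  expect_identical(z$dW, 0)
  z2 <- level_shift(ens, sol, "ESP", "LOW", geometry = g)
  expect_true(is.finite(z2$dW) && z2$dW != 0)

  # permuting whole water molecules leaves every coupling term unchanged
  parts <- mlpmf:::ensemble_coupling(ens, g, sol)
  perm <- sample(ens$box$n)
  ens_p <- ens
  ens_p$frames <- lapply(ens$frames, function(s) {
    idx <- as.vector(t(outer((perm - 1) * 3, 1:3, "+")))
    s[idx, , drop = FALSE]
  })
  parts_p <- mlpmf:::ensemble_coupling(ens_p, g, sol)
  expect_equal(parts, parts_p, tolerance = 1e-12)
})

test_that("a decoupled solute's sampled profile equals its gas-phase energy differences", {
  sol <- cached_solute()
  sol$charges$reactant[] <- 0
  sol$charges$product[] <- 0
  sol$atoms$eps[] <- 0
  box <- generate_box(n = 12, L = 7.2, seed = 44)
  path <- neb_relax(
    interpolate_path(sol$geometry$reactant, sol$geometry$product, n = 10),
    potential_solute(sol, "LOW"), neb_config(maxiter = 4000))
  pmf <- sampled_pmf(path, box, sol, "ESP",
                     sampler_config(seed = 2, equil = 10, prod = 50,
                                    stride = 10))
  gas <- vapply(seq_len(10), function(b) {
    solute_energy(matrix(path$coords[b, ], ncol = 3, byrow = TRUE),
                  sol, "ESP")$energy
  }, numeric(1))
  expect_equal(pmf$profile$dW, gas - gas[1], tolerance = 1e-9)
  expect_true(all(pmf$profile$se < 1e-12))
})

test_that("reversing the path direction negates the sampled profile within error", {
  sol <- cached_solute()
  box <- generate_box(n = 24, L = 8.95, seed = 55)
  path <- neb_relax(
    interpolate_path(sol$geometry$reactant, sol$geometry$product, n = 10),
    potential_solute(sol, "LOW"), neb_config(maxiter = 4000))
  ctr <- colMeans(matrix(path$coords[1, ], ncol = 3, byrow = TRUE))
  shift <- rep(8.95 / 2, 3) - ctr
  path$coords <- t(apply(path$coords, 1, function(v) {
    as.numeric(t(sweep(matrix(v, ncol = 3, byrow = TRUE), 2, -shift)))
  }))
  box <- carve_box(box, matrix(as.numeric(t(path$coords)), ncol = 3,
                               byrow = TRUE))
  fwd <- sampled_pmf(path, box, sol, "ESP",
                     sampler_config(seed = 6, equil = 150, prod = 500,
                                    stride = 10))
  rev_path <- path
  rev_path$coords <- path$coords[10:1, ]
  rev_path$arc_length <- max(path$arc_length) - rev(path$arc_length)
  bwd <- sampled_pmf(rev_path, box, sol, "ESP",
                     sampler_config(seed = 16, equil = 150, prod = 500,
                                    stride = 10))
  dw_f <- fwd$profile$dW[10]
  dw_b <- bwd$profile$dW[10]
  se <- sqrt(fwd$profile$se[10]^2 + bwd$profile$se[10]^2)
  expect_lt(abs(dw_f + dw_b), 4 * se + 0.15 * abs(dw_f))
})

test_that("solvent decomposition bookkeeping is exact and the helper reproduces net sums", {
  expect_equal(aqueous_contribution(6.0, 8.7, 9.4), 5.3)
  expect_equal(aqueous_contribution(27.9, 8.6, 9.4), 27.1)
  x <- runif(5); y <- runif(5); z <- runif(5)
  expect_equal(aqueous_contribution(x, y, z), x + (y - z))
})
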