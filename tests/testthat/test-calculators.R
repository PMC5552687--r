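test_that("elementary pair terms match their defining constants", {
  # Lennard-Jones is zero at r = sigma: two waters with O-O at sigma and
  # charges turned off
  p <- water_params()
  box <- suppressWarnings(generate_box(n = 2, L = 40, seed = 1, min_dist = 5))
  # place O sites exactly sigma apart, hydrogens far along +y to isolate LJ
  sites <- matrix(c(0, 0, 0,   0, 50, 0,   0, 51, 0,
                    p$sigma, 0, 0,  p$sigma, 50, 0,  p$sigma, 51, 0),
                  6, 3, byrow = TRUE)
  b0 <- box
  b0$sites <- sites
  b0$params$qO <- 0
  b0$params$qH <- 0
  # neutral-charge override must bypass the neutrality check, so build by hand
  expect_equal(water_mm_energy(b0)$energy, 0, tolerance = 1e-12)

  # Coulomb constant: unit charges at 1 A
  q <- 1
  r <- 1
  expect_equal(332.0637 * q * q / r, 332.0637)
  sol <- cached_solute()
  # Morse bond at its minimum contributes -De
  prof <- scan_bond_profile(sol, "ESP", r = sol$params$r0_morse)
  expect_equal(prof$energy, -sol$params$De)
  # dissociation plateau: De above the minimum
  far <- scan_bond_profile(sol, "ESP", r = 25)
  expect_equal(far$energy - prof$energy, sol$params$De, tolerance = 1e-6)
})

test_that("single water has no intermolecular MM energy and distant pairs are truncated", {
  b1 <- suppressWarnings(generate_box(n = 1, L = 10, seed = 2))
  expect_equal(water_mm_energy(b1)$energy, 0)
  b2 <- suppressWarnings(generate_box(n = 2, L = 60, seed = 3, min_dist = 5))
  # move the second molecule 50 A away from the first
  b2$sites[4:6, ] <- b2$sites[1:3, ] + 50 / sqrt(3)
  expect_equal(water_mm_energy(b2, cutoff = 15)$energy, 0)
})

test_that("water-water energy equals the brute-force double-loop oracle", {
  box <- suppressWarnings(generate_box(n = 10, L = 9, seed = 11, min_dist = 2.6))
  expect_equal(water_mm_energy(box)$energy, ww_energy_oracle(box),
               tolerance = 1e-8)
  expect_equal(water_mm_energy(box, cutoff = 5)$energy,
               ww_energy_oracle(box, cutoff = 5), tolerance = 1e-8)
})

test_that("overlapping water sites raise an error", {
  box <- suppressWarnings(generate_box(n = 2, L = 20, seed = 4, min_dist = 5))
  box$sites[4, ] <- box$sites[1, ] + c(0.05, 0, 0)
  expect_error(water_mm_energy(box), "overlap")
})

test_that("the Mueller-Brown surface has its three ordered minima and a stationary gradient at each", {
  starts <- list(c(-0.55, 1.45), c(-0.05, 0.45), c(0.6, 0.03))
  mins <- lapply(starts, mb_minimum_oracle)
  e <- vapply(mins, function(v) muller_brown(v), numeric(1))
  expect_true(e[1] < e[3] && e[3] < e[2])  # deepest, then lower-right, then middle
  mb <- potential_muller_brown()
  for (v in mins) expect_lt(sqrt(sum(mb$g(v)^2)), 1e-6)
})

test_that("all analytic forces agree with central finite differences", {
  sol <- cached_solute()
  set.seed(13)
  x <- as.numeric(t(coord_matrix(sol$geometry$reactant))) + rnorm(21, 0, 0.06)
  for (lv in c("ESP", "LOW", "HIGH")) {
    pot <- potential_solute(sol, lv)
    g <- pot$g(x)
    gn <- num_gradient(pot$f, x, h = 1e-5)
    expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-4)
  }
  mb <- potential_muller_brown()
  v <- c(-0.3, 0.8)
  expect_lt(max(abs(mb$g(v) - num_gradient(mb$f, v))), 1e-4)
  dw <- potential_double_well()
  expect_lt(abs(dw$g(0.3) - num_gradient(dw$f, 0.3)), 1e-6)
})

test_that("molecular energies are invariant under rigid rotation and translation", {
  sol <- cached_solute()
  x <- coord_matrix(sol$geometry$reactant)
  e0 <- solute_energy(x, sol, "HIGH")$energy
  set.seed(5)
  for (k in 1:5) {
    R <- rotation_matrix_3d(rnorm(3), runif(1, -pi, pi))
    x2 <- sweep(x %*% t(R), 2, rnorm(3, 0, 5), "+")
    expect_equal(solute_energy(x2, sol, "HIGH")$energy, e0,
                 tolerance = 1e-9)
  }
})

test_that("HIGH and LOW tiers coincide where the perturbation vanishes and split by its amplitude at the centre", {
  sol <- cached_solute()
  pc <- sol$params$pert_center
  expect_equal(scan_bond_profile(sol, "HIGH", r = pc)$energy -
                 scan_bond_profile(sol, "LOW", r = pc)$energy,
               sol$params$pert_amp)
  far <- pc + 12 * sol$params$pert_width
  expect_equal(scan_bond_profile(sol, "HIGH", r = far)$energy,
               scan_bond_profile(sol, "LOW", r = far)$energy,
               tolerance = 1e-10)
})

test_that("the 1-D bond-scan oracle locates the surrogate barrier the relaxed path reproduces", {
  sol <- cached_solute()
  sc <- scan_bond_profile(sol, "LOW")
  rel <- sc$energy - sc$energy[which.min(abs(sc$r - sol$r_ref["reactant"]))]
  i_barrier <- which(sc$r > 1.6 & sc$r < 2.7)
  barrier_1d <- max(rel[i_barrier])
  expect_gt(barrier_1d, 20)   # a substantial reactive barrier
  expect_lt(barrier_1d, 45)
  # evaluate() contract: deterministic energy, error on dimension mismatch
  pot <- potential_solute(sol, "LOW")
  x <- sol$geometry$reactant
  expect_identical(evaluate_energy(x, pot)$energy,
                   evaluate_energy(x, pot)$energy)
  expect_error(evaluate_energy(1:5, pot), "expects")
})
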