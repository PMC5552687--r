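test_that("path interpolation is linear with fixed endpoints", {
  p <- interpolate_path(c(-1, 0), c(1, 0), n = 3)
  expect_equal(p$coords[2, ], c(0, 0))           # midpoint is the average
  p2 <- interpolate_path(c(0, 0), c(2, 2), n = 2)
  expect_equal(nrow(p2$coords), 2)               # endpoints only
  expect_warning(interpolate_path(c(1, 1), c(1, 1), n = 4), "identical")
  expect_error(interpolate_path(c(1, 2, 3), c(1, 2)), "differ")
  expect_true(all(diff(p$arc_length) > 0))
})

test_that("NEB resolves the symmetric double well exactly", {
  dw <- potential_double_well()
  p <- interpolate_path(-1 / sqrt(2), 1 / sqrt(2), n = 9)
  r <- neb_relax(p, dw, neb_config(tol = 1e-8, maxiter = 5000))
  expect_true(r$converged)
  cb <- attr(r, "climbing_bead")
  expect_lt(abs(r$coords[cb, ]), 1e-8)           # saddle at x = 0
  expect_equal(max(r$energies) - r$energies[1], 0.25, tolerance = 1e-10)
  # endpoints bitwise unchanged
  expect_identical(r$coords[1, ], p$coords[1, ])
  expect_identical(r$coords[9, ], p$coords[9, ])
})

test_that("climbing-image NEB lands on the Mueller-Brown saddle found by the grid+Newton oracle", {
  sp <- mb_saddle_oracle()
  minA <- mb_minimum_oracle(c(-0.55, 1.45))
  minB <- mb_minimum_oracle(c(0.6, 0.03))
  mb <- potential_muller_brown()
  path <- interpolate_path(minA, minB, n = 15)
  r <- neb_relax(path, mb, neb_config(tol = 1e-4, maxiter = 20000,
                                      k_spring = 5, step_max = 0.05,
                                      dt_init = 0.002, dt_max = 0.01))
  expect_true(r$converged)
  cb <- attr(r, "climbing_bead")
  expect_lt(sqrt(sum((r$coords[cb, ] - sp)^2)), 1e-2)
  # between a pair of adjacent minima the relaxed profile has a single
  # interior maximum
  minC <- mb_minimum_oracle(c(-0.05, 0.45))
  rac <- neb_relax(interpolate_path(minA, minC, n = 11), mb,
                   neb_config(tol = 1e-4, maxiter = 20000, k_spring = 5,
                              step_max = 0.05, dt_init = 0.002,
                              dt_max = 0.01))
  expect_true(rac$converged)
  eac <- rac$energies
  expect_equal(sum(diff(sign(diff(eac))) < 0), 1)
  # the converged climbing bead is a first-order saddle (oracle Hessian)
  expect_equal(sum(eigen(mb_hessian_oracle(r$coords[cb, ]))$values < 0), 1)
  f <- frequencies(r$coords[cb, ], mb, tol = 1e-4)
  expect_equal(f$n_imaginary, 1)
})

test_that("the surrogate ring-opening path stretches the breakable bond monotonically", {
  sol <- cached_solute()
  p0 <- interpolate_path(sol$geometry$reactant, sol$geometry$product, n = 10)
  r <- neb_relax(p0, potential_solute(sol, "LOW"),
                 neb_config(maxiter = 4000))
  expect_true(r$converged)
  rlen <- apply(r$coords, 1, function(v) {
    x <- matrix(v, ncol = 3, byrow = TRUE)
    sqrt(sum((x[2, ] - x[5, ])^2))
  })
  # monotone stretch up to spring-equalisation wiggle in the flat entrance
  # channel of the reactant basin
  expect_true(all(diff(rlen) > -5e-3))
  expect_gt(sum(diff(rlen)), 1.3)
  # relaxed barrier agrees with the fine 1-D scan oracle to within the
  # relaxation of the remaining coordinates
  sc <- scan_bond_profile(sol, "LOW")
  rel <- sc$energy - sc$energy[which.min(abs(sc$r - rlen[1]))]
  barrier_1d <- max(rel[sc$r > 1.6 & sc$r < 2.7])
  barrier_neb <- max(r$energies) - r$energies[1]
  expect_lt(abs(barrier_neb - barrier_1d), 1.0)
  expect_lte(barrier_neb, barrier_1d + 1e-3)   # relaxation can only lower it
})

test_that("non-convergence is flagged, not silent", {
  mb <- potential_muller_brown()
  p <- interpolate_path(mb_minimum_oracle(c(-0.55, 1.45)),
                        mb_minimum_oracle(c(0.6, 0.03)), n = 11)
  expect_warning(r <- neb_relax(p, mb, neb_config(maxiter = 3)),
                 "did not converge")
  expect_false(r$converged)
})

test_that("frequency analysis matches the closed-form harmonic oscillator", {
  k <- 300                                   # kcal/mol/A^2
  pot <- potential_harmonic(k, 0, masses = 1)
  f <- frequencies(0, pot)
  # closed form recomputed from physical constants: sqrt(k/m)/(2 pi c)
  conv <- (4184 / 6.02214076e23) / (1.66053906660e-27 * 1e-20)
  nu <- sqrt(k * conv) / (2 * pi * 2.99792458e10)
  expect_equal(f$frequencies_cm, nu, tolerance = 1e-5)
  expect_equal(f$n_imaginary, 0)
})

test_that("saddles show exactly one imaginary mode; minima none", {
  dw <- potential_double_well()
  expect_equal(frequencies(0, dw, tol = 1e-6)$n_imaginary, 1)
  expect_equal(frequencies(1 / sqrt(2), dw, tol = 1e-6)$n_imaginary, 0)
  sol <- cached_solute()
  fr <- frequencies(sol$geometry$reactant, potential_solute(sol, "LOW"),
                    tol = 1e-4)
  expect_equal(length(fr$eigenvalues), 15)   # 3N - 6 internal modes
  expect_equal(fr$n_imaginary, 0)
  expect_true(all(fr$frequencies_cm > 0))
})

test_that("non-stationary input to frequencies warns", {
  dw <- potential_double_well()
  expect_warning(frequencies(0.4, dw, tol = 1e-6), "not stationary")
})

test_that("paths serialise to multi-frame XYZ and tidy/glance summarise them", {
  sol <- cached_solute()
  p0 <- interpolate_path(sol$geometry$reactant, sol$geometry$product, n = 5)
  r <- neb_relax(p0, potential_solute(sol, "LOW"), neb_config(maxiter = 3000))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_path_xyz(r, f)
  frames <- read_xyz_frames(f)
  expect_length(frames, 5)
  td <- tidy(r)
  expect_equal(td$energy_rel[1], 0)
  gl <- glance(r)
  expect_equal(gl$barrier, max(r$energies) - r$energies[1])
})
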