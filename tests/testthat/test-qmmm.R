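test_that("partitioning splits QM and MM exhaustively and rejects bad input", {
  sol <- cached_solute()
  waters <- suppressWarnings(as_tibble(generate_box(n = 3, L = 18, seed = 2)))
  system <- dplyr::bind_rows(sol$geometry$reactant,
                             waters[, names(sol$geometry$reactant)])
  parts <- partition_system(system)
  expect_equal(nrow(parts$qm), 7)
  expect_equal(nrow(parts$mm), 9)
  expect_equal(nrow(parts$qm) + nrow(parts$mm), nrow(system))

  all_qm <- sol$geometry$reactant
  p2 <- partition_system(all_qm)
  expect_equal(nrow(p2$mm), 0)

  expect_error(partition_system(all_qm[0, ]), "empty")
  bad <- system
  bad$region[3] <- NA
  expect_error(partition_system(bad), "region")
})

test_that("Eq.-2 style additivity holds exactly for composed evaluations", {
  sol <- cached_solute()
  box <- suppressWarnings(generate_box(n = 8, L = 10, seed = 6,
                                       min_dist = 2.9))
  g <- coord_matrix(sol$geometry$reactant)
  g <- sweep(g, 2, colMeans(g) - c(5, 5, 5))
  box <- carve_box(box, g, clearance = 2.2)
  d <- compose_energy(g, sol, box, embedding_scheme(15), "LOW")
  expect_identical(d$V_total, d$V_qm + d$V_qmmm + d$V_mm)
})

test_that("coupling matches a hand-summed three-site oracle", {
  sol <- cached_solute()
  # one water near the solute; sum the 7x3 Coulomb terms plus O-site LJ by hand
  box <- suppressWarnings(generate_box(n = 1, L = 30, seed = 8))
  gx <- coord_matrix(sol$geometry$reactant)
  box$sites <- matrix(c(6, 0, 0,  6.57, 0.77, 0,  6.57, -0.77, 0),
                      3, 3, byrow = TRUE)
  ce <- coupling_energy(gx, sol, box, embedding_scheme(15), "ESP")
  q_sol <- solute_charges(gx, sol, "ESP")
  p <- box$params
  qw <- c(p$qO, p$qH, p$qH)
  manual <- 0
  for (a in 1:7) for (s in 1:3) {
    r <- sqrt(sum((gx[a, ] - box$sites[s, ])^2))
    manual <- manual + 332.0637 * q_sol[a] * qw[s] / r
  }
  lj <- mix_lj_oracle(sol, p)
  for (a in 1:7) {
    r2 <- sum((gx[a, ] - box$sites[1, ])^2)
    sr6 <- (lj$sigma[a]^2 / r2)^3
    manual <- manual + 4 * lj$eps[a] * (sr6^2 - sr6)
  }
  expect_equal(ce$energy, manual, tolerance = 1e-8)
})

test_that("the cutoff boundary is strict and outside-coupling is Coulomb-only", {
  sol <- cached_solute()
  gx <- coord_matrix(sol$geometry$reactant)
  box <- suppressWarnings(generate_box(n = 1, L = 100, seed = 9))
  # straddle the boundary: r < cutoff is inside, r >= cutoff is outside
  dir <- c(1, 0, 0)
  near <- gx[which.max(gx[, 1]), ]
  o_out <- near + (15 + 1e-6) * dir
  box$sites <- rbind(o_out, o_out + c(0.5, 0.8, 0), o_out + c(0.5, -0.8, 0))
  ce <- coupling_energy(gx, sol, box, embedding_scheme(15), "ESP")
  expect_equal(ce$n_inside, 0)
  expect_equal(ce$lj_in, 0)             # Coulomb-only beyond the cutoff
  o_in <- near + (15 - 1e-6) * dir
  box$sites <- rbind(o_in, o_in + c(0.5, 0.8, 0), o_in + c(0.5, -0.8, 0))
  ce2 <- coupling_energy(gx, sol, box, embedding_scheme(15), "ESP")
  expect_equal(ce2$n_inside, 1)
})

test_that("outside-cutoff coupling is bilinear: doubling all charges quadruples it", {
  sol <- cached_solute()
  gx <- coord_matrix(sol$geometry$reactant)
  box <- suppressWarnings(generate_box(n = 2, L = 90, seed = 10,
                                       min_dist = 30))
  box$sites <- box$sites + 40           # far outside the cutoff
  e1 <- coupling_energy(gx, sol, box, embedding_scheme(15), "ESP")$energy
  sol2 <- sol
  sol2$charges$reactant <- sol$charges$reactant * 2
  sol2$charges$product <- sol$charges$product * 2
  box2 <- box
  box2$params$qO <- box$params$qO * 2
  box2$params$qH <- box$params$qH * 2
  e2 <- coupling_energy(gx, sol2, box2, embedding_scheme(15), "ESP")$energy
  expect_equal(e2, 4 * e1, tolerance = 1e-10)
})

test_that("coupling vanishes as the solute-water separation grows", {
  sol <- cached_solute()
  gx <- coord_matrix(sol$geometry$reactant)
  box <- suppressWarnings(generate_box(n = 2, L = 20, seed = 12,
                                       min_dist = 4))
  es <- vapply(c(0, 200, 2000), function(shift) {
    b <- box
    b$sites <- b$sites + shift
    abs(coupling_energy(gx, sol, b, embedding_scheme(15), "ESP")$energy)
  }, numeric(1))
  expect_true(all(diff(es) < 0))
  expect_lt(es[3], 1e-3)
})

test_that("composition is translation invariant for the non-periodic droplet", {
  sol <- cached_solute()
  box <- suppressWarnings(generate_box(n = 6, L = 12, seed = 14,
                                       min_dist = 2.9))
  gx <- sweep(coord_matrix(sol$geometry$reactant), 2, c(20, 0, 0), "+")
  b2 <- box
  b2$sites <- b2$sites + 7.5
  g2 <- gx + 7.5
  d1 <- compose_energy(gx, sol, box, embedding_scheme(15), "ESP")
  d2 <- compose_energy(g2, sol, b2, embedding_scheme(15), "ESP")
  expect_equal(d1$V_total, d2$V_total, tolerance = 1e-9)
})

test_that("missing Lennard-Jones parameters name the offending atom", {
  sol <- cached_solute()
  sol$atoms$eps[3] <- NA
  box <- suppressWarnings(generate_box(n = 2, L = 16, seed = 15,
                                       min_dist = 4))
  expect_error(
    coupling_energy(coord_matrix(sol$geometry$reactant), sol, box),
    "O10")
})
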