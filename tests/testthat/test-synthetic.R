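test_that("generated boxes are seeded, dense, and respect the minimum distance", {
  b1 <- generate_box(n = 40, L = 10.6, seed = 9)
  b2 <- generate_box(n = 40, L = 10.6, seed = 9)
  expect_identical(b1$sites, b2$sites)
  b3 <- generate_box(n = 40, L = 10.6, seed = 10)
  expect_false(identical(b1$sites, b3$sites))
  # exhaustive O(n^2) check of the placement constraint
  O <- b1$sites[seq(1, 3 * b1$n, by = 3), ]
  expect_gte(min(stats::dist(O)), 0.9 * 3.166)
  expect_true(all(b1$sites >= -1.01 & b1$sites <= 10.6 + 1.01))
})

test_that("the reference box hits the published density", {
  box <- generate_box(n = 1752, L = 37.5, seed = 1)
  # arithmetic oracle: 1752 * 18.0153 g/mol / (N_A * (37.5 A)^3)
  expected <- 1752 * 18.0153 / (6.02214076e23 * (37.5e-8)^3)
  expect_equal(box_density(box), expected, tolerance = 1e-12)
  expect_equal(round(expected, 3), 0.994)
  O <- box$sites[seq(1, 3 * box$n, by = 3), ]
  expect_gte(min(stats::dist(O)), 0.9 * 3.166)
})

test_that("single-water and infeasible boxes behave as documented", {
  b <- suppressWarnings(generate_box(n = 1, L = 25, seed = 2))
  expect_equal(water_mm_energy(b)$energy, 0)
  expect_error(suppressWarnings(generate_box(n = 200, L = 8, seed = 1)),
               "reduce n")
})

test_that("rigid water geometry matches the model parameters", {
  b <- suppressWarnings(generate_box(n = 5, L = 14, seed = 3))
  s <- as_tibble(b)
  for (i in 1:5) {
    mol <- s[s$resno == i, ]
    expect_equal(bond_length(mol, mol$name[1], mol$name[2]), 1.0,
                 tolerance = 1e-9)
    expect_equal(bond_angle(mol, mol$name[2], mol$name[1], mol$name[3]),
                 109.47, tolerance = 1e-6)
  }
  expect_equal(sum(s$charge), 0, tolerance = 1e-12)
})

test_that("the surrogate solute is a tier-consistent reactive system", {
  sol <- cached_solute()
  # reactant is a LOW-tier stationary point
  g <- solute_energy(sol$geometry$reactant, sol, "LOW",
                     gradient = TRUE)$gradient
  expect_lt(max(abs(g)), 1e-4)
  gp <- solute_energy(sol$geometry$product, sol, "LOW",
                      gradient = TRUE)$gradient
  expect_lt(max(abs(gp)), 1e-4)
  # breakable bond near 1.47 A in the reactant, >= 2.8 A in the product
  expect_equal(bond_length(sol$geometry$reactant, "C8", "N9"), 1.47,
               tolerance = 0.01)
  expect_gte(bond_length(sol$geometry$product, "C8", "N9"), 2.8)
  # charge sets are neutral in both states and at every tier scale
  expect_equal(sum(sol$charges$reactant), 0, tolerance = 1e-12)
  expect_equal(sum(sol$charges$product), 0, tolerance = 1e-12)
  for (lv in c("ESP", "LOW", "HIGH")) {
    q <- solute_charges(sol$geometry$reactant, sol, lv)
    expect_equal(sum(q), 0, tolerance = 1e-12)
  }
  # charges interpolate between the end-point sets along the bond
  mid <- sol$geometry$reactant
  stretch <- (sol$r_ref["product"] + sol$r_ref["reactant"]) / 2 /
    sol$r_ref["reactant"]
  m <- coord_matrix(mid)
  m[5, ] <- m[2, ] + (m[5, ] - m[2, ]) * stretch
  qm <- solute_charges(set_coords(mid, m), sol, "ESP")
  expect_true(all(pmin(sol$charges$reactant, sol$charges$product) - 1e-9 <= qm &
                    qm <= pmax(sol$charges$reactant, sol$charges$product) + 1e-9))
})

test_that("reference tables load with non-empty provenance labels", {
  for (nm in c("ts_basis_coords", "stationary_coords", "energies")) {
    tab <- reference_table(nm)
    expect_gt(nrow(tab), 0)
    expect_true(all(nzchar(tab$source)))
  }
  expect_equal(reference_value("pmf_barrier_high"), 31.6)
  expect_error(reference_value("nope"), "unknown")
})

test_that("carving removes exactly the clashing waters", {
  sol <- cached_solute()
  box <- generate_box(n = 27, L = 9.3, seed = 13)
  g <- coord_matrix(sol$geometry$reactant)
  g <- sweep(g, 2, colMeans(g) - 9.3 / 2)
  carved <- carve_box(box, g, clearance = 2.4)
  expect_lt(carved$n, box$n)
  O <- carved$sites[seq(1, 3 * carved$n, by = 3), , drop = FALSE]
  dmin <- apply(O, 1, function(o) min(sqrt(colSums((t(g) - o)^2))))
  expect_true(all(dmin >= 2.4))
})
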