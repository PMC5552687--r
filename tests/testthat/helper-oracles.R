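# Independent oracles and small fixture builders used across the suite.
# These re-implement reference quantities from scratch (separate constants,
# plain double loops) so the package code under test never checks itself.

# --- independent Mueller-Brown implementation (energy/gradient/Hessian) -----
mb_par <- list(A = c(-200, -100, -170, 15),
               a = c(-1, -1, -6.5, 0.7),
               b = c(0, 0, 11, 0.6),
               cc = c(-10, -10, -6.5, 0.7),
               x0 = c(1, 0, -0.5, -1),
               y0 = c(0, 0.5, 1.5, 1))

mb_energy_oracle <- function(v) {
  with(mb_par, {
    dx <- v[1] - x0; dy <- v[2] - y0
    sum(A * exp(a * dx^2 + b * dx * dy + cc * dy^2))
  })
}

mb_grad_oracle <- function(v) {
  with(mb_par, {
    dx <- v[1] - x0; dy <- v[2] - y0
    e <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    c(sum(e * (2 * a * dx + b * dy)), sum(e * (b * dx + 2 * cc * dy)))
  })
}

# analytic second derivatives of the Gaussian sum
mb_hessian_oracle <- function(v) {
  with(mb_par, {
    dx <- v[1] - x0; dy <- v[2] - y0
    e <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    gx <- 2 * a * dx + b * dy
    gy <- b * dx + 2 * cc * dy
    matrix(c(sum(e * (gx^2 + 2 * a)), sum(e * (gx * gy + b)),
             sum(e * (gx * gy + b)), sum(e * (gy^2 + 2 * cc))),
           2, 2)
  })
}

# dense grid scan + Newton refinement: locate the saddle between the two
# deepest minima (brute-force oracle, no use of package optimizers)
mb_saddle_oracle <- function() {
  gx <- seq(-1.2, 0.2, by = 0.02)
  gy <- seq(0.2, 1.2, by = 0.02)
  best <- NULL
  best_e <- Inf
  for (x in gx) for (y in gy) {
    v <- c(x, y)
    H <- mb_hessian_oracle(v)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] > 0 && ev[2] < 0) {       # index-1 curvature region
      gn <- sqrt(sum(mb_grad_oracle(v)^2))
      if (gn < best_e) { best <- v; best_e <- gn }
    }
  }
  v <- best
  for (k in 1:60) {
    g <- mb_grad_oracle(v)
    if (max(abs(g)) < 1e-13) break
    v <- v - solve(mb_hessian_oracle(v), g)
  }
  v
}

mb_minimum_oracle <- function(start) {
  v <- stats::optim(start, mb_energy_oracle, mb_grad_oracle,
                    method = "BFGS", control = list(reltol = 1e-16))$par
  for (k in 1:20) {          # Newton polish to machine stationarity
    g <- mb_grad_oracle(v)
    if (max(abs(g)) < 1e-13) break
    v <- v - solve(mb_hessian_oracle(v), g)
  }
  v
}

# --- brute-force water-water energy (independent double loop) ---------------
ww_energy_oracle <- function(box, cutoff = Inf) {
  p <- box$params
  s <- box$sites
  q <- c(p$qO, p$qH, p$qH)
  kc <- 332.0637
  e <- 0
  for (i in seq_len(box$n - 1)) {
    for (j in (i + 1):box$n) {
      oi <- s[3 * (i - 1) + 1, ]; oj <- s[3 * (j - 1) + 1, ]
      if (sqrt(sum((oi - oj)^2)) >= cutoff) next
      for (a in 1:3) for (b in 1:3) {
        r <- sqrt(sum((s[3 * (i - 1) + a, ] - s[3 * (j - 1) + b, ])^2))
        e <- e + kc * q[a] * q[b] / r
      }
      r2 <- sum((oi - oj)^2)
      sr6 <- (p$sigma^2 / r2)^3
      e <- e + 4 * p$eps * (sr6^2 - sr6)
    }
  }
  e
}

# --- hand-built structures ---------------------------------------------------
# near-linear water dimer: donor O-H pointing at the acceptor O, O...O 2.9 A
water_dimer <- function(oo = 2.9) {
  mol_structure(
    name = c("O1", "H1", "H2", "O2", "H3", "H4"),
    element = c("O", "H", "H", "O", "H", "H"),
    x = c(0, 0.96, -0.32, oo, oo + 0.30, oo + 0.30),
    y = c(0, 0, 0.90, 0, 0.80, -0.80),
    z = c(0, 0, 0, 0, 0.30, 0.30)
  )
}

rotation_matrix_3d <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# shared expensive fixtures, built once per test run
test_cache <- new.env(parent = emptyenv())

cached_solute <- function() {
  if (is.null(test_cache$solute)) test_cache$solute <- generate_solute()
  test_cache$solute
}

# Lorentz-Berthelot mixing, re-derived for the hand-summed coupling oracle
mix_lj_oracle <- function(sol, p) {
  list(sigma = (sol$atoms$sigma + p$sigma) / 2,
       eps = sqrt(sol$atoms$eps * p$eps))
}

cached_pipeline_report <- function() {
  if (is.null(test_cache$pipeline_report)) {
    test_cache$pipeline_report <- run_pipeline(
      pipeline_config(seed = 3, n_waters = 32, box_length = 9.85,
                      n_beads = 10,
                      sampler = sampler_config(equil = 60, prod = 150,
                                               stride = 15)))
  }
  test_cache$pipeline_report
}
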