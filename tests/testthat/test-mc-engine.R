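# Metropolis sampling machinery: acceptance rule, single moves, constraint
# preservation, determinism, detailed balance on a closed toy system.

test_that("Metropolis rule accepts downhill always, uphill with exp(-dU)", {
  expect_true(all(metropolis_accept(rep(0, 100))))
  expect_true(all(metropolis_accept(c(-1, -10, 0))))
  expect_false(any(metropolis_accept(rep(Inf, 100))))
  set.seed(1)
  n <- 20000
  rate <- mean(metropolis_accept(rep(2, n)))
  se <- sqrt(exp(-2) * (1 - exp(-2)) / n)
  expect_lt(abs(rate - exp(-2)), 3 * se)
})

test_that("ion translation moves only the chosen ion and respects the box", {
  sys <- make_fixture("random10", seed = 3)
  set.seed(10)
  for (k in 1:20) {
    out <- ion_translation_move(sys, 4, move_spec(ion_step = 2))
    moved <- out$state$pos
    expect_identical(moved[-4, ], sys$pos[-4, ])
    expect_true(all(abs(moved[4, ]) <= sys$box$L / 2))
    sys <- out$state
  }
})

test_that("free-ion guard rejects chain beads", {
  sys <- make_fixture("bridge_toy")
  expect_error(ion_translation_move(sys, 1), "not a free ion")
})

test_that("rotatable chains stay straight rods with exact bonds", {
  sys <- build_system("rotatable_rigid", x = 6, c11_mM = 0, c33_mM = 0,
                      L = 30, seed = 2)
  l0 <- sys$params$bond_length
  central <- sys$chains[[1]]$central
  c0 <- sys$pos[central, ]
  set.seed(11)
  n_acc <- 0
  for (k in 1:300) {
    out <- pivot_move(sys, 1, move_spec(pivot_max_angle = 0.2))
    n_acc <- n_acc + out$accepted
    sys <- out$state
  }
  expect_gt(n_acc, 0)
  pos <- sys$pos[sys$chains[[1]]$idx, ]
  expect_equal(bond_lengths(pos), rep(l0, 20), tolerance = 1e-9)
  expect_equal(max(chain_angles(pos)), 0, tolerance = 1e-7)  # still straight
  expect_identical(sys$pos[central, ], c0)                   # centre fixed
})

test_that("parallel_rigid chains reject pivot moves and never move", {
  sys <- build_system("parallel_rigid", x = 2, c33_mM = 5, L = 20, seed = 3)
  expect_error(pivot_move(sys, 1), "static")
  mono <- sys$pos[sys$chain_id > 0, ]
  run <- run_production(sys, move_spec(sweeps_prod = 50, seed = 5),
                        snapshot_stride = 10)
  expect_identical(run$state$pos[sys$chain_id > 0, ], mono)
})

test_that("bendable pivots preserve bonds and the fixed central bead", {
  sys <- make_fixture("wlc_chain", P_nm = 2, N = 21)
  l0 <- sys$params$bond_length
  central <- sys$chains[[1]]$central
  c0 <- sys$pos[central, ]
  run <- run_production(sys, move_spec(sweeps_prod = 250, seed = 6),
                        snapshot_stride = 250, force_every = 0)
  # 250 sweeps x 42 pivot attempts = 10500 pivot moves
  pos <- run$state$pos
  expect_equal(bond_lengths(pos), rep(l0, 20), tolerance = 1e-8)
  expect_identical(pos[central, ], c0)
  # the chain actually explored bent conformations
  expect_gt(max(chain_angles(pos)), 0.01)
})

test_that("confinement cylinder is never violated", {
  sys <- build_system("rotatable_rigid", x = 2, c33_mM = 5, L = 16, seed = 7)
  run <- run_production(sys, move_spec(sweeps_prod = 300, seed = 8),
                        snapshot_stride = 5)
  expect_identical(run$confinement_violations, 0L)
  for (ch in run$trajectory$chains) {
    for (s in run$trajectory$positions) {
      radial <- sqrt((s[ch$idx, 1] - ch$axis[1])^2 +
                     (s[ch$idx, 2] - ch$axis[2])^2)
      expect_true(all(radial <= ch$confinement_radius + 1e-9))
    }
  }
})

test_that("runs are reproducible for a fixed seed", {
  sys <- build_system("bendable", x = 3, P_nm = 10, c33_mM = 5, L = 16,
                      seed = 4)
  m <- move_spec(sweeps_prod = 80, seed = 99)
  r1 <- run_production(sys, m, seed = 99)
  r2 <- run_production(sys, m, seed = 99)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$forces$Fbar, r2$forces$Fbar)
})

test_that("a closed two-state toy system reaches Boltzmann occupancy", {
  dU <- 1.3
  set.seed(21)
  n <- 40000
  state <- 0L
  occ1 <- 0L
  for (k in seq_len(n)) {
    du <- if (state == 0L) dU else -dU
    if (metropolis_accept(du)) state <- 1L - state
    occ1 <- occ1 + state
  }
  p1 <- occ1 / n
  p1_exp <- exp(-dU) / (1 + exp(-dU))
  # 3 standard errors with a conservative correlation allowance
  se <- sqrt(p1_exp * (1 - p1_exp) / n) * 3
  expect_lt(abs(p1 - p1_exp), 3 * se)
})

test_that("force-symmetric ion-free systems equilibrate immediately", {
  sys <- build_system("parallel_rigid", x = 2, c11_mM = 0, c33_mM = 0,
                      L = 20, seed = 1)
  sys <- local({  # strip counterions: bare mirror-symmetric rods
    keep <- sys$chain_id > 0
    sys$pos <- sys$pos[keep, , drop = FALSE]
    sys$valence <- sys$valence[keep]
    sys$kind <- sys$kind[keep]
    sys$chain_id <- sys$chain_id[keep]
    sys
  })
  eq <- run_until_equilibrium(sys, move_spec(sweeps_equil = 100, seed = 2),
                              window = 20)
  expect_true(eq$converged)
  expect_identical(eq$sweeps, 20)
  expect_equal(eq$trace$F1, eq$trace$F2)
})

test_that("non-convergence raises an error carrying the force trace", {
  sys <- build_system("parallel_rigid", x = 2, c33_mM = 5, L = 16, seed = 5)
  err <- tryCatch(
    run_until_equilibrium(sys, move_spec(sweeps_equil = 40, seed = 6),
                          window = 20, tol = 0),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "not met")
  expect_s3_class(err$trace, "data.frame")
  expect_identical(nrow(err$trace), 40L)
})
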