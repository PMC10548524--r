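## Single-frame trajectory from a structure fixture.
struct_traj <- function(st, n_frames = 1) {
  coords <- array(NA_real_, c(n_frames, nrow(st), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- as.matrix(st[, c("x", "y", "z")])
  trajectory(coords, st[, c("name", "resname", "resno", "chain", "element")],
             times_ns = (seq_len(n_frames) - 1) * 0.05)
}

test_that("chi1 is recovered exactly from constructed side chains", {
  for (chi in c(60, -60, 175, -2.2)) {
    st <- make_fixture_sidechain(chi)
    rs <- compute_chi1(struct_traj(st, 2), resno = 101)
    expect_equal(rs$chi1_deg, rep(chi, 2), tolerance = 1e-9)
  }
  ## -60 reported as -60, not 300
  st <- make_fixture_sidechain(-60)
  expect_equal(compute_chi1(struct_traj(st), 101)$chi1_deg, -60,
               tolerance = 1e-9)
  ## missing atom errors
  st2 <- make_fixture_sidechain(60)
  st2 <- st2[st2$name != "OG", ]
  expect_error(compute_chi1(struct_traj(structure_model(st2)), 101),
               "OG")
})

test_that("rotamer classification partitions the circle with fixed sectors", {
  expect_equal(classify_rotamer(c(175, 55, -65, 120, -120, 0, 180, -179)),
               c("trans", "plus", "minus", "trans", "minus", "plus",
                 "trans", "trans"))
  ## every finite angle gets exactly one state; invariant under +-360
  set.seed(1)
  ang <- runif(500, -1000, 1000)
  s0 <- classify_rotamer(ang)
  expect_false(anyNA(s0))
  expect_identical(classify_rotamer(ang + 360), s0)
  expect_identical(classify_rotamer(ang - 720), s0)
  expect_error(classify_rotamer(Inf), "finite")
})

test_that("rotamer histograms normalize per replica and average correctly", {
  s180 <- rotamer_series(0, 180)
  h <- rotamer_distribution(s180, bin_width = 5)
  expect_equal(nrow(h), 72)
  expect_equal(sum(h$mean_mass), 1, tolerance = 1e-12)
  expect_equal(h$mean_mass[h$bin_lo == 175], 1)
  ## two replicas with disjoint single-bin masses: mean 0.5, population s.d. 0.5
  sA <- rotamer_series(c(0, 0.05), c(60, 60), replica = 1)
  sB <- rotamer_series(c(0, 0.05), c(180, 180), replica = 2)
  h2 <- rotamer_distribution(list(sA, sB), bin_width = 5)
  expect_equal(sum(h2$mean_mass), 1, tolerance = 1e-12)
  occupied <- h2[h2$mean_mass > 0, ]
  expect_equal(occupied$mean_mass, c(0.5, 0.5))
  expect_equal(occupied$sd_mass, c(0.5, 0.5))
  expect_equal(h2$mean_density, h2$mean_mass / 5)
})

test_that("a balanced synthetic rotamer model splits mass evenly", {
  m <- rotamer_model(switch_rates = c(1, 1))
  s <- simulate_rotamer_series(m, rep(FALSE, 2e4), 50, seed = 12)
  h <- rotamer_distribution(s)
  plus_mass <- sum(h$mean_mass[h$bin_mid > 0 & h$bin_mid < 120])
  trans_mass <- sum(h$mean_mass[h$bin_mid > 120 | h$bin_mid < -120])
  expect_lt(abs(plus_mass - 0.5), 0.03)
  expect_lt(abs(trans_mass - 0.5), 0.03)
})

test_that("occupancy-conditioned fractions expose the coupling", {
  m <- rotamer_model(switch_rates = c(0.5, 0.5),
                     occupied_switch_rates = c(5, 0.1))
  occ <- rep(rep(c(TRUE, FALSE), 50), each = 200)
  s <- simulate_rotamer_series(m, occ, 50, seed = 13)
  cf <- conditional_rotamer_fractions(s, occ)
  expect_gt(cf["occupied", "trans"] - cf["unoccupied", "trans"], 0.3)
  ## never-occupied: unoccupied fractions equal unconditional ones
  s0 <- simulate_rotamer_series(m, rep(FALSE, 5000), 50, seed = 14)
  cf0 <- conditional_rotamer_fractions(s0, rep(FALSE, 5000))
  expect_true(all(is.na(cf0["occupied", c("plus", "trans", "minus")])))
  expect_equal(unlist(cf0["unoccupied", c("plus", "trans", "minus")]),
               rotamer_state_fractions(s0), ignore_attr = TRUE)
  expect_error(conditional_rotamer_fractions(s0, rep(TRUE, 10)), "lengths")
})

test_that("independent occupancy leaves conditional fractions unchanged", {
  m <- rotamer_model(switch_rates = c(1, 1))  # no coupling
  n <- 2e4
  s <- simulate_rotamer_series(m, rep(FALSE, n), 50, seed = 15)
  set.seed(16)
  occ <- runif(n) < 0.4  # occupancy independent of the chain
  cf <- conditional_rotamer_fractions(s, occ)
  p_all <- rotamer_state_fractions(s)
  ## correlated frames: effective sample size ~ n / (2 k tau) with dwell
  ## ~20 frames; use 4 s.e. on the effective count
  for (st in c("plus", "trans")) {
    n_eff_o <- sum(occ) / 20
    n_eff_u <- sum(!occ) / 20
    se <- sqrt(p_all[[st]] * (1 - p_all[[st]])) *
      sqrt(1 / n_eff_o + 1 / n_eff_u)
    expect_lt(abs(cf["occupied", st] - cf["unoccupied", st]), 4 * se)
  }
})

test_that("identical frames give zero RMSF", {
  st <- make_fixture_complex(10, 3)
  rf <- superpose_and_rmsf(struct_traj(st, 5), seq_len(nrow(st)))
  expect_equal(rf$rmsf_A, rep(0, nrow(st)), tolerance = 1e-9)
})

test_that("frames differing only by rigid motions give zero RMSF", {
  set.seed(17)
  ref <- matrix(runif(30, 0, 10), 10, 3)
  traj <- simulate_fluctuation_trajectory(ref, fluct_sd = 0, n_frames = 8,
                                          rigid_motion = TRUE, seed = 18)
  rf <- superpose_and_rmsf(traj, 1:10)
  expect_equal(rf$rmsf_A, rep(0, 10), tolerance = 1e-6)
})

test_that("RMSF recovers per-atom spreads and the displaced-atom limit", {
  ## enough atoms that the 6 rigid-body degrees of freedom absorbed by the
  ## superposition are a small fraction (6 / 3N ~ 3%) of each atom's spread
  set.seed(19)
  n_at <- 60
  ref <- matrix(runif(3 * n_at, 0, 20), n_at, 3)
  sds <- seq(0.2, 0.8, length.out = n_at)
  traj <- simulate_fluctuation_trajectory(ref, sds, 600, seed = 20)
  rf <- superpose_and_rmsf(traj, 1:n_at)
  expect_lt(max(abs(rf$rmsf_A - sqrt(3) * sds) / (sqrt(3) * sds)), 0.15)
  ## two frames, one atom displaced by d among many anchors -> RMSF d/2
  n_fix <- 60
  base <- matrix(runif(3 * (n_fix + 1), 0, 30), n_fix + 1, 3)
  coords <- array(NA_real_, c(2, n_fix + 1, 3))
  coords[1, , ] <- base
  base2 <- base
  base2[n_fix + 1, 1] <- base2[n_fix + 1, 1] + 2
  coords[2, , ] <- base2
  traj2 <- trajectory(coords,
                      data.frame(name = "CA", resname = "GLY",
                                 resno = seq_len(n_fix + 1), chain = "A",
                                 element = "C"),
                      times_ns = c(0, 0.05))
  rf2 <- superpose_and_rmsf(traj2, seq_len(n_fix + 1))
  expect_equal(rf2$rmsf_A[n_fix + 1], 1, tolerance = 0.05)
})

test_that("degenerate selections are rejected", {
  coords <- array(0, c(3, 3, 3))
  coords[, , 1] <- matrix(rep(c(0, 1, 2), 3), 3, 3, byrow = TRUE)
  traj <- trajectory(coords + array(0, c(3, 3, 3)),
                     data.frame(name = "CA", resname = "GLY", resno = 1:3,
                                chain = "A", element = "C"),
                     times_ns = c(0, 0.05, 0.1))
  expect_error(superpose_and_rmsf(traj, 1:3), "colinear")
})

test_that("dihedral agrees with the independent oracle on random quadruples", {
  set.seed(21)
  for (i in 1:1000) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    a <- tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                  error = function(e) NA)
    if (is.na(a)) next
    b <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    dd <- abs(a - b) %% 360
    expect_lt(min(dd, 360 - dd), 1e-9)
  }
})
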