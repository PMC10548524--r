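make_point_traj <- function(pos, stride_ps = 50) {
  pos <- rbind(pos)
  coords <- array(NA_real_, c(nrow(pos), 1, 3))
  coords[, 1, ] <- pos
  trajectory(coords,
             data.frame(name = "O1", resname = "OXY", resno = 1L,
                        chain = "A", element = "O"),
             times_ns = (seq_len(nrow(pos)) - 1) * stride_ps / 1000)
}

test_that("all samples at one point give a single unit-probability voxel", {
  traj <- make_point_traj(matrix(rep(c(1.1, 2.2, 3.3), 20), ncol = 3,
                                 byrow = TRUE))
  gs <- grid_spec(c(0, 0, 0), 0.5, c(10, 10, 10))
  d <- accumulate_density(traj, "O1", gs)
  expect_equal(sum(d$prob), 1)
  expect_equal(sum(d$prob > 0), 1)
  expect_equal(max(d$prob), 1)
  expect_equal(d$n_samples, 20)
})

test_that("uniform sampling gives near-uniform voxel probabilities", {
  set.seed(2)
  n <- 1e5
  pos <- matrix(runif(3 * n, 0, 2), ncol = 3)
  gs <- grid_spec(c(0, 0, 0), 0.5, c(4, 4, 4))
  d <- accumulate_density(make_point_traj(pos), 1L, gs)
  p0 <- 1 / 64
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(d$prob - p0) < 4 * se))
})

test_that("sample stride subsamples frames and rejects non-multiples", {
  pos <- matrix(rep(c(0.2, 0.2, 0.2), 11), ncol = 3, byrow = TRUE)
  traj <- make_point_traj(pos, stride_ps = 50)
  gs <- grid_spec(c(0, 0, 0), 0.5, c(2, 2, 2))
  d100 <- accumulate_density(traj, 1L, gs, sample_stride_ps = 100)
  expect_equal(d100$n_samples, 6)  # every other frame of 11
  expect_error(accumulate_density(traj, 1L, gs, sample_stride_ps = 75),
               "multiple")
})

test_that("positions outside the grid error unless clipping is enabled", {
  traj <- make_point_traj(rbind(c(0.2, 0.2, 0.2), c(9, 9, 9)))
  gs <- grid_spec(c(0, 0, 0), 0.5, c(2, 2, 2))
  expect_error(accumulate_density(traj, 1L, gs), "outside the grid")
  d <- accumulate_density(traj, 1L, gs, clip = TRUE)
  expect_equal(d$n_samples, 1)
})

test_that("two separated clouds are detected as two clusters at true centers", {
  set.seed(3)
  mu1 <- c(2, 2, 2); mu2 <- c(8, 7, 6)
  pos <- rbind(matrix(rnorm(3 * 4000, sd = 0.5), ncol = 3) +
                 matrix(mu1, 4000, 3, byrow = TRUE),
               matrix(rnorm(3 * 4000, sd = 0.5), ncol = 3) +
                 matrix(mu2, 4000, 3, byrow = TRUE))
  gs <- grid_spec_from_points(pos, 0.5, 1)
  d <- accumulate_density(make_point_traj(pos), 1L, gs)
  sites <- detect_sites(d, iso_level = 0.01, min_voxels = 2)
  expect_length(sites, 2)
  centers <- rbind(sites[[1]]$center, sites[[2]]$center)
  ## sorted by mass; match each to its nearest true mean, within 1 voxel
  d1 <- min(sqrt(colSums((t(centers) - mu1)^2)))
  d2 <- min(sqrt(colSums((t(centers) - mu2)^2)))
  expect_lt(d1, 0.5)
  expect_lt(d2, 0.5)
  ## labels follow the mass ordering
  expect_identical(unname(vapply(sites, `[[`, "", "label")), c("I", "II"))
  expect_gte(sites[[1]]$mass, sites[[2]]$mass)
})

test_that("an iso level above the maximum density yields no sites", {
  gs <- grid_spec(c(0, 0, 0), 0.5, c(3, 3, 3))
  d <- density_grid_from_values(gs, array(1, c(3, 3, 3)))
  expect_identical(detect_sites(d, iso_level = 10), list())
})

test_that("thresholding an analytic cloud recovers a 15 A^3 site volume", {
  ## isotropic Gaussian density on a fine grid; the level set at radius
  ## r = (3*15 / 4pi)^(1/3) encloses 15 A^3. The detected voxel count must
  ## equal the direct center-in-sphere count, and the volume the analytic
  ## value within the lattice discretization (~5% at 0.25 A spacing).
  h <- 0.25
  gs <- grid_spec(c(-3, -3, -3), h, c(24, 24, 24))
  ctr <- .5 * h + h * (0:23) - 3
  g <- expand.grid(x = ctr, y = ctr, z = ctr)
  r2 <- g$x^2 + g$y^2 + g$z^2
  dens_vals <- array(exp(-r2 / 2), dim = c(24, 24, 24))
  d <- density_grid_from_values(gs, dens_vals)
  r_sphere <- (3 * 15 / (4 * pi))^(1 / 3)
  iso <- exp(-r_sphere^2 / 2) / sum(dens_vals) / h^3  # density at radius r
  sites <- detect_sites(d, iso_level = iso)
  expect_length(sites, 1)
  n_direct <- sum(r2 <= r_sphere^2 + 1e-12)
  expect_equal(length(sites[[1]]$voxels), n_direct)
  expect_equal(sites[[1]]$volume_A3, 15, tolerance = 0.05)
})

test_that("Boltzmann inversion gives the closed-form energy gap", {
  gs <- grid_spec(c(0, 0, 0), 1, c(2, 1, 1))
  d <- density_grid_from_values(gs, array(c(exp(1), 1), c(2, 1, 1)))
  fe <- boltzmann_invert(d, 300)
  expect_equal(fe$values[1, 1, 1], 0)
  expect_equal(fe$values[2, 1, 1], 1.9872e-3 * 300, tolerance = 1e-9)
  ## uniform -> all zero
  u <- boltzmann_invert(density_grid_from_values(
    grid_spec(c(0, 0, 0), 1, c(3, 3, 1)), array(5, c(3, 3, 1))), 300)
  expect_true(all(u$values == 0))
})

test_that("free energy is monotone in probability and masks empty voxels", {
  set.seed(4)
  gs <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  vals <- array(rpois(64, 20), dim = c(4, 4, 4))
  vals[1, 1, 1] <- 0
  d <- density_grid_from_values(gs, vals)
  d$counts <- vals  # counts semantics for masking
  fe <- boltzmann_invert(d, 310)
  expect_true(is.na(fe$values[1, 1, 1]))
  ord_p <- order(d$prob[vals > 0])
  ord_g <- order(-fe$values[vals > 0])
  expect_equal(ord_p, ord_g)
  expect_equal(min(fe$values, na.rm = TRUE), 0)
})

test_that("reweighting with zero or constant bias equals plain accumulation", {
  set.seed(5)
  pos <- matrix(runif(3 * 500, 0, 3), ncol = 3)
  traj <- make_point_traj(pos)
  gs <- grid_spec(c(0, 0, 0), 0.5, c(6, 6, 6))
  plain <- accumulate_density(traj, 1L, gs)
  rw0 <- reweight_biased(traj, rep(0, 500), gs, 300)
  rwc <- reweight_biased(traj, rep(2.5, 500), gs, 300)
  expect_equal(rw0$prob, plain$prob, tolerance = 1e-12)
  expect_equal(rwc$prob, plain$prob, tolerance = 1e-12)
  expect_error(reweight_biased(traj, rep(0, 10), gs), "does not match")
  expect_error(reweight_biased(traj, c(NA, rep(0, 499)), gs), "finite")
})

test_that("reweighting a known linear bias recovers a uniform density", {
  ## sampling follows exp(-V/kBT) on a 1D lattice of 8 cells (flat true
  ## landscape + bias V); weighting by exp(+V/kBT) must undo it.
  set.seed(6)
  kT <- 1.9872e-3 * 300
  ncell <- 8
  V <- 0.35 * (0:(ncell - 1))  # kcal/mol, linear
  p_bias <- exp(-V / kT) / sum(exp(-V / kT))
  n <- 4e4
  cell <- sample.int(ncell, n, replace = TRUE, prob = p_bias)
  pos <- cbind((cell - 0.5) * 0.5, 0.25, 0.25)
  traj <- make_point_traj(pos)
  gs <- grid_spec(c(0, 0, 0), 0.5, c(ncell, 1, 1))
  rw <- reweight_biased(traj, V[cell], gs, 300)
  w <- exp((V - max(V)) / kT) * p_bias
  n_eff <- n * sum(w)^2 / sum(w^2 / p_bias) / sum(p_bias * 0 + 1)
  ## per-voxel tolerance: 4 s.e. of the importance-sampling estimate
  p_hat <- rw$prob[, 1, 1]
  for (i in seq_len(ncell)) {
    se_i <- sqrt(p_bias[i] * (1 - p_bias[i]) / n) *
      exp((V[i] - max(V)) / kT) / sum(exp((V - max(V)) / kT) * p_bias)
    expect_lt(abs(p_hat[i] - 1 / ncell), 4 * se_i + 1e-3)
  }
})

test_that("minimax barrier matches construction and brute-force oracle", {
  ## 1D double well: values 0 | 2 | 0.5 along x
  gs <- grid_spec(c(0, 0, 0), 1, c(5, 1, 1))
  prof <- c(0, 1, 2, 1.2, 0.5)
  d <- density_grid_from_values(gs, array(exp(-prof), c(5, 1, 1)))
  fe <- boltzmann_invert(d, 1 / 1.9872e-3)  # kT = 1 -> values = prof
  expect_equal(fe$values[, 1, 1], prof, tolerance = 1e-9)
  res <- barrier_and_ratio(fe, 1L, 5L)
  expect_equal(res$barrier_kcal, 2)
  ## flat landscape -> barrier 0, ratio 1
  dflat <- density_grid_from_values(gs, array(1, c(5, 1, 1)))
  feflat <- boltzmann_invert(dflat, 300)
  rflat <- barrier_and_ratio(feflat, 1L, 5L, 300, reference_barrier = 0)
  expect_equal(rflat$barrier_kcal, 0)
  expect_equal(rflat$ratio_vs_reference, 1)
  ## random small grids vs Dijkstra widest-path oracle
  for (s in 1:4) {
    set.seed(100 + s)
    dims <- c(4, 4, 4)
    vals <- array(runif(prod(dims), 0.05, 1), dim = dims)
    dg <- density_grid_from_values(grid_spec(c(0, 0, 0), 1, dims), vals)
    fe2 <- boltzmann_invert(dg, 300)
    a <- 1L; b <- prod(dims)
    res2 <- barrier_and_ratio(fe2, a, b)
    lvl <- oracle_minimax_level(fe2$values, fe2$mask, a, b)
    expect_equal(res2$saddle_kcal, lvl, tolerance = 1e-12)
  }
})

test_that("a disconnected mask is reported as having no finite path", {
  gs <- grid_spec(c(0, 0, 0), 1, c(5, 1, 1))
  vals <- array(c(1, 1, 0, 1, 1), c(5, 1, 1))
  d <- density_grid_from_values(gs, vals)
  d$counts <- vals
  fe <- boltzmann_invert(d, 300)
  expect_error(barrier_and_ratio(fe, 1L, 5L), "no finite path")
})

test_that("Boltzmann ratio of the entry barriers is about 56-fold", {
  expect_equal(boltzmann_ratio(4.1, 6.5, 300), 56.0, tolerance = 0.01)
  expect_equal(boltzmann_ratio(6.5, 4.1, 300), 1 / 56.0, tolerance = 0.01)
})

test_that("detected sites are independent of voxel iteration order", {
  set.seed(7)
  pos <- matrix(rnorm(3 * 2000, sd = 0.8), ncol = 3) + 3
  gs <- grid_spec(c(0, 0, 0), 0.5, c(12, 12, 12))
  d <- accumulate_density(make_point_traj(pos), 1L, gs)
  s1 <- detect_sites(d, 0.005)
  s2 <- detect_sites(d, 0.005)
  expect_identical(site_table(s1), site_table(s2))
})
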