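## Trajectory of a particle moving radially: distance from origin given per
## frame, placed along +x.
dist_traj <- function(d, stride_ps = 50) {
  coords <- array(0, c(length(d), 1, 3))
  coords[, 1, 1] <- d
  trajectory(coords,
             data.frame(name = "O1", resname = "OXY", resno = 1L,
                        chain = "A", element = "O"),
             times_ns = (seq_along(d) - 1) * stride_ps / 1000)
}

rsite <- region_spec("R-site", center = c(0, 0, 0), radius = 2,
                     outer_radius = 3)

test_that("a particle inside for the whole run is one censored event", {
  ev <- detect_events(dist_traj(rep(1, 100)), "O1", rsite)
  expect_equal(nrow(ev), 1)
  expect_true(ev$censored[1])
  expect_equal(ev$duration_ns[1], 99 * 0.05)
})

test_that("square-wave excursions give the constructed dwell times", {
  ## three visits of 10, 20, 40 frames separated by far excursions
  d <- c(rep(10, 5), rep(1, 10), rep(10, 5), rep(1, 20), rep(10, 5),
         rep(1, 40), rep(10, 5))
  ev <- detect_events(dist_traj(d), "O1", rsite)
  expect_equal(nrow(ev), 3)
  expect_false(any(ev$censored))
  expect_equal(ev$duration_ns, c(10, 20, 40) * 0.05)
})

test_that("hysteresis bridges flicker between the inner and outer radius", {
  ## mid-dwell excursion to d = 2.5 (outside inner, inside outer): 1 event
  d <- c(rep(10, 3), rep(1, 10), 2.5, rep(1, 10), rep(10, 5))
  ev <- detect_events(dist_traj(d), "O1", rsite)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_ns[1], 21 * 0.05)
  ## but a crossing beyond the outer radius splits it
  d2 <- c(rep(10, 3), rep(1, 10), 3.5, rep(1, 10), rep(10, 5))
  ev2 <- detect_events(dist_traj(d2), "O1", rsite)
  expect_equal(nrow(ev2), 2)
})

test_that("events shorter than min_frames_inside are discarded", {
  d <- c(rep(10, 3), 1, rep(10, 3), rep(1, 5), rep(10, 3))
  ev <- detect_events(dist_traj(d), "O1", rsite, min_frames_inside = 2)
  expect_equal(nrow(ev), 1)  # the 1-frame touch is dropped
  ev0 <- detect_events(dist_traj(d), "O1", rsite, min_frames_inside = 1)
  expect_equal(nrow(ev0), 2)
})

test_that("region centered on a reference atom follows that atom", {
  coords <- array(0, c(10, 2, 3))
  coords[, 1, 1] <- 1:10          # particle drifts away in x
  coords[, 2, 1] <- c(1:5, rep(0, 5))  # center follows it for 5 frames
  traj <- trajectory(coords,
                     data.frame(name = c("O1", "OG"), resname = c("OXY", "SER"),
                                resno = 1:2, chain = "A",
                                element = c("O", "O")),
                     times_ns = (0:9) * 0.05)
  reg <- region_spec("near-OG", atom = "OG", radius = 2, outer_radius = 2.5)
  ev <- detect_events(traj, "O1", reg)
  expect_equal(nrow(ev), 1)
  expect_false(ev$censored[1])
})

test_that("summary statistics reproduce the censored-run bookkeeping", {
  ## 29/30 escapes
  ev1 <- event_table(data.frame(
    run_id = 1:30,
    duration_ns = c(seq(2, 30, length.out = 29), 50),
    censored = c(rep(FALSE, 29), TRUE)), cutoff = 50)
  s1 <- summarize_events(ev1)
  expect_equal(s1$escape_fraction_pct, 100 * 29 / 30)
  expect_lt(abs(s1$escape_fraction_pct - 96.6), 0.1)
  ## 2/30 escapes with the observed durations 33.1 and 47.5 ns
  ev2 <- event_table(data.frame(
    run_id = 1:30,
    duration_ns = c(33.1, 47.5, rep(50, 28)),
    censored = c(FALSE, FALSE, rep(TRUE, 28))), cutoff = 50)
  s2 <- summarize_events(ev2)
  expect_equal(s2$escape_fraction_pct, 100 * 2 / 30)
  expect_lt(abs(s2$escape_fraction_pct - 6.7), 0.1)
  expect_equal(s2$mean_ns, 40.3)
  ## single escape: mean defined, s.e.m. missing
  s3 <- summarize_events(event_table(data.frame(
    run_id = 1, duration_ns = 4.2, censored = FALSE)))
  expect_equal(s3$mean_ns, 4.2)
  expect_true(is.na(s3$sem_ns))
})

test_that("censored-exponential MLE matches hand-computed cases", {
  ev <- event_table(data.frame(run_id = 1:3, duration_ns = c(1, 2, 3),
                               censored = FALSE))
  expect_equal(fit_koff(ev)$koff_inv_ns, 2)
  ev2 <- event_table(data.frame(run_id = 1:4, duration_ns = c(1, 2, 3, 4),
                                censored = c(FALSE, FALSE, FALSE, TRUE)),
                     cutoff = 4)
  expect_equal(fit_koff(ev2)$koff_inv_ns, 10 / 3)
  ## invariant under event order; equals sample mean when uncensored
  shuf <- ev2[c(3, 1, 4, 2), ]
  attr(shuf, "cutoff") <- 4
  class(shuf) <- class(ev2)
  expect_equal(fit_koff(shuf)$koff_inv_ns, 10 / 3)
  ## zero escapes: lower bound only
  ev3 <- event_table(data.frame(run_id = 1:2, duration_ns = c(5, 5),
                                censored = TRUE), cutoff = 5)
  expect_warning(f3 <- fit_koff(ev3), "lower bound")
  expect_true(is.na(f3$koff_inv_ns))
  expect_equal(f3$lower_bound_ns, 10)
})

test_that("MLE agrees with the survival-model oracle on censored data", {
  ev <- simulate_escape_events(escape_model(15, 50, 200), seed = 77)
  fit <- survival::survreg(
    survival::Surv(duration_ns, !censored) ~ 1,
    data = as.data.frame(ev), dist = "exponential")
  expect_equal(fit_koff(ev)$koff_inv_ns, exp(unname(coef(fit))),
               tolerance = 1e-6)
})

test_that("both estimators recover the true k_off^-1 at the study scale", {
  set.seed(88)
  est <- replicate(200, fit_koff(simulate_escape_events(
    escape_model(15, 50, 30)))$koff_inv_ns)
  ## MLE s.e. per batch ~ 15/sqrt(n_esc~29); average of 200 batches
  expect_lt(abs(mean(est) - 15), 3 * (15 / sqrt(29)) / sqrt(200) + 0.2)
  ## cumulative fit converges to the MLE for large n
  ev <- simulate_escape_events(escape_model(15, 50, 5000), seed = 89)
  mle <- fit_koff(ev)$koff_inv_ns
  cum <- fit_koff(ev, "cumulative")$koff_inv_ns
  expect_lt(abs(cum - mle) / mle, 0.02)
})

test_that("detect_events on the hopping generator recovers the dwell law", {
  ## site 1 inside the region (dwell mean 5 ns), site 2 far outside
  m <- hopping_model(rbind(c(0, 0, 0), c(10, 0, 0)),
                     rbind(c(0, 0.2), c(0.5, 0)), noise_sd = 0.3)
  r <- simulate_hopping_trajectory(m, 2000, 50, seed = 99)
  reg <- region_spec("site1", center = c(0, 0, 0), radius = 1.5,
                     outer_radius = 2.5)
  ev <- detect_events(r$trajectory, "O1", reg)
  esc <- ev$duration_ns[!ev$censored]
  expect_gt(length(esc), 100)
  expect_lt(abs(mean(esc) - 5), 3 * 5 / sqrt(length(esc)))
})

test_that("truncated mean has the closed form and its limits", {
  expect_equal(truncated_mean(15, 50), 13.15031, tolerance = 1e-6)
  expect_equal(truncated_mean(15, Inf), 15)
  expect_equal(truncated_mean(7, 1e6), 7, tolerance = 1e-9)
  ## c << m: escapes look uniform on (0, c) -> mean ~ c/2
  expect_equal(truncated_mean(1e5, 0.01), 0.005, tolerance = 1e-4)
  expect_error(truncated_mean(-1, 10), "> 0")
})

test_that("simulated uncensored means sit inside the truncated-mean band", {
  set.seed(101)
  means <- replicate(200, {
    e <- simulate_escape_events(escape_model(15, 50, 30))
    mean(e$duration_ns[!e$censored])
  })
  expect_lt(abs(mean(means) - truncated_mean(15, 50)), 0.5)
})
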