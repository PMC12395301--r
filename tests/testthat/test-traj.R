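test_that("frame alignment removes rigid motion and restores noisy frames to the sigma band", {
  sim <- make_two_state_trajectory(n_frames = 3, sigma = 0, seed = 1)
  ref <- sim$e2pi
  tm <- sort(unlist(sim$selections$helices))

  # identical frame: zero RMSD
  t0 <- new_trajectory(list(ref), 0)
  expect_equal(rmsd_series(align_frames(t0, ref, tm), ref, tm), 0,
               tolerance = 1e-8)

  # rigidly moved frame: zero RMSD after alignment
  R <- rotation_matrix(c(1, 2, 3), 37)
  moved <- sweep(ref %*% t(R), 2, c(5, -3, 8), "+")
  t1 <- new_trajectory(list(moved), 0)
  aligned <- align_frames(t1, ref, tm)
  expect_equal(rmsd_series(aligned, ref, tm), 0, tolerance = 1e-6)
  # alignment must not increase the RMSD
  expect_lte(rmsd_series(aligned, ref, tm),
             rmsd_series(t1, ref, tm) + 1e-9)

  # Monte-Carlo: noisy frames land in the expected RMSD band around
  # sigma * sqrt(3)
  set.seed(99)
  frames <- lapply(1:100, function(i)
    ref + matrix(rnorm(length(ref), 0, 0.5), nrow(ref), 3))
  tn <- align_frames(new_trajectory(frames, 1:100), ref, tm)
  r <- rmsd_series(tn, ref, tm)
  expect_true(all(r > 0.3 * sqrt(3) & r < 0.7 * sqrt(3)))
})

test_that("equilibration trim removes early frames by timestamp", {
  sim <- make_two_state_trajectory(n_frames = 400, sigma = 0,
                                   total_time = 400, seed = 1)
  trimmed <- equilibration_trim(sim$traj, 50)
  expect_true(all(trimmed$times > 50))
  # count oracle for the uniform 400-frame grid over [0, 400]
  expect_equal(length(trimmed), sum(sim$traj$times > 50))
  expect_equal(length(equilibration_trim(sim$traj, 0)), 400L)
  expect_error(equilibration_trim(sim$traj, 1000), "every frame")
})

test_that("RMSD matches hand computation and scales linearly in deviations", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0))
  f1 <- rbind(c(0, 0, 1), c(1, 0, 2))    # per-atom deviations 1 and 2
  tr <- new_trajectory(list(ref, f1), 0:1)
  r <- rmsd_series(tr, ref)
  expect_equal(r[1], 0)
  expect_equal(r[2], sqrt((1 + 4) / 2))
  f2 <- ref + 2 * (f1 - ref)
  expect_equal(rmsd_series(new_trajectory(list(f2), 0), ref), 2 * r[2])
})

test_that("tilt angle reproduces constructed geometries", {
  # scaffold: kink vector along x, anchor at origin
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  sel <- list(kink_a = 1, kink_b = 2, basal_anchor = 3, a_domain = 4)
  mk <- function(v2) rbind(base, v2)
  expect_equal(tilt_angle(mk(c(3, 0, 0)), sel), 0)
  expect_equal(tilt_angle(mk(c(0, 5, 0)), sel), 90)
  expect_equal(tilt_angle(mk(c(-2, 0, 0)), sel), 180)
  # rotate a reference direction by a known 23 degrees about z
  v <- as.numeric(rotation_matrix(c(0, 0, 1), 23) %*% c(4, 0, 0))
  expect_equal(tilt_angle(mk(v), sel), 23, tolerance = 0.5)
  expect_error(tilt_angle(mk(c(0, 0, 0)), sel), "zero-length")
})

test_that("delta distance is a center-of-mass Euclidean distance", {
  e1 <- matrix(rnorm(30), 10, 3)
  expect_equal(delta_distance(e1, e1, 1:10), 0)
  shifted <- sweep(e1, 2, c(3, 4, 0), "+")
  expect_equal(delta_distance(shifted, e1, 1:10), 5)
  # oracle on random rigid placements
  set.seed(7)
  for (k in 1:20) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 180))
    tr <- rnorm(3, sd = 10)
    placed <- sweep(e1 %*% t(R), 2, tr, "+")
    expect_equal(delta_distance(placed, e1, 1:10),
                 sqrt(sum((colMeans(placed) - colMeans(e1))^2)))
  }
})

test_that("movement score honors the endpoint, fraction and sign conventions", {
  e2pi <- c(60, 12); e1 <- c(40, 0)
  expect_equal(movement_score(e1, e2pi, e1), 100)
  expect_equal(movement_score(e2pi, e2pi, e1), 0)
  f25 <- e2pi + 0.25 * (e1 - e2pi)
  expect_equal(movement_score(f25, e2pi, e1), 25)
  beyond <- e1 + 1.5 * (e2pi - e1)   # past E2Pi, away from E1
  expect_equal(movement_score(beyond, e2pi, e1), -50)
  expect_error(movement_score(c(1, 1), c(2, 3), c(2, 3)), "zero target")
})

test_that("movement score is invariant to isotropic but not anisotropic rescaling", {
  f <- c(50, 2); e2pi <- c(60, 12); e1 <- c(40, 0)
  s0 <- movement_score(f, e2pi, e1)
  iso <- function(v) v * 3.7
  expect_equal(movement_score(iso(f), iso(e2pi), iso(e1)), s0)
  aniso <- function(v) v * c(1, 10)
  expect_false(isTRUE(all.equal(
    movement_score(aniso(f), aniso(e2pi), aniso(e1)), s0)))
})

test_that("score density integrates to one and finds planted modes", {
  x <- c(rnorm(500, -20, 2), rnorm(500, 60, 2))
  d <- score_density(x, bins = 40)
  expect_equal(sum(d$table$density * d$table$width), 1)
  expect_equal(d$max_score, max(x))
  # two modes at the planted locations (within a bin width)
  dens <- d$table
  top2 <- dens$mid[order(dens$density, decreasing = TRUE)][1:4]
  expect_true(any(abs(top2 - -20) <= max(dens$width)))
  expect_true(any(abs(top2 - 60) <= max(dens$width)))

  const <- score_density(rep(3, 10))
  expect_equal(nrow(const$table), 1L)
  expect_equal(const$max_score, 3)
})

test_that("helix DDMs vanish on self and rigid motion and recover a planted block shift", {
  sim <- make_two_state_trajectory(n_frames = 5, sigma = 0,
                                   block2_shift = 2, seed = 1)
  hel <- sim$selections$helices
  expect_equal(helix_ddm(sim$e2pi, sim$e2pi, hel),
               matrix(0, 8, 8, dimnames = list(names(hel), names(hel))))

  R <- rotation_matrix(c(0, 1, 1), 50)
  moved <- sweep(sim$e2pi %*% t(R), 2, c(10, -5, 2), "+")
  expect_equal(max(abs(helix_ddm(moved, sim$e2pi, hel))), 0,
               tolerance = 1e-9)

  ddm <- helix_ddm(sim$traj$frames[[5]], sim$e2pi, hel)
  expect_identical(ddm, t(ddm))
  s <- interblock_summary(ddm)
  expect_equal(s$max_interblock, 2)
  expect_equal(s$mean_intrablock, 0)

  # relabeling helices within a block leaves the summary unchanged
  s2 <- interblock_summary(ddm, blocks = list(
    b1 = c("M2", "MA", "M1", "MB"), b2 = c("M6", "M3", "M5", "M4")))
  expect_equal(s2, s, ignore_attr = TRUE)

  expect_error(helix_ddm(sim$e2pi, sim$e2pi, hel[1:7]), "8 named helix")
})

test_that("noise-free trajectories score exactly 100 t and noisy ones recover the slope", {
  sim <- make_two_state_trajectory(n_frames = 21, sigma = 0, seed = 1)
  mo <- motion_analysis(sim$traj, sim$e2pi, sim$e1, sim$selections)
  expect_equal(mo$score, 100 * sim$t, tolerance = 1e-9)
  # monotone in the ground-truth parameter
  expect_true(all(diff(mo$score) > 0))

  sim2 <- make_two_state_trajectory(n_frames = 400, sigma = 0.5, seed = 42)
  mo2 <- motion_analysis(sim2$traj, sim2$e2pi, sim2$e1, sim2$selections)
  slope <- unname(stats::coef(stats::lm(mo2$score ~ sim2$t))[2])
  expect_lt(abs(slope - 100) / 100, 0.05)
})
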