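const_traj <- function(conf, k) trajectory(rep(list(conf), k), seq_len(k))

test_that("end_to_end_series computes per-frame terminal distances", {
  ext <- build_extended_conformation(10, 2)
  expect_equal(end_to_end_series(const_traj(ext, 5))$values, rep(18, 5))
  f1 <- conformation(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)))
  f2 <- conformation(rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 5)))
  expect_equal(end_to_end_series(trajectory(list(f1, f2), 1:2))$values,
               c(10, 5))
})

test_that("kabsch superposition is exact on rigid copies and beats a rotation grid", {
  ref <- random_conformation(12, seed = 1)
  expect_lt(kabsch_superpose(ref, ref)$rmsd, 1e-9)
  # rigid transform invariance
  R <- random_rotation()
  moved <- conformation(sweep(ref$coordinates %*% R, 2, c(3, -7, 11), "+"))
  expect_lt(kabsch_superpose(ref, moved)$rmsd, 1e-6)
  # brute-force random-rotation oracle on a perturbed copy
  set.seed(2)
  mob <- conformation(ref$coordinates + matrix(rnorm(36), ncol = 3))
  rmsd <- kabsch_superpose(ref, mob)$rmsd
  expect_lte(rmsd, grid_rmsd_oracle(ref, mob, 2000, seed = 3) + 1e-6)
  # symmetry after optimal superposition
  expect_equal(rmsd, kabsch_superpose(mob, ref)$rmsd, tolerance = 1e-9)
  # proper rotation, never a reflection
  expect_equal(det(kabsch_superpose(ref, mob)$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(ref, random_conformation(5, 1)), "differ")
})

test_that("rmsd_series is zero exactly where a frame equals the reference", {
  ref <- build_extended_conformation(8, 3)
  other <- random_conformation(8, seed = 5)
  tr <- trajectory(list(other, ref, other), 1:3)
  rs <- rmsd_series(tr, ref)$values
  expect_lt(rs[2], 1e-9)
  expect_gt(rs[1], 0.1)
})

test_that("equilibration detection finds the stable tail", {
  # constant series stabilises immediately
  s <- scalar_series(rep(5, 200))
  expect_equal(as.integer(detect_equilibration(s, window = 50)), 1L)
  # ramp then constant tail: detected inside the tail region
  ramp <- scalar_series(c(seq(10, 1, length.out = 150), rep(1, 150)))
  idx <- detect_equilibration(ramp, window = 100, rel_tol = 0.25)
  expect_true(attr(idx, "converged"))
  expect_gte(as.integer(idx), 51)  # window must already overlap the tail
  expect_lte(as.integer(idx), 201)
  # pure noise never stabilises below a tiny tolerance: flagged
  set.seed(8)
  noisy <- scalar_series(abs(rnorm(300)) + 1)
  expect_warning(res <- detect_equilibration(noisy, window = 100,
                                             rel_tol = 0.01),
                 "last admissible")
  expect_false(attr(res, "converged"))
  expect_error(detect_equilibration(scalar_series(1:10), window = 50),
               "shorter")
})

test_that("trajectory summaries use the sample SD over the equilibrated tail", {
  expect_equal(summarize_trajectory(scalar_series(rep(3.5, 10))),
               c(mean = 3.5, sd = 0))
  expect_equal(summarize_trajectory(scalar_series(c(1, 2, 3))),
               c(mean = 2, sd = 1))
  s <- scalar_series(c(100, 100, 4, 6))
  expect_equal(summarize_trajectory(s, eq_start = 3)[["mean"]], 5)
  expect_error(summarize_trajectory(s, eq_start = 4), "fewer than 2")
})

test_that("replicate combination reproduces the zero-force table summary rows", {
  g1 <- combine_trajectories(c(40.1, 33.4, 43.9))
  expect_equal(round(g1[["grand_mean"]]), 39)
  expect_equal(round(g1[["spread"]]), 3)
  expect_equal(g1[["grand_mean"]], mean(c(40.1, 33.4, 43.9)))
  expect_equal(g1[["spread"]], sd(c(40.1, 33.4, 43.9)) / sqrt(3))
  g2 <- combine_trajectories(c(52.3, 60.1, 68.8))
  expect_equal(round(g2[["grand_mean"]]), 60)
  expect_equal(round(g2[["spread"]]), 5)
  expect_equal(combine_trajectories(c(7, 7, 7))[["spread"]], 0)
  expect_error(combine_trajectories(42), "at least 2")
})

test_that("equilibrium_summary aggregates per-trajectory rows", {
  per <- data.frame(mean_L_A = c(40.1, 33.4, 43.9), sd_L_A = c(14.6, 20.5, 15.1))
  eq <- equilibrium_summary(per)
  expect_equal(eq$grand_mean, 39.13333, tolerance = 1e-5)
  expect_equal(eq$n_trajectories, 3L)
  single <- equilibrium_summary(per[1, , drop = FALSE])
  expect_true(is.na(single$grand_spread))
})
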