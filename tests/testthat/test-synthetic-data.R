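test_that("extended conformations have the prescribed end-to-end length", {
  expect_equal(end_to_end(build_extended_conformation(2, 3.4)), 3.4)
  expect_equal(end_to_end(build_extended_conformation(36, 118.1 / 35)),
               118.1, tolerance = 0.01)
  expect_equal(end_to_end(build_extended_conformation(50, 166.5 / 49)),
               166.5, tolerance = 0.01)
  expect_error(build_extended_conformation(1, 3.4), ">= 2")
  expect_error(build_extended_conformation(5, 0), "> 0")
})

test_that("fragment_spec enforces geometry and ladder invariants", {
  frs <- masp_fragments()
  expect_equal(frs$MaSp1a$n_residues, 36L)
  expect_equal(frs$MaSp1a$l_max, 118.1)
  expect_equal(frs$MaSp2.2a$rise_per_residue, 166.5 / 49)
  expect_error(fragment_spec("x", 10, l_max = 30, rise_per_residue = 5),
               "inconsistent")
  expect_error(fragment_spec("x", 10, l_max = 30, force_ladder = c(5, 5)),
               "strictly increasing")
})

test_that("exact sampler obeys the random-walk and Langevin closed forms", {
  m <- chain_model(15, 8.1, 298)
  s0 <- sample_fjc_end_to_end(m, 0, 20000, seed = 101)
  msq <- mean(s0$magnitudes^2)
  se <- sd(s0$magnitudes^2) / sqrt(20000)
  expect_lt(abs(msq - 15 * 8.1^2), 3 * se)
  # isotropy at zero force
  for (k in 1:3)
    expect_lt(abs(mean(s0$vectors[, k])),
              3 * sd(s0$vectors[, k]) / sqrt(20000))
  # tilted sampling matches the closed form
  s50 <- sample_fjc_end_to_end(m, 50, 20000, seed = 102)
  se50 <- sd(s50$z) / sqrt(20000)
  expect_lt(abs(mean(s50$z) - fjc_extension(50, m)), 3 * se50)
  # saturation
  shi <- sample_fjc_end_to_end(m, 1e4, 5000, seed = 103)
  expect_lt(abs(mean(shi$z) - contour_length(m)) / contour_length(m), 0.01)
  expect_error(sample_fjc_end_to_end(m, -1, 10), ">= 0")
})

test_that("sampler is a pure function of its seed", {
  m <- chain_model(10, 5)
  a <- sample_fjc_end_to_end(m, 30, 100, seed = 9)
  b <- sample_fjc_end_to_end(m, 30, 100, seed = 9)
  expect_identical(a, b)
  c <- sample_fjc_end_to_end(m, 30, 100, seed = 10)
  expect_false(identical(a$z, c$z))
})

test_that("BD trajectories replay bit-identically from the same seed", {
  m <- chain_model(8, 8.1, 298)
  frag <- fragment_spec("mini", 9, l_max = 8 * 8.1)
  bd <- bd_params(n_steps = 5e4, save_stride = 500, seed = 4)
  t1 <- simulate_trajectory(frag, m, 100, bd)
  t2 <- simulate_trajectory(frag, m, 100, bd)
  expect_identical(t1$frames, t2$frames)
  expect_equal(length(t1), 100)
})

test_that("BD stability guard rejects reckless settings before running", {
  m <- chain_model(8, 8.1, 298)
  frag <- fragment_spec("mini", 9, l_max = 8 * 8.1)
  expect_error(
    simulate_trajectory(frag, m, 0, bd_params(timestep = 1e-2)),
    "unstable")
  expect_error(
    simulate_trajectory(frag, m, 0,
                        bd_params(timestep = 2e-4, bond_stiffness = 200)),
    "unstable")
})

test_that("BD chain relaxes from full extension and saturates under high force", {
  m <- chain_model(8, 8.1, 298)
  frag <- fragment_spec("mini", 9, l_max = 8 * 8.1)
  # zero force: downward trend from the extended start
  tr <- simulate_trajectory(frag, m, 0,
                            bd_params(n_steps = 2e6, save_stride = 2e3, seed = 21))
  v <- end_to_end_series(tr)$values
  dec <- length(v) %/% 10
  expect_gt(mean(v[1:dec]), mean(v[(length(v) - dec + 1):length(v)]))
  expect_lt(mean(v[(length(v) %/% 2):length(v)]), 0.6 * contour_length(m))
  # high force: stationary mean within 5% of the contour length
  th <- simulate_trajectory(frag, m, 600,
                            bd_params(n_steps = 5e5, save_stride = 500, seed = 22))
  vh <- end_to_end_series(th)$values
  vh <- vh[-(1:100)]
  expect_lt(abs(mean(vh) - contour_length(m)) / contour_length(m), 0.05)
})

test_that("BD stationary mean-square end-to-end matches the FJC sampler", {
  m <- chain_model(8, 8.1, 298)
  frag <- fragment_spec("mini", 9, l_max = 8 * 8.1)
  tr <- simulate_trajectory(frag, m, 0,
                            bd_params(n_steps = 4e7, save_stride = 4e3, seed = 31))
  v <- end_to_end_series(tr)$values
  v <- v[-(1:1000)]  # burn-in: first tenth
  expect_lt(abs(mean(v^2) - m$n_links * m$link_length^2) /
            (m$n_links * m$link_length^2), 0.10)
})

test_that("run_force_ladder summarises every rung with rising extension", {
  m <- chain_model(8, 8.1, 298)
  frag <- fragment_spec("mini", 9, l_max = 8 * 8.1,
                        force_ladder = c(20, 100, 300, 600))
  lad <- run_force_ladder(frag, m,
                          bd_params(n_steps = 4e5, save_stride = 400),
                          seed = 7)
  expect_equal(nrow(lad$summary), 4)
  expect_true(all(diff(lad$summary$mean_L_A) > 0))
  # tighter fluctuations at high force
  expect_lt(lad$summary$sd_L_A[4], lad$summary$sd_L_A[1])
  expect_equal(lad$summary$seed, 7 + 1:4)
})
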