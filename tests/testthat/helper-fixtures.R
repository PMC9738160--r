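# Shared fixtures and independent mini-oracles for the test suite.

# Independent root finder for the inverse Langevin: plain bisection on
# coth(x) - 1/x = y over a wide bracket. Used to freeze expected values
# without touching the package's Newton solver.
bisect_inv_langevin <- function(y, lo = 1e-9, hi = 50, iter = 200) {
  f <- function(x) 1 / tanh(x) - 1 / x - y
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Noiseless force-extension summary generated straight from the Langevin
# closed form (no call into the fitting path).
noiseless_summary <- function(a, n_links, temperature = 298,
                              forces = default_force_ladder(), sd = 1) {
  ext <- n_links * a * (1 / tanh(forces * a / (kB * temperature)) -
                        (kB * temperature) / (forces * a))
  data.frame(force_pN = forces, mean_L_A = ext, sd_L_A = sd, n_frames = 1000L)
}

# As noiseless_summary, but parameterised by the contour length directly:
# extension = l_max * L(F a / kT).
noiseless_summary_lmax <- function(a, l_max, temperature = 298,
                                   forces = default_force_ladder(), sd = 1) {
  ext <- l_max * (1 / tanh(forces * a / (kB * temperature)) -
                  (kB * temperature) / (forces * a))
  data.frame(force_pN = forces, mean_L_A = ext, sd_L_A = sd, n_frames = 1000L)
}

# Monte-Carlo force-extension summary from the exact sampler.
mc_summary <- function(model, forces = default_force_ladder(),
                       n_samples = 2000, seed = 123) {
  rows <- lapply(seq_along(forces), function(i) {
    s <- sample_fjc_end_to_end(model, forces[i], n_samples, seed = seed + i)
    data.frame(force_pN = forces[i], mean_L_A = mean(s$z), sd_L_A = sd(s$z),
               n_frames = n_samples)
  })
  do.call(rbind, rows)
}

# Random compact conformation (beads in a gaussian blob).
random_conformation <- function(n_beads, seed) {
  set.seed(seed)
  conformation(matrix(rnorm(n_beads * 3, sd = 5), ncol = 3))
}

# Uniform-ish random rotation matrix via QR of a gaussian matrix,
# det forced to +1.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force superposition oracle: best RMSD over `n_rot` random
# rotations applied to the centred mobile coordinates.
grid_rmsd_oracle <- function(reference, mobile, n_rot, seed = 1) {
  set.seed(seed)
  P <- sweep(reference$coordinates, 2, colMeans(reference$coordinates))
  Q <- sweep(mobile$coordinates, 2, colMeans(mobile$coordinates))
  best <- Inf
  for (i in seq_len(n_rot)) {
    R <- random_rotation()
    best <- min(best, sqrt(mean(rowSums((Q %*% R - P)^2))))
  }
  best
}
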