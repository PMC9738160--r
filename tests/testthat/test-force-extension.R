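masp1 <- masp_fragments()$MaSp1a
masp2 <- masp_fragments()$MaSp2.2a

test_that("build_curve sorts, validates and merges duplicate force levels", {
  frag <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  s <- noiseless_summary(8.1, 15)[c(1, 16), ]
  cv <- build_curve(s, frag)
  expect_s3_class(cv, "fe_curve")
  expect_equal(nrow(cv$points), 2)
  # shuffle invariance
  s16 <- noiseless_summary(8.1, 15)
  shuffled <- s16[sample(nrow(s16)), ]
  expect_equal(build_curve(shuffled, frag)$points,
               build_curve(s16, frag)$points)
  # duplicate merge keeps the common mean, pools the frames
  dup <- rbind(s16, s16[3, ])
  merged <- build_curve(dup, frag)
  expect_equal(nrow(merged$points), 16)
  expect_equal(merged$points$mean_L_A[3], s16$mean_L_A[3])
  expect_equal(merged$points$n_frames[3], 2000L)
  expect_error(build_curve(s16[1, ], frag), "2 distinct")
  bad <- s16; bad$mean_L_A[16] <- 130
  expect_error(build_curve(bad, frag), "exceeds")
})

test_that("normalisation divides by the contour length and inverts exactly", {
  s <- noiseless_summary_lmax(8.1, 118.1)
  s$mean_L_A[9] <- 118.1  # fully extended point at 250 pN
  cv <- build_curve(s, masp1)
  nc <- normalize_curve(cv)
  expect_equal(nc$fraction[nc$force_pN == 250], 1.0)
  expect_equal(nc$fraction * masp1$l_max, cv$points$mean_L_A)
  expect_true(all(nc$fraction >= 0 & nc$fraction <= 1.02))
})

test_that("link-length fit recovers any generating value on noiseless curves", {
  for (a_true in c(4.05, 8.1, 12.3)) {
    n <- 15L
    frag <- fragment_spec("ideal", n + 1L, l_max = n * a_true)
    cv <- build_curve(noiseless_summary(a_true, n), frag)
    ft <- fit_link_length(cv)
    expect_equal(ft$a_fit, a_true, tolerance = 0.01 / a_true)
    expect_false(ft$at_boundary)
  }
})

test_that("exact noiseless self-consistency at the fragment scales", {
  frag <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  cv <- build_curve(noiseless_summary(8.1, 15), frag)
  ft <- fit_link_length(cv)
  expect_equal(ft$a_fit, 8.1, tolerance = 0.001)
  expect_lt(ft$fit_residual, 1e-3)
  frag2 <- fragment_spec("ideal29", 30, l_max = 29 * 4.05)
  cv2 <- build_curve(noiseless_summary(4.05, 29), frag2)
  expect_equal(fit_link_length(cv2)$a_fit, 4.05, tolerance = 0.001)
})

test_that("fit recovers the link length from Monte-Carlo curves within 5%", {
  frag <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  m <- chain_model(15, 8.1, 298)
  cv <- build_curve(mc_summary(m, n_samples = 2000, seed = 55), frag)
  ft <- fit_link_length(cv)
  expect_lt(abs(ft$a_fit - 8.1) / 8.1, 0.05)
})

test_that("fitting is scale-consistent in force and temperature", {
  frag <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  s <- noiseless_summary(8.1, 15)
  a1 <- fit_link_length(build_curve(s, frag))$a_fit
  s2 <- s; s2$force_pN <- s$force_pN * 3
  a2 <- fit_link_length(build_curve(s2, frag), temperature = 3 * 298)$a_fit
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("fitted link length is a local optimum of the weighted objective", {
  frag <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  m <- chain_model(15, 8.1, 298)
  cv <- build_curve(mc_summary(m, n_samples = 500, seed = 77), frag)
  ft <- fit_link_length(cv)
  resid_at <- function(a) {
    pts <- cv$points
    w <- 1 / pts$sd_L_A^2
    sqrt(sum(w * (pts$mean_L_A -
                  frag$l_max * langevin(pts$force_pN * a / (kB * 298)))^2) /
         sum(w))
  }
  expect_lte(ft$fit_residual, resid_at(ft$a_fit + 0.5))
  expect_lte(ft$fit_residual, resid_at(ft$a_fit - 0.5))
})

test_that("joint fitting pools both fragments into one shared link length", {
  f1 <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  f2 <- fragment_spec("ideal21", 22, l_max = 21 * 8.1)
  cvs <- list(build_curve(noiseless_summary(8.1, 15), f1),
              build_curve(noiseless_summary(8.1, 21), f2))
  ft <- fit_link_length_joint(cvs)
  expect_equal(ft$a_fit, 8.1, tolerance = 0.001)
  expect_equal(ft$n_points, 32L)
})

test_that("fit demands at least three positive-force points", {
  frag <- fragment_spec("ideal15", 16, l_max = 15 * 8.1)
  s <- noiseless_summary(8.1, 15)[1:2, ]
  expect_error(fit_link_length(build_curve(s, frag)), "at least 3")
})

test_that("analyze_fragment reproduces the full published derivation chain", {
  eq1 <- equilibrium_summary(data.frame(
    mean_L_A = c(40.1, 33.4, 43.9), sd_L_A = c(14.6, 20.5, 15.1)))
  s <- noiseless_summary_lmax(8.1, 118.1)
  s$mean_L_A[9] <- 118.1
  rep1 <- analyze_fragment(build_curve(s, masp1), eq1, a_fixed = 8.1)
  expect_equal(rep1$n_links, 15L)
  expect_equal(round(rep1$l_eq_theory, 1), 31.4)
  expect_equal(round(rep1$l_hidden), 79)
  expect_equal(round(rep1$hidden_ratio, 1), 2.0)
  expect_equal(rep1$f_at_lmax, 250)
  eq2 <- equilibrium_summary(data.frame(
    mean_L_A = c(52.3, 60.1, 68.8), sd_L_A = c(27.6, 22.0, 24.8)))
  rep2 <- analyze_fragment(build_curve(noiseless_summary_lmax(8.1, 166.5), masp2),
                           eq2, a_fixed = 8.1)
  expect_equal(rep2$n_links, 21L)
  expect_equal(round(rep2$l_eq_theory), 37)
  expect_equal(round(rep2$l_hidden), 106)
  expect_equal(round(rep2$hidden_ratio, 1), 1.8)
  # no point reaches 0.995 L_max in the unmodified noiseless ladder
  expect_true(is.na(rep2$f_at_lmax))
  expect_s3_class(as.data.frame(rep2), "data.frame")
})
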