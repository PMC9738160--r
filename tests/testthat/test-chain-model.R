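masp1_model <- chain_model(15, 8.1, 298)

test_that("chain_model validates its invariants", {
  expect_error(chain_model(0, 8.1), "positive integer")
  expect_error(chain_model(2.5, 8.1), "positive integer")
  expect_error(chain_model(15, -1), "link_length")
  expect_error(chain_model(15, 8.1, 0), "temperature")
  expect_equal(contour_length(masp1_model), 121.5)
})

test_that("fjc_force reproduces the derived half-extension value and stiffens", {
  expect_identical(fjc_force(0, masp1_model), 0)
  # (kB*298/8.1) * inverse_langevin(0.5), frozen from the bisection oracle
  expect_equal(fjc_force(0.5 * contour_length(masp1_model), masp1_model),
               9.1265, tolerance = 0.02)
  l <- seq(0, 0.999, length.out = 1000) * contour_length(masp1_model)
  f <- fjc_force(l, masp1_model)
  expect_true(all(diff(f) > 0))                 # monotone
  expect_true(all(diff(diff(f)) > -1e-9))       # non-decreasing slope
  expect_error(fjc_force(contour_length(masp1_model), masp1_model),
               "contour length")
  expect_error(fjc_force(-1, masp1_model), ">= 0")
})

test_that("fjc_extension inverts fjc_force and saturates at the contour length", {
  expect_identical(fjc_extension(0, masp1_model), 0)
  na <- contour_length(masp1_model)
  for (frac in c(0.1, 0.5, 0.9)) {
    l <- frac * na
    expect_equal(fjc_extension(fjc_force(l, masp1_model), masp1_model), l,
                 tolerance = 1e-6)
  }
  expect_lt(abs(fjc_extension(1e4, masp1_model) - na) / na, 0.005)
  expect_error(fjc_extension(-5, masp1_model), ">= 0")
})

test_that("equilibrium end-to-end distance follows the random-walk identity", {
  expect_equal(round(equilibrium_end_to_end(masp1_model), 1), 31.4)
  expect_equal(round(equilibrium_end_to_end(chain_model(21, 8.1))), 37)
  expect_equal(equilibrium_end_to_end(chain_model(1, 5)), 5)
  # <L>^2 = N a^2 algebraically
  expect_equal(equilibrium_end_to_end(masp1_model)^2,
               masp1_model$n_links * masp1_model$link_length^2)
})

test_that("link_count rounds the contour-length quotient and keeps it", {
  expect_equal(as.integer(link_count(118.1, 8.1)), 15L)
  expect_equal(as.integer(link_count(166.5, 8.1)), 21L)
  expect_equal(as.integer(link_count(81.0, 8.1)), 10L)
  expect_equal(attr(link_count(118.1, 8.1), "quotient"), 118.1 / 8.1)
  expect_equal(as.integer(link_count(12.5, 5)), 3L)  # ties away from zero
  expect_error(link_count(-1, 8.1), "> 0")
  expect_error(link_count(118.1, 0), "> 0")
})

test_that("hidden length and its ratio reproduce the fragment values", {
  expect_equal(round(hidden_length(118.1, 39.1333333)), 79)
  expect_equal(round(hidden_length(166.5, 60.4)), 106)
  expect_identical(hidden_length(100, 100), 0)
  expect_error(hidden_length(100, 101), "cannot exceed")
  expect_equal(round(hidden_length_ratio(78.9666667, 39.1333333), 1), 2.0)
  expect_equal(round(hidden_length_ratio(106.1, 60.4), 1), 1.8)
  expect_identical(hidden_length_ratio(0, 3), 0)
  expect_error(hidden_length_ratio(10, 0), "> 0")
})

test_that("theoretical_curve evaluates the force law on a fractional grid", {
  expect_equal(theoretical_curve(masp1_model, 0)$force_pN, 0)
  expect_equal(theoretical_curve(masp1_model, 0.5)$force_pN, 9.1265,
               tolerance = 0.02)
  tc <- theoretical_curve(masp1_model, seq(0, 0.99, by = 0.01))
  expect_true(all(diff(tc$force_pN) > 0))
  expect_error(theoretical_curve(masp1_model, 1), "\\[0, 1\\)")
})
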