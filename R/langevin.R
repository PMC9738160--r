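#' Boltzmann constant in pN.Angstrom/K
#'
#' The package works in piconewtons, Angstroms and Kelvin throughout.
#' \code{kB} is the SI Boltzmann constant (1.380649e-23 J/K) converted with
#' 1 J = 1e22 pN.A, giving 0.1380649 pN.A/K. At 298 K, \code{kB * 298}
#' is about 41.14 pN.A, the thermal energy scale of all force laws here.
#'
#' @format A length-one numeric.
#' @export
kB <- 0.1380649

#' Langevin function
#'
#' \code{langevin(x)} evaluates \eqn{L(x) = \coth(x) - 1/x}, the mean
#' fractional extension of a freely jointed chain under reduced force
#' \eqn{x = F a / (k_B T)}. The function is odd, strictly increasing and
#' bounded in (-1, 1). For small |x| the direct form suffers catastrophic
#' cancellation, so the Taylor series \eqn{x/3 - x^3/45} is used below a
#' threshold of 1e-4.
#'
#' @param x numeric vector of reduced forces (any finite real).
#' @return numeric vector of the same length, values in (-1, 1).
#' @examples
#' langevin(0)       # 0
#' langevin(2)       # coth(2) - 1/2 = 0.5373...
#' @export
langevin <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Inverse Langevin function
#'
#' Solves \eqn{L(x) = y} for x given \eqn{|y| < 1}. Uses the Pade
#' approximant \eqn{x \approx y (3 - y^2) / (1 - y^2)} as the initial
#' guess, refined by safeguarded Newton iterations (falling back to
#' bisection steps when Newton leaves the bracket) until
#' \eqn{|L(x) - y| \le tol}.
#'
#' @param y numeric vector, each element strictly inside (-1, 1). At
#'   \eqn{|y| = 1} the chain is fully extended and the force diverges.
#' @param tol convergence tolerance on the residual \eqn{|L(x) - y|};
#'   default 1e-10.
#' @return numeric vector x with \code{langevin(x)} equal to \code{y}
#'   within \code{tol}; exactly 0 at y = 0.
#' @examples
#' inverse_langevin(0.5)             # approx 1.7968
#' langevin(inverse_langevin(0.9))   # 0.9
#' @export
inverse_langevin <- function(y, tol = 1e-10) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (any(abs(y) >= 1)) {
    stop("inverse_langevin: |y| must be < 1 (chain fully extended, force diverges)")
  }
  vapply(y, .inv_langevin_scalar, numeric(1), tol = tol)
}

.inv_langevin_scalar <- function(y, tol) {
  if (y == 0) return(0)
  s <- sign(y)
  y <- abs(y)
  # bracket: L(x) < x/3 so lo = 3y/2 would overshoot? L is concave on x>0,
  # L(x) <= x/3, hence the root is >= 3y; upper bound from L(x) > 1 - 1/x.
  lo <- 3 * y
  hi <- max(1 / (1 - y) + 1, lo + 1)
  x <- y * (3 - y^2) / (1 - y^2)  # Pade initial guess
  x <- min(max(x, lo), hi)
  for (i in 1:100) {
    fx <- langevin(x) - y
    if (abs(fx) <= tol) break
    if (fx > 0) hi <- x else lo <- x
    # derivative of L: 1/x^2 - 1/sinh(x)^2 (series 1/3 - x^2/15 for small x)
    d <- if (x < 1e-4) 1 / 3 - x^2 / 15 else 1 / x^2 - 1 / sinh(x)^2
    xn <- x - fx / d
    x <- if (is.finite(xn) && xn > lo && xn < hi) xn else (lo + hi) / 2
  }
  s * x
}
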