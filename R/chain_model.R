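#' Freely jointed chain model
#'
#' Container for the three FJC parameters: the number of rigid links N,
#' the link length a (Angstrom) and the temperature T (Kelvin). The
#' contour length of the chain is \code{n_links * link_length}.
#'
#' @param n_links positive integer, number of links N.
#' @param link_length positive length of one link a, in Angstrom.
#' @param temperature temperature in Kelvin (default 298).
#' @return an object of class \code{"chain_model"}.
#' @examples
#' chain_model(15, 8.1)
#' @export
chain_model <- function(n_links, link_length, temperature = 298) {
  stopifnot(length(n_links) == 1, length(link_length) == 1, length(temperature) == 1)
  if (!is.finite(n_links) || n_links < 1 || n_links != round(n_links))
    stop("n_links must be a positive integer")
  if (!is.finite(link_length) || link_length <= 0)
    stop("link_length must be > 0")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  structure(
    list(n_links = as.integer(n_links), link_length = link_length,
         temperature = temperature),
    class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("Freely jointed chain: N = %d links, a = %.4g A, T = %g K\n",
              x$n_links, x$link_length, x$temperature))
  cat(sprintf("  contour length N*a = %.4g A; kB*T = %.4f pN.A\n",
              contour_length(x), kB * x$temperature))
  invisible(x)
}

#' Contour (maximum) length of a chain
#'
#' \eqn{L_{max} = N a}: the end-to-end distance of the fully extended chain.
#'
#' @param model a \code{\link{chain_model}}.
#' @return length in Angstrom.
#' @export
contour_length <- function(model) {
  stopifnot(inherits(model, "chain_model"))
  model$n_links * model$link_length
}

#' FJC force at a given end-to-end distance
#'
#' The entropic restoring force of a freely jointed chain held at
#' end-to-end distance L:
#' \deqn{F = (k_B T / a) L^{-1}(L / (N a))}
#' where \eqn{L^{-1}} is the inverse Langevin function. The force is zero
#' at L = 0, strictly increasing, and diverges as L approaches the contour
#' length (the elastomeric stiffening regime).
#'
#' @param l_dist end-to-end distance in Angstrom; must satisfy
#'   \code{0 <= l_dist < contour_length(model)}.
#' @param model a \code{\link{chain_model}}.
#' @return force in pN (vectorised over \code{l_dist}).
#' @examples
#' m <- chain_model(15, 8.1, 298)
#' fjc_force(0.5 * contour_length(m), m)   # about 9.13 pN
#' @export
fjc_force <- function(l_dist, model) {
  stopifnot(inherits(model, "chain_model"), is.numeric(l_dist))
  lmax <- contour_length(model)
  if (any(l_dist < 0)) stop("l_dist must be >= 0")
  if (any(l_dist >= lmax))
    stop("l_dist must be below the contour length N*a (chain breaks at full extension)")
  (kB * model$temperature / model$link_length) * inverse_langevin(l_dist / lmax)
}

#' Mean FJC extension under constant force
#'
#' Closed-form mean end-to-end extension of an FJC pulled with constant
#' force F: \eqn{\langle L \rangle = N a \, L(F a / (k_B T))}. This is the
#' inverse of \code{\link{fjc_force}}.
#'
#' @param force force in pN, \code{force >= 0} (vectorised).
#' @param model a \code{\link{chain_model}}.
#' @return extension in Angstrom; 0 at F = 0, saturating at N*a.
#' @export
fjc_extension <- function(force, model) {
  stopifnot(inherits(model, "chain_model"), is.numeric(force))
  if (any(force < 0)) stop("force must be >= 0")
  contour_length(model) *
    langevin(force * model$link_length / (kB * model$temperature))
}

#' Equilibrium (zero-force) end-to-end distance of an FJC
#'
#' The root-mean-square end-to-end distance of an ideal chain of N links
#' of length a, \eqn{\langle L \rangle = \sqrt{N}\, a} (the random-walk
#' identity \eqn{\langle L^2 \rangle = N a^2}).
#'
#' @param model a \code{\link{chain_model}}.
#' @return length in Angstrom.
#' @examples
#' equilibrium_end_to_end(chain_model(15, 8.1))  # 31.4 A
#' @export
equilibrium_end_to_end <- function(model) {
  stopifnot(inherits(model, "chain_model"))
  sqrt(model$n_links) * model$link_length
}

#' Number of links from contour length and link length
#'
#' Inverts \eqn{L_{max} = N a}: returns the nearest integer to
#' \eqn{L_{max} / a} (ties rounded away from zero), with the unrounded
#' quotient attached for diagnostics.
#'
#' @param l_max contour length in Angstrom, > 0.
#' @param a link length in Angstrom, > 0.
#' @return integer link count with attribute \code{"quotient"} holding the
#'   unrounded value.
#' @examples
#' link_count(118.1, 8.1)  # 15
#' link_count(166.5, 8.1)  # 21
#' @export
link_count <- function(l_max, a) {
  stopifnot(length(l_max) == 1, length(a) == 1)
  if (!is.finite(l_max) || l_max <= 0 || !is.finite(a) || a <= 0)
    stop("l_max and a must be > 0")
  q <- l_max / a
  n <- as.integer(floor(abs(q) + 0.5) * sign(q))  # ties away from zero
  structure(n, quotient = q)
}

#' Hidden length of a chain
#'
#' \eqn{L_{hl} = L_{max} - \langle L \rangle}: the part of the contour
#' length not bearing load at equilibrium, recruited when the chain is
#' stretched.
#'
#' @param l_max contour length in Angstrom.
#' @param l_eq equilibrium end-to-end distance in Angstrom;
#'   \code{0 <= l_eq <= l_max}.
#' @return hidden length in Angstrom, >= 0.
#' @export
hidden_length <- function(l_max, l_eq) {
  stopifnot(is.numeric(l_max), is.numeric(l_eq))
  if (any(l_eq < 0)) stop("l_eq must be >= 0")
  if (any(l_eq > l_max))
    stop("equilibrium length cannot exceed the contour length")
  l_max - l_eq
}

#' Hidden-length ratio
#'
#' The hidden length divided by the equilibrium length,
#' \eqn{L_{hl} / \langle L \rangle}: the strain contribution available
#' from recruiting the hidden length.
#'
#' @param l_hl hidden length in Angstrom.
#' @param l_eq equilibrium length in Angstrom, > 0.
#' @return dimensionless ratio.
#' @export
hidden_length_ratio <- function(l_hl, l_eq) {
  if (any(l_eq <= 0)) stop("l_eq must be > 0")
  l_hl / l_eq
}

#' Theoretical FJC force-extension curve on a fractional grid
#'
#' Evaluates the FJC force law on a grid of fractional extensions
#' \eqn{L / L_{max} \in [0, 1)}; used for theory overlays and for
#' generating noiseless fixture curves.
#'
#' @param model a \code{\link{chain_model}}.
#' @param fractional_grid numeric vector of values in [0, 1).
#' @return data.frame with columns \code{fraction} (L/L_max) and
#'   \code{force_pN}.
#' @export
theoretical_curve <- function(model, fractional_grid) {
  stopifnot(inherits(model, "chain_model"), is.numeric(fractional_grid))
  if (any(fractional_grid < 0 | fractional_grid >= 1))
    stop("fractional grid values must lie in [0, 1)")
  data.frame(
    fraction = fractional_grid,
    force_pN = fjc_force(fractional_grid * contour_length(model), model))
}
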