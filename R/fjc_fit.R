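#' Fit a freely jointed chain to force-extension data
#'
#' The package's modelling interface. Takes per-force mean extensions of
#' a chain of known contour length and fits the FJC link length a by
#' weighted least squares in the extension domain (see
#' \code{\link{fit_link_length}}); the link count follows as
#' \code{round(l_max / a)}. Accepts either an assembled curve from
#' \code{\link{build_curve}} or raw vectors.
#'
#' @param x an \code{fe_curve}, or a data.frame with columns
#'   \code{force_pN}, \code{mean_L_A} and optionally \code{sd_L_A},
#'   \code{n_frames}.
#' @param fragment a \code{\link{fragment_spec}}; required when \code{x}
#'   is not already an \code{fe_curve}.
#' @param temperature temperature in K (default 298).
#' @param bounds search bracket for the link length, Angstrom.
#' @return an object of class \code{"fjc_fit"} with components
#'   \code{model} (the fitted \code{\link{chain_model}}), \code{curve},
#'   \code{a_fit}, \code{fit_residual}, \code{fitted} (model extensions at
#'   the data forces) and \code{derived} (contour length, equilibrium
#'   end-to-end distance, hidden length and ratio relative to the
#'   theoretical equilibrium length).
#' @examples
#' frag <- masp_fragments()$MaSp1a
#' m <- chain_model(15, 8.1)
#' dat <- data.frame(force_pN = default_force_ladder(),
#'                   mean_L_A = fjc_extension(default_force_ladder(), m),
#'                   sd_L_A = 1, n_frames = 1000)
#' fit <- fjc_fit(dat, frag)
#' coef(fit)
#' @export
fjc_fit <- function(x, fragment = NULL, temperature = 298, bounds = c(1, 20)) {
  if (inherits(x, "fe_curve")) {
    curve <- x
  } else {
    if (is.null(fragment)) stop("supply a fragment_spec with raw data")
    x <- as.data.frame(x)
    if (!"sd_L_A" %in% names(x)) x$sd_L_A <- 0
    if (!"n_frames" %in% names(x)) x$n_frames <- 1L
    curve <- build_curve(x, fragment)
  }
  ft <- fit_link_length(curve, temperature, bounds)
  n <- link_count(curve$fragment$l_max, ft$a_fit)
  model <- chain_model(n, ft$a_fit, temperature)
  pts <- curve$points
  fitted <- curve$fragment$l_max *
    langevin(pts$force_pN * ft$a_fit / (kB * temperature))
  l_eq <- equilibrium_end_to_end(model)
  l_hl <- hidden_length(curve$fragment$l_max, l_eq)
  structure(
    list(model = model, curve = curve, a_fit = ft$a_fit,
         fit_residual = ft$fit_residual, at_boundary = ft$at_boundary,
         fitted = fitted,
         derived = c(l_max = curve$fragment$l_max, l_eq_theory = l_eq,
                     l_hidden = l_hl,
                     hidden_ratio = hidden_length_ratio(l_hl, l_eq))),
    class = "fjc_fit")
}

#' @export
print.fjc_fit <- function(x, ...) {
  cat(sprintf("FJC fit for %s: a = %.2f A, N = %d links (T = %g K)\n",
              x$curve$fragment$name, x$a_fit, x$model$n_links,
              x$model$temperature))
  cat(sprintf("  weighted RMS extension residual %.3g A over %d force levels\n",
              x$fit_residual, nrow(x$curve$points)))
  invisible(x)
}

#' @export
coef.fjc_fit <- function(object, ...) {
  c(a = object$a_fit, n_links = object$model$n_links)
}

#' @export
summary.fjc_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fjc_fit")
}

#' @export
print.summary.fjc_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  d <- f$derived
  cat(sprintf("  contour length L_max        %.1f A\n", d["l_max"]))
  cat(sprintf("  equilibrium <L> = sqrt(N) a %.1f A\n", d["l_eq_theory"]))
  cat(sprintf("  hidden length L_max - <L>   %.1f A (ratio %.1f)\n",
              d["l_hidden"], d["hidden_ratio"]))
  if (f$at_boundary) cat("  warning: fit at the search boundary\n")
  invisible(x)
}

#' Predicted FJC extension (or force) from a fit
#'
#' @param object an \code{\link{fjc_fit}}.
#' @param force forces in pN at which to predict the mean extension;
#'   defaults to the data's force levels.
#' @param type \code{"extension"} (default) returns mean extension (A) at
#'   the given forces; \code{"force"} returns the restoring force at the
#'   extensions passed via \code{extension}.
#' @param extension extensions in A, used when \code{type = "force"}.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fjc_fit <- function(object, force = NULL,
                            type = c("extension", "force"),
                            extension = NULL, ...) {
  type <- match.arg(type)
  if (type == "extension") {
    if (is.null(force)) force <- object$curve$points$force_pN
    fjc_extension(force, object$model)
  } else {
    if (is.null(extension)) stop("supply extensions for type = 'force'")
    fjc_force(extension, object$model)
  }
}

#' @export
residuals.fjc_fit <- function(object, ...) {
  object$curve$points$mean_L_A - object$fitted
}

#' Draw equilibrium chains from a fitted FJC
#'
#' Samples end-to-end vectors from the fitted chain at a given constant
#' force using the exact tilted-link Monte-Carlo sampler.
#'
#' @param object an \code{\link{fjc_fit}}.
#' @param nsim number of chains to draw.
#' @param seed integer seed.
#' @param force pulling force in pN (default 0).
#' @param ... unused.
#' @return as \code{\link{sample_fjc_end_to_end}}.
#' @export
simulate.fjc_fit <- function(object, nsim = 1000, seed = 1L, force = 0, ...) {
  sample_fjc_end_to_end(object$model, force, nsim, seed)
}

#' Plot a force-extension fit
#'
#' Data points (fractional extension vs force, with SD bars) overlaid
#' with the fitted FJC theory curve.
#'
#' @param x an \code{\link{fjc_fit}}.
#' @param ... passed to \code{plot}.
#' @export
plot.fjc_fit <- function(x, ...) {
  pts <- normalize_curve(x$curve)
  grid <- seq(0, 0.995, length.out = 200)
  th <- theoretical_curve(x$model, grid)
  graphics::plot(pts$fraction, pts$force_pN, pch = 19,
                 xlab = expression(L / L[max]), ylab = "Force (pN)",
                 main = sprintf("%s: FJC fit, a = %.2f A",
                                x$curve$fragment$name, x$a_fit), ...)
  graphics::arrows(pts$fraction - pts$sd_fraction, pts$force_pN,
                   pts$fraction + pts$sd_fraction, pts$force_pN,
                   angle = 90, code = 3, length = 0.02)
  graphics::lines(th$fraction, th$force_pN, col = "firebrick", lwd = 2)
  invisible(x)
}
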