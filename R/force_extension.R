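#' Assemble a force-extension curve from per-force summaries
#'
#' Validates, sorts by force and merges duplicate force levels (pooled
#' mean and pooled variance weighted by frame counts).
#'
#' @param summaries data.frame with columns \code{force_pN},
#'   \code{mean_L_A}, \code{sd_L_A}, \code{n_frames} (the per-force
#'   summary schema; \code{n_frames_equilibrated} is accepted as an alias).
#' @param fragment the \code{\link{fragment_spec}} the curve belongs to.
#' @param tol_lmax fractional tolerance by which a mean extension may
#'   exceed the fragment's contour length before it is rejected (default
#'   0.02; thermal bond stretching can push the measured mean slightly
#'   past L_max).
#' @return an object of class \code{"fe_curve"}: list with \code{fragment}
#'   and \code{points} (data.frame sorted by strictly increasing force).
#' @export
build_curve <- function(summaries, fragment, tol_lmax = 0.02) {
  stopifnot(is.data.frame(summaries), inherits(fragment, "fragment_spec"))
  if ("n_frames_equilibrated" %in% names(summaries) &&
      !"n_frames" %in% names(summaries))
    names(summaries)[names(summaries) == "n_frames_equilibrated"] <- "n_frames"
  need <- c("force_pN", "mean_L_A", "sd_L_A", "n_frames")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(summaries$force_pN)) < 2)
    stop("need at least 2 distinct force levels")
  if (any(summaries$mean_L_A > fragment$l_max * (1 + tol_lmax)))
    stop("mean extension exceeds the fragment contour length beyond tolerance")
  # merge duplicate force levels by pooled mean / pooled variance
  sp <- split(summaries, summaries$force_pN)
  pts <- do.call(rbind, lapply(sp, function(g) {
    n <- sum(g$n_frames)
    m <- sum(g$mean_L_A * g$n_frames) / n
    ss <- sum((g$n_frames - 1) * g$sd_L_A^2 + g$n_frames * (g$mean_L_A - m)^2)
    data.frame(force_pN = g$force_pN[1], mean_L_A = m,
               sd_L_A = if (n > 1) sqrt(ss / (n - 1)) else g$sd_L_A[1],
               n_frames = n)
  }))
  pts <- pts[order(pts$force_pN), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(fragment = fragment, points = pts), class = "fe_curve")
}

#' @export
print.fe_curve <- function(x, ...) {
  cat(sprintf("Force-extension curve for %s (%d force levels, L_max %.1f A)\n",
              x$fragment$name, nrow(x$points), x$fragment$l_max))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Normalise a curve to fractional extension
#'
#' Divides each mean extension (and SD) by the fragment's contour length,
#' yielding F versus L/L_max.
#'
#' @param curve an \code{\link{build_curve}} result.
#' @return data.frame with columns \code{force_pN}, \code{fraction},
#'   \code{sd_fraction}, \code{n_frames}.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "fe_curve"))
  lm <- curve$fragment$l_max
  with(curve$points, data.frame(
    force_pN = force_pN, fraction = mean_L_A / lm,
    sd_fraction = sd_L_A / lm, n_frames = n_frames))
}

#' Fit the FJC link length to a force-extension curve
#'
#' Weighted least squares in the extension domain: finds the link length
#' a minimising
#' \deqn{\sum_i w_i \left(L_i - L_{max}\, \mathcal{L}(F_i a / (k_B T))\right)^2}
#' over a bracket, where \eqn{\mathcal{L}} is the Langevin function and
#' \eqn{L_{max}} is the fragment's contour length. Weights are
#' \eqn{1/sd_i^2} when every point has a positive SD, else 1. The
#' zero-force point is excluded (the model maps F = 0 to L = 0 while a
#' measured zero-force mean is a magnitude average). Minimisation is a
#' coarse grid (step 0.05 A) followed by golden-section refinement to
#' 1e-4 A.
#'
#' @param curve an \code{fe_curve} from \code{\link{build_curve}}.
#' @param temperature temperature in K (default 298).
#' @param bounds length-2 positive vector (a_lo, a_hi) in Angstrom.
#' @return list with \code{a_fit} (A), \code{fit_residual} (weighted RMS
#'   extension residual, A), \code{at_boundary} (logical flag) and
#'   \code{n_points}.
#' @export
fit_link_length <- function(curve, temperature = 298, bounds = c(1, 20)) {
  stopifnot(inherits(curve, "fe_curve"), length(bounds) == 2,
            all(bounds > 0), bounds[1] < bounds[2])
  pts <- curve$points[curve$points$force_pN > 0, , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points with force > 0")
  lmax <- curve$fragment$l_max
  kT <- kB * temperature
  w <- if (all(pts$sd_L_A > 0)) 1 / pts$sd_L_A^2 else rep(1, nrow(pts))
  obj <- function(a)
    sum(w * (pts$mean_L_A - lmax * langevin(pts$force_pN * a / kT))^2)
  grid <- seq(bounds[1], bounds[2], by = 0.05)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-4)
  a_fit <- opt$minimum
  at_boundary <- a_fit <= bounds[1] + 0.05 || a_fit >= bounds[2] - 0.05
  if (at_boundary) warning("fitted link length lies at the search boundary")
  list(a_fit = a_fit,
       fit_residual = sqrt(opt$objective / sum(w)),
       at_boundary = at_boundary, n_points = nrow(pts))
}

#' Joint link-length fit across several fragments
#'
#' Pools the weighted extension residuals of several curves and fits a
#' single shared link length, the natural mode when the fragments are
#' expected to share link chemistry.
#'
#' @param curves list of \code{fe_curve} objects.
#' @inheritParams fit_link_length
#' @return as \code{\link{fit_link_length}}.
#' @export
fit_link_length_joint <- function(curves, temperature = 298, bounds = c(1, 20)) {
  stopifnot(is.list(curves), length(curves) >= 1)
  kT <- kB * temperature
  parts <- lapply(curves, function(cv) {
    stopifnot(inherits(cv, "fe_curve"))
    pts <- cv$points[cv$points$force_pN > 0, , drop = FALSE]
    list(pts = pts, lmax = cv$fragment$l_max,
         w = if (all(pts$sd_L_A > 0)) 1 / pts$sd_L_A^2 else rep(1, nrow(pts)))
  })
  if (sum(vapply(parts, function(p) nrow(p$pts), integer(1))) < 3)
    stop("need at least 3 points with force > 0")
  obj <- function(a) sum(vapply(parts, function(p)
    sum(p$w * (p$pts$mean_L_A -
               p$lmax * langevin(p$pts$force_pN * a / kT))^2), numeric(1)))
  grid <- seq(bounds[1], bounds[2], by = 0.05)
  i <- which.min(vapply(grid, obj, numeric(1)))
  opt <- stats::optimize(obj, lower = grid[max(1, i - 1)],
                         upper = grid[min(length(grid), i + 1)], tol = 1e-4)
  wtot <- sum(vapply(parts, function(p) sum(p$w), numeric(1)))
  a_fit <- opt$minimum
  at_boundary <- a_fit <= bounds[1] + 0.05 || a_fit >= bounds[2] - 0.05
  if (at_boundary) warning("fitted link length lies at the search boundary")
  list(a_fit = a_fit, fit_residual = sqrt(opt$objective / wtot),
       at_boundary = at_boundary,
       n_points = sum(vapply(parts, function(p) nrow(p$pts), integer(1))))
}

#' Full elastomer analysis of one fragment
#'
#' Chains the whole derivation for a fragment: fits the link length to
#' its force-extension curve (or accepts a fixed one), derives the link
#' count from the contour length, the theoretical equilibrium end-to-end
#' distance, the hidden length relative to the measured equilibrium
#' length, the hidden-length ratio, and the smallest force at which the
#' curve reaches the contour length.
#'
#' @param curve an \code{fe_curve}.
#' @param equilibrium an \code{\link{equilibrium_summary}} of zero-force
#'   replicates for the same fragment.
#' @param temperature temperature in K.
#' @param a_fixed optional link length in A; when given, the fit is
#'   skipped and this value is used (e.g. to replay a published value).
#' @param lmax_threshold fraction of L_max counted as "fully extended"
#'   when locating \code{f_at_lmax} (default 0.995).
#' @return an object of class \code{"elastomer_report"}.
#' @export
analyze_fragment <- function(curve, equilibrium, temperature = 298,
                             a_fixed = NULL, lmax_threshold = 0.995) {
  stopifnot(inherits(curve, "fe_curve"),
            inherits(equilibrium, "equilibrium_summary"))
  lmax <- curve$fragment$l_max
  if (is.null(a_fixed)) {
    ft <- fit_link_length(curve, temperature)
    a <- ft$a_fit; resid <- ft$fit_residual
  } else {
    a <- a_fixed
    pts <- curve$points[curve$points$force_pN > 0, , drop = FALSE]
    kT <- kB * temperature
    resid <- sqrt(mean((pts$mean_L_A -
                        lmax * langevin(pts$force_pN * a / kT))^2))
  }
  n <- link_count(lmax, a)
  model <- chain_model(n, a, temperature)
  l_eq_th <- equilibrium_end_to_end(model)
  l_eq_meas <- equilibrium$grand_mean
  l_hl <- hidden_length(lmax, l_eq_meas)
  ratio <- hidden_length_ratio(l_hl, l_eq_meas)
  ext <- curve$points$mean_L_A >= lmax_threshold * lmax
  f_at_lmax <- if (any(ext)) min(curve$points$force_pN[ext]) else NA_real_
  structure(
    list(fragment = curve$fragment$name, a_fit = a,
         n_links = as.integer(n), n_links_quotient = attr(n, "quotient"),
         l_max = lmax, l_eq_measured = l_eq_meas, l_eq_theory = l_eq_th,
         l_hidden = l_hl, hidden_ratio = ratio, f_at_lmax = f_at_lmax,
         fit_residual = resid, temperature = temperature),
    class = "elastomer_report")
}

#' @export
print.elastomer_report <- function(x, ...) {
  cat(sprintf("Elastomer report - %s (T = %g K)\n", x$fragment, x$temperature))
  cat(sprintf("  link length a            %.2f A\n", x$a_fit))
  cat(sprintf("  links N = round(Lmax/a)  %d (quotient %.2f)\n",
              x$n_links, x$n_links_quotient))
  cat(sprintf("  contour length L_max     %.1f A\n", x$l_max))
  cat(sprintf("  <L> theory (sqrt(N) a)   %.1f A\n", x$l_eq_theory))
  cat(sprintf("  <L> measured             %.1f A\n", x$l_eq_measured))
  cat(sprintf("  hidden length L_hl       %.1f A (ratio L_hl/<L> = %.1f)\n",
              x$l_hidden, x$hidden_ratio))
  if (is.finite(x$f_at_lmax))
    cat(sprintf("  force reaching L_max     %g pN\n", x$f_at_lmax))
  cat(sprintf("  fit residual (RMS)       %.2f A\n", x$fit_residual))
  invisible(x)
}

#' @export
as.data.frame.elastomer_report <- function(x, ...) {
  data.frame(fragment = x$fragment, a_fit = x$a_fit, n_links = x$n_links,
             l_max = x$l_max, l_eq_measured = x$l_eq_measured,
             l_eq_theory = x$l_eq_theory, l_hidden = x$l_hidden,
             hidden_ratio = x$hidden_ratio, f_at_lmax = x$f_at_lmax,
             fit_residual = x$fit_residual)
}
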