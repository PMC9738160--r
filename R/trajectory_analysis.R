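#' Scalar per-frame series
#'
#' A per-frame scalar observable (end-to-end distance or RMSD, Angstrom)
#' with its frame indices and times.
#'
#' @param values numeric vector, finite and >= 0.
#' @param frame_times times in ps (same length).
#' @param frames frame indices (default 1-based sequence).
#' @return an object of class \code{"scalar_series"}.
#' @export
scalar_series <- function(values, frame_times = seq_along(values),
                          frames = seq_along(values)) {
  stopifnot(length(values) == length(frame_times),
            length(values) == length(frames),
            all(is.finite(values)), all(values >= 0))
  structure(list(frames = frames, values = values, frame_times = frame_times),
            class = "scalar_series")
}

#' End-to-end distance series of a trajectory
#'
#' Per-frame Euclidean distance between the first and last bead.
#'
#' @param traj a \code{\link{trajectory}}.
#' @return a \code{\link{scalar_series}} of distances in Angstrom.
#' @export
end_to_end_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(traj$frames)) stop("empty trajectory")
  scalar_series(vapply(traj$frames, end_to_end, numeric(1)),
                frame_times = traj$frame_times)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the coordinate
#' RMSD of \code{mobile} onto \code{reference}, via singular value
#' decomposition of the centred cross-covariance matrix with the usual
#' sign correction enforcing det(R) = +1 (no reflection).
#'
#' @param reference,mobile \code{\link{conformation}} objects with equal
#'   bead counts (>= 3).
#' @return list with \code{rotation} (3 x 3 proper rotation applied to the
#'   centred mobile coordinates), \code{translation} (so that
#'   \code{mobile \%*\% R + t} superposes onto reference), \code{rmsd}
#'   (minimised RMSD, Angstrom) and \code{fitted} (transformed mobile
#'   coordinates).
#' @export
kabsch_superpose <- function(reference, mobile) {
  stopifnot(inherits(reference, "conformation"), inherits(mobile, "conformation"))
  P <- reference$coordinates
  Q <- mobile$coordinates
  if (nrow(P) != nrow(Q)) stop("bead counts differ")
  if (nrow(P) < 3) stop("need at least 3 beads for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Qc, Pc))       # H = Qc' Pc; R = V diag(1,1,d) U' ...
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # Qc %*% R aligns onto Pc
  fitted <- Qc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Pc)^2)))
  trans <- cp - as.numeric(cq %*% R)
  list(rotation = R, translation = trans, rmsd = rmsd,
       fitted = sweep(fitted, 2, cp, "+"))
}

#' RMSD series against a fixed reference
#'
#' Per-frame minimised superposition RMSD of each trajectory frame against
#' a fixed reference conformation (typically the extended start). Its
#' stabilisation over time is the equilibration signal.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param reference a \code{\link{conformation}} with matching bead count.
#' @return a \code{\link{scalar_series}} of RMSD values in Angstrom.
#' @export
rmsd_series <- function(traj, reference) {
  stopifnot(inherits(traj, "trajectory"), inherits(reference, "conformation"))
  scalar_series(
    vapply(traj$frames, function(f) kabsch_superpose(reference, f)$rmsd,
           numeric(1)),
    frame_times = traj$frame_times)
}

#' Detect equilibration by series stabilisation
#'
#' Scans for the first frame index i such that the standard deviation of
#' the series over the window [i, i + window) drops to at most
#' \code{rel_tol} times the standard deviation of the full series; from
#' there on the series is considered stationary. If no window qualifies
#' the last admissible start is returned with attribute
#' \code{"converged" = FALSE} and a warning.
#'
#' @param series a \code{\link{scalar_series}}.
#' @param window window length in frames; defaults to 10 percent of the
#'   series (100 frames for a 1000-frame trajectory).
#' @param rel_tol fraction of the full-series SD that counts as stable
#'   (default 0.25).
#' @return 1-based frame index with logical attribute \code{"converged"}.
#' @export
detect_equilibration <- function(series, window = NULL, rel_tol = 0.25) {
  stopifnot(inherits(series, "scalar_series"))
  v <- series$values
  if (is.null(window)) window <- max(2L, as.integer(round(0.1 * length(v))))
  if (window < 2) stop("window must be >= 2")
  if (length(v) < window) stop("series shorter than the window")
  full_sd <- stats::sd(v)
  if (full_sd == 0) return(structure(1L, converged = TRUE))
  # rolling SD via cumulative sums
  n <- length(v)
  cs <- cumsum(c(0, v)); cs2 <- cumsum(c(0, v^2))
  starts <- seq_len(n - window + 1L)
  sums <- cs[starts + window] - cs[starts]
  sums2 <- cs2[starts + window] - cs2[starts]
  wsd <- sqrt(pmax(0, (sums2 - sums^2 / window) / (window - 1)))
  ok <- which(wsd <= rel_tol * full_sd)
  if (length(ok)) {
    structure(as.integer(ok[1]), converged = TRUE)
  } else {
    warning("no window reached the stability tolerance; using the last admissible start")
    structure(as.integer(n - window + 1L), converged = FALSE)
  }
}

#' Mean and SD of a series over its equilibrated tail
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the series values from \code{eq_start} on.
#'
#' @param l_series a \code{\link{scalar_series}}.
#' @param eq_start 1-based first equilibrated frame.
#' @return named numeric vector \code{c(mean =, sd =)} in Angstrom.
#' @export
summarize_trajectory <- function(l_series, eq_start = 1L) {
  stopifnot(inherits(l_series, "scalar_series"))
  n <- length(l_series$values)
  if (eq_start > n) stop("eq_start beyond the series")
  tail_v <- l_series$values[eq_start:n]
  if (length(tail_v) < 2) stop("fewer than 2 equilibrated frames")
  c(mean = mean(tail_v), sd = stats::sd(tail_v))
}

#' Combine per-trajectory means into a grand summary
#'
#' Arithmetic mean of the per-trajectory mean end-to-end distances and
#' its spread across trajectories. The displayed spread is the standard
#' error of the mean (sample SD / sqrt(n)); the sample SD itself is also
#' returned.
#'
#' @param per_traj_means numeric vector of >= 2 per-trajectory means (A).
#' @return named numeric vector \code{c(grand_mean =, spread =, sd =,
#'   n =)}.
#' @examples
#' combine_trajectories(c(40.1, 33.4, 43.9))  # 39.13 +/- 3.09
#' @export
combine_trajectories <- function(per_traj_means) {
  if (length(per_traj_means) < 2)
    stop("need at least 2 trajectories for a spread")
  m <- mean(per_traj_means)
  s <- stats::sd(per_traj_means)
  c(grand_mean = m, spread = s / sqrt(length(per_traj_means)), sd = s,
    n = length(per_traj_means))
}

#' Equilibrium summary across replicate trajectories
#'
#' Bundles per-trajectory equilibrated statistics with the cross-trajectory
#' grand mean and spread, the layout of the zero-force replicate table.
#'
#' @param per_trajectory data.frame with columns \code{mean_L_A},
#'   \code{sd_L_A} and optionally \code{eq_start}.
#' @return an object of class \code{"equilibrium_summary"} with fields
#'   \code{per_trajectory}, \code{grand_mean}, \code{grand_spread} (SEM),
#'   \code{grand_sd}, \code{n_trajectories}.
#' @export
equilibrium_summary <- function(per_trajectory) {
  stopifnot(is.data.frame(per_trajectory), "mean_L_A" %in% names(per_trajectory),
            nrow(per_trajectory) >= 1)
  n <- nrow(per_trajectory)
  if (n >= 2) {
    g <- combine_trajectories(per_trajectory$mean_L_A)
    out <- list(per_trajectory = per_trajectory,
                grand_mean = unname(g["grand_mean"]),
                grand_spread = unname(g["spread"]),
                grand_sd = unname(g["sd"]), n_trajectories = n)
  } else {
    out <- list(per_trajectory = per_trajectory,
                grand_mean = per_trajectory$mean_L_A[1],
                grand_spread = NA_real_, grand_sd = NA_real_,
                n_trajectories = 1L)
  }
  structure(out, class = "equilibrium_summary")
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat(sprintf("Equilibrium over %d trajectories:\n", x$n_trajectories))
  print(x$per_trajectory, row.names = FALSE)
  if (is.na(x$grand_spread)) {
    cat(sprintf("  grand mean %.1f A (spread unavailable, single trajectory)\n",
                x$grand_mean))
  } else {
    cat(sprintf("  grand mean %.0f +/- %.0f A (SEM; sample SD %.1f A)\n",
                x$grand_mean, x$grand_spread, x$grand_sd))
  }
  invisible(x)
}
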