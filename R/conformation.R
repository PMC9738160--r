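#' Chain conformation (C-alpha trace)
#'
#' An ordered set of bead coordinates, one per residue, in Angstrom.
#'
#' @param coordinates numeric matrix with one row per bead and columns
#'   x, y, z; at least 2 rows, all finite.
#' @param labels optional character vector of residue labels.
#' @return an object of class \code{"conformation"}.
#' @export
conformation <- function(coordinates, labels = NULL) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 2 || ncol(coordinates) != 3 ||
      !all(is.finite(coordinates)))
    stop("coordinates must be a finite n x 3 matrix with n >= 2")
  colnames(coordinates) <- c("x", "y", "z")
  if (!is.null(labels)) stopifnot(length(labels) == nrow(coordinates))
  structure(list(coordinates = coordinates, labels = labels),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d beads, end-to-end %.2f A\n",
              nrow(x$coordinates), end_to_end(x)))
  invisible(x)
}

#' End-to-end distance of a conformation
#'
#' Euclidean distance between the first and last bead.
#'
#' @param conf a \code{\link{conformation}}.
#' @return distance in Angstrom.
#' @export
end_to_end <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  xyz <- conf$coordinates
  sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
}

#' Build a fully extended reference conformation
#'
#' Places beads collinearly along the +z (pulling) axis at a fixed rise,
#' the straight-trace idealisation of the extended beta-pleated starting
#' structure. The end-to-end distance is
#' \code{(n_residues - 1) * rise_per_residue}.
#'
#' @param n_residues number of beads (>= 2).
#' @param rise_per_residue spacing in Angstrom (> 0).
#' @return a \code{\link{conformation}}.
#' @examples
#' end_to_end(build_extended_conformation(36, 118.1 / 35))  # 118.1
#' @export
build_extended_conformation <- function(n_residues, rise_per_residue) {
  if (n_residues < 2 || n_residues != round(n_residues))
    stop("n_residues must be an integer >= 2")
  if (rise_per_residue <= 0) stop("rise_per_residue must be > 0")
  z <- (seq_len(n_residues) - 1) * rise_per_residue
  conformation(cbind(0, 0, z))
}

#' Trajectory of conformations
#'
#' Ordered frames of bead coordinates with frame times, the applied
#' pulling force, the seed that generated them and the simulator
#' parameters.
#'
#' @param frames list of \code{\link{conformation}} objects with identical
#'   bead counts.
#' @param frame_times strictly increasing times in ps.
#' @param force_applied constant pulling force in pN.
#' @param seed integer seed of the generating run.
#' @param params simulator parameter list (may be NULL for trajectories
#'   read from file).
#' @return an object of class \code{"trajectory"}.
#' @export
trajectory <- function(frames, frame_times, force_applied = 0, seed = NA,
                       params = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1,
            length(frame_times) == length(frames))
  nb <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (length(unique(nb)) != 1) stop("all frames must have the same bead count")
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  structure(list(frames = frames, frame_times = frame_times,
                 force_applied = force_applied, seed = seed, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d beads, F = %g pN, t = [%g, %g] ps\n",
    length(x$frames), nrow(x$frames[[1]]$coordinates), x$force_applied,
    x$frame_times[1], x$frame_times[length(x$frame_times)]))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)
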