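#' Write a conformation or trajectory as a C-alpha PDB file
#'
#' Writes fixed-column ATOM records (one CA atom per bead, chain A,
#' 1-based residue numbers, occupancy 1.00, B-factor 0.00). Trajectories
#' become multi-model PDB files with MODEL/ENDMDL bracketing each frame.
#'
#' @param x a \code{\link{conformation}} or \code{\link{trajectory}}.
#' @param path output file path.
#' @param labels 3-letter residue names recycled over beads (default GLY).
#' @return \code{path}, invisibly.
#' @export
write_pdb_trace <- function(x, path, labels = "GLY") {
  frames <- if (inherits(x, "trajectory")) x$frames
            else if (inherits(x, "conformation")) list(x)
            else stop("x must be a conformation or trajectory")
  nb <- nrow(frames[[1]]$coordinates)
  res <- rep_len(labels, nb)
  multi <- length(frames) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", fi), con)
    xyz <- frames[[fi]]$coordinates
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nb), res, seq_len(nb), xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a C-alpha trace PDB file
#'
#' Parses fixed-column ATOM records; MODEL/ENDMDL blocks become
#' trajectory frames. Tolerates trailing whitespace and missing element
#' columns.
#'
#' @param path PDB file path.
#' @param frame_times optional times (ps) for multi-model files; defaults
#'   to 1, 2, ... frames.
#' @return a \code{\link{conformation}} (single model) or
#'   \code{\link{trajectory}} (multi-model).
#' @export
read_pdb_trace <- function(path, frame_times = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM records in ", path)
  model_id <- cumsum(is_model)
  ids <- model_id[is_atom]
  if (!any(is_model)) ids <- rep(1L, sum(is_atom))
  atom_lines <- lines[is_atom]
  parse_block <- function(ls) {
    xyz <- cbind(as.numeric(substr(ls, 31, 38)),
                 as.numeric(substr(ls, 39, 46)),
                 as.numeric(substr(ls, 47, 54)))
    if (any(!is.finite(xyz)))
      stop("malformed coordinate field in ", path)
    conformation(xyz, labels = trimws(substr(ls, 18, 20)))
  }
  frames <- lapply(split(atom_lines, ids), parse_block)
  if (length(frames) == 1) return(frames[[1]])
  if (is.null(frame_times)) frame_times <- seq_along(frames)
  trajectory(unname(frames), frame_times)
}

#' Write a trajectory's scalar series as CSV
#'
#' Schema: \code{frame, time_ps, L_A, rmsd_A}, 0-based frame indices.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output CSV path.
#' @param reference reference conformation for the RMSD column; defaults
#'   to the extended start implied by the first frame's bead count and
#'   the trajectory's link geometry being unavailable, the first frame.
#' @return \code{path}, invisibly.
#' @export
write_series_csv <- function(traj, path, reference = traj$frames[[1]]) {
  l <- end_to_end_series(traj)
  r <- rmsd_series(traj, reference)
  utils::write.csv(
    data.frame(frame = seq_along(l$values) - 1L, time_ps = l$frame_times,
               L_A = l$values, rmsd_A = r$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scalar-series CSV
#'
#' @param path CSV with columns \code{frame, time_ps, L_A} and optionally
#'   \code{rmsd_A}.
#' @return list of \code{\link{scalar_series}}: \code{L} and, when
#'   present, \code{rmsd}.
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "time_ps", "L_A")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("malformed series CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  out <- list(L = scalar_series(d$L_A, d$time_ps, d$frame + 1L))
  if ("rmsd_A" %in% names(d))
    out$rmsd <- scalar_series(d$rmsd_A, d$time_ps, d$frame + 1L)
  out
}

#' Write / read the per-force summary CSV
#'
#' Schema: \code{force_pN, mean_L_A, sd_L_A, n_frames_equilibrated, seed}.
#'
#' @param summary data.frame in the per-force summary schema.
#' @param path CSV path.
#' @return \code{path} (writer) or the data.frame (reader).
#' @export
write_summary_csv <- function(summary, path) {
  need <- c("force_pN", "mean_L_A", "sd_L_A", "n_frames_equilibrated", "seed")
  miss <- setdiff(need, names(summary))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(summary[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("force_pN", "mean_L_A", "sd_L_A")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("malformed summary CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  d
}

#' Write a zero-force replicate table (trajectory means plus summary row)
#'
#' @param eq an \code{\link{equilibrium_summary}}.
#' @param path CSV path.
#' @export
write_table1_csv <- function(eq, path) {
  stopifnot(inherits(eq, "equilibrium_summary"))
  per <- eq$per_trajectory
  rows <- data.frame(trajectory = as.character(seq_len(nrow(per))),
                     mean_L_A = per$mean_L_A, sd_L_A = per$sd_L_A)
  rows <- rbind(rows, data.frame(trajectory = "mean",
                                 mean_L_A = eq$grand_mean,
                                 sd_L_A = eq$grand_spread))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
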