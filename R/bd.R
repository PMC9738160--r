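#' Brownian-dynamics simulator parameters
#'
#' Integration settings for the overdamped bead-spring pulling simulator.
#' The chain is discretised at one bead per FJC link end (N links, N + 1
#' beads) with stiff harmonic bonds of rest length a, so its stationary
#' statistics converge to the ideal freely jointed chain as the bond
#' stiffness grows.
#'
#' @param timestep integration step in ps.
#' @param n_steps total number of steps; the default 2e7 (400 ps at the
#'   default timestep) covers several end-to-end relaxation times of the
#'   15-link chain.
#' @param save_stride save one frame every \code{save_stride} steps
#'   (default chosen so about 1000 frames are kept).
#' @param friction drag coefficient gamma in pN.ps/A (overdamped mobility
#'   is dt/gamma).
#' @param bond_stiffness harmonic bond stiffness in units of kB*T per A^2;
#'   default 200 keeps bond-length fluctuations ~0.07 A, far below the
#'   8.1 A link length.
#' @param seed integer RNG seed; runs are pure functions of it.
#' @return an object of class \code{"bd_params"}.
#' @export
bd_params <- function(timestep = 2e-5, n_steps = 2e7,
                      save_stride = max(1L, floor(n_steps / 1000)),
                      friction = 1, bond_stiffness = 200, seed = 1L) {
  p <- list(timestep = timestep, n_steps = round(n_steps),
            save_stride = as.integer(save_stride), friction = friction,
            bond_stiffness = bond_stiffness, seed = as.integer(seed))
  stopifnot(p$timestep > 0, p$n_steps >= p$save_stride, p$save_stride >= 1,
            p$friction > 0, p$bond_stiffness > 0)
  class(p) <- "bd_params"
  p
}

# Stability guard: per-step RMS thermal displacement must stay below a
# tenth of the link length, and the deterministic bond-relaxation factor
# k*dt/gamma must stay below 1/2 (explicit Euler stability margin).
.check_bd_stability <- function(bd, model) {
  kT <- kB * model$temperature
  rms <- sqrt(2 * kT * bd$timestep / bd$friction)
  if (rms >= 0.1 * model$link_length)
    stop(sprintf(
      "unstable BD settings: per-step RMS displacement %.3g A >= 0.1 * a = %.3g A",
      rms, 0.1 * model$link_length))
  kreal <- bd$bond_stiffness * kT
  if (kreal * bd$timestep / bd$friction >= 0.5)
    stop(sprintf(
      "unstable BD settings: bond relaxation factor k*dt/gamma = %.3g >= 0.5",
      kreal * bd$timestep / bd$friction))
  invisible(TRUE)
}

#' Simulate a constant-force pulling trajectory
#'
#' Overdamped Brownian dynamics of a bead-spring chain representing the
#' fragment at FJC resolution: \code{model$n_links + 1} beads joined by
#' stiff harmonic bonds of rest length \code{model$link_length}. A
#' constant force \code{-F}/\code{+F} (pN) is applied along z to the two
#' end beads, mimicking outward pulling on the terminal C-alpha atoms.
#' The run starts from the fully extended conformation
#' (\code{\link{build_extended_conformation}}) and relaxes under thermal
#' noise of per-coordinate variance \code{2*kB*T*dt/friction}.
#'
#' @param fragment a \code{\link{fragment_spec}} (names the run; the
#'   chain geometry comes from \code{model}).
#' @param model a \code{\link{chain_model}}.
#' @param force constant pulling force in pN, >= 0.
#' @param bd a \code{\link{bd_params}}; its stability guard is checked
#'   before running.
#' @return a \code{\link{trajectory}} of the saved frames.
#' @export
simulate_trajectory <- function(fragment, model, force, bd = bd_params()) {
  stopifnot(inherits(fragment, "fragment_spec"),
            inherits(model, "chain_model"), inherits(bd, "bd_params"))
  if (force < 0) stop("force must be >= 0")
  .check_bd_stability(bd, model)
  kT <- kB * model$temperature
  start <- build_extended_conformation(model$n_links + 1L, model$link_length)
  set.seed(bd$seed)
  arr <- bd_run_cpp(start$coordinates, model$link_length,
                    bd$bond_stiffness * kT, force, bd$timestep, bd$friction,
                    kT, bd$n_steps, bd$save_stride)
  n_saved <- dim(arr)[3]
  frames <- lapply(seq_len(n_saved), function(f)
    conformation(t(arr[, , f])))
  times <- seq_len(n_saved) * bd$save_stride * bd$timestep
  trajectory(frames, times, force_applied = force, seed = bd$seed,
             params = c(bd, fragment = fragment$name))
}

#' Run the full constant-force ladder for one fragment
#'
#' Simulates one pulling trajectory per force in the fragment's ladder and
#' summarises the equilibrated end-to-end distance of each (mean, SD, and
#' number of equilibrated frames via \code{\link{detect_equilibration}}).
#' Per-trajectory seeds are derived as \code{seed + force index}, so the
#' whole ladder is reproducible from the root seed.
#'
#' @param fragment a \code{\link{fragment_spec}}.
#' @param model a \code{\link{chain_model}}.
#' @param bd a \code{\link{bd_params}} template (its seed is replaced per
#'   force level).
#' @param seed root integer seed.
#' @param keep_trajectories keep the full trajectories in the result
#'   (default FALSE: only summaries, which is what the force-extension
#'   analysis consumes).
#' @return list with \code{summary} (data.frame with columns
#'   \code{force_pN, mean_L_A, sd_L_A, n_frames_equilibrated, seed}) and,
#'   if requested, \code{trajectories}.
#' @export
run_force_ladder <- function(fragment, model, bd = bd_params(), seed = 1L,
                             keep_trajectories = FALSE) {
  stopifnot(inherits(fragment, "fragment_spec"))
  forces <- fragment$force_ladder
  if (!length(forces)) stop("fragment has an empty force ladder")
  trajs <- vector("list", length(forces))
  rows <- vector("list", length(forces))
  for (i in seq_along(forces)) {
    bd_i <- bd
    bd_i$seed <- as.integer(seed + i)
    tr <- simulate_trajectory(fragment, model, forces[i], bd_i)
    ls <- end_to_end_series(tr)
    # a run that is stationary from the start (typical at high force, where
    # the extended start is already the equilibrium state) has no window
    # with SD below the tolerance; summarise its tail without the warning
    # and record the flag instead
    eq <- suppressWarnings(detect_equilibration(ls))
    st <- summarize_trajectory(ls, eq)
    rows[[i]] <- data.frame(
      force_pN = forces[i], mean_L_A = st[["mean"]], sd_L_A = st[["sd"]],
      n_frames_equilibrated = length(ls$values) - eq + 1L,
      equilibration_converged = isTRUE(attr(eq, "converged")),
      seed = bd_i$seed)
    if (keep_trajectories) trajs[[i]] <- tr
  }
  out <- list(summary = do.call(rbind, rows))
  if (keep_trajectories) out$trajectories <- trajs
  out
}
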