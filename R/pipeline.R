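#' Run configuration for the simulation/analysis pipeline
#'
#' Builds and validates the configuration driving
#' \code{\link{elc_simulate}}. Unknown fields are rejected.
#'
#' @param fragments list of \code{\link{fragment_spec}} objects.
#' @param temperature K (default 298).
#' @param link_length FJC link length a (A) used to discretise each chain
#'   (default 8.1).
#' @param bd a \code{\link{bd_params}} template.
#' @param seed root seed.
#' @param n_zero_force_replicates zero-force replicate runs per fragment
#'   (default 3).
#' @param write_pdb also write multi-model PDB trajectories (default
#'   FALSE; the analysis consumes the CSV series).
#' @return an object of class \code{"run_config"}.
#' @export
run_config <- function(fragments = masp_fragments(), temperature = 298,
                       link_length = 8.1, bd = bd_params(), seed = 1L,
                       n_zero_force_replicates = 3L, write_pdb = FALSE) {
  stopifnot(is.list(fragments), length(fragments) >= 1,
            all(vapply(fragments, inherits, logical(1), "fragment_spec")),
            inherits(bd, "bd_params"), temperature > 0, link_length > 0,
            n_zero_force_replicates >= 0)
  structure(list(fragments = fragments, temperature = temperature,
                 link_length = link_length, bd = bd, seed = as.integer(seed),
                 n_zero_force_replicates = as.integer(n_zero_force_replicates),
                 write_pdb = isTRUE(write_pdb)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys \code{temperature, link_length, seed,
#' n_zero_force_replicates, write_pdb, bd: \{timestep, n_steps,
#' save_stride, friction, bond_stiffness\}} and a \code{fragments} list of
#' \code{\{name, n_residues, l_max, force_ladder\}} entries. Unknown keys
#' are rejected with an error naming them.
#'
#' @param path YAML file path.
#' @return a validated \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  y <- yaml::read_yaml(path)
  known <- c("temperature", "link_length", "seed", "n_zero_force_replicates",
             "write_pdb", "bd", "fragments")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  frs <- if (is.null(y$fragments)) masp_fragments() else lapply(y$fragments,
    function(f) {
      fk <- setdiff(names(f), c("name", "n_residues", "l_max", "force_ladder"))
      if (length(fk)) stop("unknown fragment key(s): ", paste(fk, collapse = ", "))
      fragment_spec(f$name, f$n_residues, l_max = f$l_max,
                    force_ladder = if (is.null(f$force_ladder))
                      default_force_ladder() else as.numeric(f$force_ladder))
    })
  bd <- if (is.null(y$bd)) bd_params() else {
    bk <- setdiff(names(y$bd),
                  c("timestep", "n_steps", "save_stride", "friction",
                    "bond_stiffness"))
    if (length(bk)) stop("unknown bd key(s): ", paste(bk, collapse = ", "))
    do.call(bd_params, y$bd)
  }
  args <- y[intersect(names(y), c("temperature", "link_length", "seed",
                                  "n_zero_force_replicates", "write_pdb"))]
  do.call(run_config, c(list(fragments = frs, bd = bd), args))
}

#' Simulate the configured experiments and write their outputs
#'
#' For every fragment: the configured number of zero-force relaxation
#' replicates plus one pulling trajectory per ladder force. Writes one
#' scalar-series CSV per trajectory, a per-force summary CSV per
#' fragment, and (optionally) multi-model PDB trajectories. Child seeds
#' are \code{seed + 1000*fragment_index + replicate/force index}, logged
#' in the summary files.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return named list per fragment with the summary data.frame and the
#'   zero-force \code{\link{equilibrium_summary}}, invisibly.
#' @export
elc_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (fi in seq_along(config$fragments)) {
    frag <- config$fragments[[fi]]
    n <- link_count(frag$l_max, config$link_length)
    model <- chain_model(n, config$link_length, config$temperature)
    base_seed <- config$seed + 1000L * fi
    # zero-force replicates
    zf <- NULL
    if (config$n_zero_force_replicates > 0) {
      rows <- lapply(seq_len(config$n_zero_force_replicates), function(r) {
        bd_r <- config$bd; bd_r$seed <- base_seed + r
        tr <- simulate_trajectory(frag, model, 0, bd_r)
        ls <- end_to_end_series(tr)
        eq <- detect_equilibration(ls)
        st <- summarize_trajectory(ls, eq)
        write_series_csv(tr, file.path(out_dir,
          sprintf("%s_F0_rep%d_series.csv", frag$name, r)),
          reference = build_extended_conformation(model$n_links + 1L,
                                                  model$link_length))
        if (config$write_pdb)
          write_pdb_trace(tr, file.path(out_dir,
            sprintf("%s_F0_rep%d.pdb", frag$name, r)))
        data.frame(mean_L_A = st[["mean"]], sd_L_A = st[["sd"]],
                   eq_start = as.integer(eq))
      })
      zf <- equilibrium_summary(do.call(rbind, rows))
      write_table1_csv(zf, file.path(out_dir,
        sprintf("%s_zero_force_table.csv", frag$name)))
    }
    lad <- run_force_ladder(frag, model, config$bd,
                            seed = base_seed + 100L,
                            keep_trajectories = config$write_pdb)
    if (config$write_pdb)
      for (i in seq_along(lad$trajectories))
        write_pdb_trace(lad$trajectories[[i]], file.path(out_dir,
          sprintf("%s_F%g.pdb", frag$name, frag$force_ladder[i])))
    write_summary_csv(lad$summary, file.path(out_dir,
      sprintf("%s_force_summary.csv", frag$name)))
    out[[frag$name]] <- list(summary = lad$summary, zero_force = zf)
  }
  invisible(out)
}

#' Analyse trajectory series files into an equilibrium summary
#'
#' Reads scalar-series CSVs (or accepts \code{\link{scalar_series}}
#' objects), detects equilibration on each, summarises the equilibrated
#' end-to-end distance and combines the replicates.
#'
#' @param series_paths character vector of series CSV paths, or a list of
#'   \code{scalar_series}.
#' @param window,rel_tol passed to \code{\link{detect_equilibration}}.
#' @return an \code{\link{equilibrium_summary}}.
#' @export
elc_analyze <- function(series_paths, window = NULL, rel_tol = 0.25) {
  series <- if (is.character(series_paths))
    lapply(series_paths, function(p) read_series_csv(p)$L)
  else series_paths
  stopifnot(all(vapply(series, inherits, logical(1), "scalar_series")))
  rows <- lapply(series, function(s) {
    eq <- detect_equilibration(s, window = window, rel_tol = rel_tol)
    st <- summarize_trajectory(s, eq)
    data.frame(mean_L_A = st[["mean"]], sd_L_A = st[["sd"]],
               eq_start = as.integer(eq))
  })
  equilibrium_summary(do.call(rbind, rows))
}

#' Fit a force-extension summary file
#'
#' Reads a per-force summary CSV, assembles the curve for the named
#' fragment and fits the FJC link length.
#'
#' @param summary_path per-force summary CSV (schema of
#'   \code{\link{write_summary_csv}}, or \code{force_pN, mean_L_A,
#'   sd_L_A, n_frames}).
#' @param fragment a \code{\link{fragment_spec}}.
#' @param temperature K.
#' @return an \code{\link{fjc_fit}}.
#' @export
elc_fit <- function(summary_path, fragment, temperature = 298) {
  d <- read_summary_csv(summary_path)
  fjc_fit(d, fragment, temperature = temperature)
}
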