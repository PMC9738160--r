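#' Peptide fragment specification
#'
#' A named polyglycine-rich fragment, characterised by its residue count,
#' its maximum (contour) length between terminal C-alpha atoms in the
#' fully extended beta-pleated conformation, and the implied per-residue
#' rise. The force ladder lists the constant pulling forces applied to it.
#'
#' @param name fragment label.
#' @param n_residues number of residues (>= 2).
#' @param l_max end-to-end length of the fully extended conformation, in
#'   Angstrom. Exactly one of \code{l_max} / \code{rise_per_residue} may be
#'   omitted; the other is derived via
#'   \code{l_max = (n_residues - 1) * rise_per_residue}.
#' @param rise_per_residue per-residue rise in Angstrom.
#' @param force_ladder strictly increasing vector of pulling forces (pN),
#'   all >= 0.
#' @return an object of class \code{"fragment_spec"}.
#' @examples
#' fragment_spec("MaSp1a", 36, l_max = 118.1)
#' @export
fragment_spec <- function(name, n_residues, l_max = NULL,
                          rise_per_residue = NULL,
                          force_ladder = default_force_ladder()) {
  stopifnot(is.character(name), length(name) == 1)
  if (n_residues < 2 || n_residues != round(n_residues))
    stop("n_residues must be an integer >= 2")
  if (is.null(rise_per_residue) && is.null(l_max))
    stop("give l_max or rise_per_residue")
  if (is.null(rise_per_residue)) rise_per_residue <- l_max / (n_residues - 1)
  if (is.null(l_max)) l_max <- (n_residues - 1) * rise_per_residue
  if (abs(l_max - (n_residues - 1) * rise_per_residue) > 0.05)
    stop("l_max inconsistent with (n_residues - 1) * rise_per_residue")
  if (length(force_ladder) && (any(force_ladder < 0) ||
      any(diff(force_ladder) <= 0)))
    stop("force_ladder must be non-negative and strictly increasing")
  structure(
    list(name = name, n_residues = as.integer(n_residues), l_max = l_max,
         rise_per_residue = rise_per_residue, force_ladder = force_ladder),
    class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("Fragment %s: %d residues, L_max = %.1f A (rise %.4f A/residue)\n",
              x$name, x$n_residues, x$l_max, x$rise_per_residue))
  cat(sprintf("  force ladder (pN): %s\n",
              paste(x$force_ladder, collapse = ", ")))
  invisible(x)
}

#' The constant-force pulling ladder
#'
#' The 16 pulling forces (pN) applied to each fragment:
#' 10-50 in steps of 10, then 100-600 in steps of 50.
#'
#' @return numeric vector of 16 forces in pN.
#' @export
default_force_ladder <- function() {
  c(10, 20, 30, 40, 50, 100, 150, 200, 250, 300, 350, 400, 450, 500, 550, 600)
}

#' Packaged spidroin fragment fixtures
#'
#' The two Argiope aurantia major-ampullate spidroin fragments studied by
#' the pipeline: the MaSp1a polyglycine-rich fragment (36 residues,
#' extended length 118.1 A) and the MaSp2.2a fragment (50 residues,
#' 166.5 A). Per-residue rises are back-computed from the extended
#' lengths.
#'
#' @return named list of two \code{\link{fragment_spec}} objects,
#'   \code{MaSp1a} and \code{MaSp2.2a}.
#' @export
masp_fragments <- function() {
  list(
    MaSp1a   = fragment_spec("MaSp1a",   36, l_max = 118.1),
    MaSp2.2a = fragment_spec("MaSp2.2a", 50, l_max = 166.5))
}

#' Zero-force trajectory averages for the spidroin fragments
#'
#' Per-trajectory mean end-to-end distances (Angstrom) and their standard
#' deviations from three independent 20 ns all-atom pulling-free runs of
#' each fragment, as tabulated in the source study. These serve as the
#' measured equilibrium lengths entering the hidden-length analysis.
#'
#' @return data.frame with columns \code{fragment}, \code{trajectory},
#'   \code{mean_L_A}, \code{sd_L_A}.
#' @export
masp_zero_force_table <- function() {
  data.frame(
    fragment   = rep(c("MaSp1a", "MaSp2.2a"), each = 3),
    trajectory = rep(1:3, 2),
    mean_L_A   = c(40.1, 33.4, 43.9, 52.3, 60.1, 68.8),
    sd_L_A     = c(14.6, 20.5, 15.1, 27.6, 22.0, 24.8))
}
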