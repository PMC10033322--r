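## Polar transmembrane defect reaction coordinate.
##
## xi = fraction of thin slices across the hydrophobic transmembrane slab
## (default 2.8 nm, 0.1 nm increments, 28 slices, centred on the bilayer
## centre) that contain at least one lipid or water oxygen atom.  xi = 0 is
## an intact membrane, xi = 1 a continuous polar defect (pore).

#' Build the transmembrane slice grid
#'
#' @param slab_thickness slab thickness, nm (default 2.8).
#' @param increment slice thickness, nm (default 0.1); must divide the slab
#'   thickness to within 1e-6 nm, otherwise a configuration error is raised
#'   (no silent truncation).
#' @return a \code{slice_grid} with \code{n_slices = slab_thickness/increment}.
#' @export
build_slice_grid <- function(slab_thickness = 2.8, increment = 0.1) {
  if (slab_thickness <= 0 || increment <= 0)
    stop("slab_thickness and increment must be > 0")
  n <- slab_thickness / increment
  if (abs(n - round(n)) * increment > 1e-6)
    stop("configuration error: slab thickness ", slab_thickness,
         " nm is not an integer multiple of increment ", increment, " nm")
  structure(list(slab_thickness = slab_thickness, increment = increment,
                 n_slices = as.integer(round(n))),
            class = "slice_grid")
}

#' @export
print.slice_grid <- function(x, ...) {
  cat(sprintf("<slice_grid> %d slices of %g nm spanning %g nm\n",
              x$n_slices, x$increment, x$slab_thickness))
  invisible(x)
}

## Slice index for z-positions relative to the bilayer centre.
## Slices tile [-slab/2, +slab/2]; membership is (lo, hi] so an atom exactly
## on a boundary belongs to the lower slice.  Returns NA outside the slab.
slice_index <- function(zrel, grid) {
  z0 <- -grid$slab_thickness / 2
  u <- (zrel - z0) / grid$increment
  idx <- ceiling(u) - 1
  exact <- u == floor(u)             # boundary -> lower slice
  idx[exact] <- u[exact] - 1
  idx[idx < 0 | idx >= grid$n_slices] <- NA
  as.integer(idx)
}

occupied_slices <- function(z, center, grid) {
  idx <- slice_index(z - center, grid)
  unique(idx[!is.na(idx)])
}

#' Per-frame polar defect reaction coordinate
#'
#' @param frame an \code{edgepore_frame}.
#' @param top topology.
#' @param grid a \code{slice_grid} (default paper grid: 2.8 nm / 0.1 nm).
#' @param polar index vector of polar atoms (default lipid + water oxygens);
#'   an empty selection is an error, distinct from a legal xi = 0 on a slab
#'   that simply contains no polar atoms.
#' @param center bilayer centre z; computed from the lipid atoms when NULL.
#' @param center_weighting passed to \code{\link{bilayer_center}}.
#' @return xi in [0, 1]; always a multiple of 1/n_slices.
#' @export
frame_xi <- function(frame, top, grid = build_slice_grid(),
                     polar = polar_selection(top), center = NULL,
                     center_weighting = "mass") {
  if (!length(polar))
    stop("empty polar selection: the defect coordinate needs lipid/water oxygens")
  if (is.null(center)) center <- bilayer_center(frame, top, center_weighting)
  occ <- occupied_slices(frame$coords[polar, 3], center, grid)
  length(occ) / grid$n_slices
}

#' Define a beta-strand edge for per-edge defect attribution
#'
#' @param label edge label.
#' @param atoms heavy-atom index vector of the edge beta-strands.
#' @param lateral_cutoff in-plane distance cutoff, nm (default 1.0): a polar
#'   atom is attributed to the edge when its lateral minimum-image distance
#'   to the nearest edge-strand heavy atom is at most this value.
#' @return an \code{edge_definition}.
#' @export
edge_definition <- function(label, atoms, lateral_cutoff = 1.0) {
  if (!length(atoms)) stop("edge '", label, "': empty atom list")
  if (lateral_cutoff <= 0) stop("edge '", label, "': cutoff must be > 0")
  structure(list(label = label, atoms = as.integer(atoms),
                 lateral_cutoff = lateral_cutoff),
            class = "edge_definition")
}

#' Per-edge polar defect reaction coordinate
#'
#' Identical to \code{\link{frame_xi}} but counting only polar atoms whose
#' lateral (xy) minimum-image distance to the nearest edge-strand heavy atom
#' is within the edge's lateral cutoff.  An atom may satisfy this for several
#' edges and then counts toward each; consequently per-edge xi is bounded by
#' the total xi frame-wise.
#'
#' @inheritParams frame_xi
#' @param edge an \code{edge_definition}.
#' @return xi in [0, 1].
#' @export
edge_xi <- function(frame, top, grid = build_slice_grid(), edge,
                    polar = polar_selection(top), center = NULL,
                    center_weighting = "mass") {
  if (!length(polar))
    stop("empty polar selection: the defect coordinate needs lipid/water oxygens")
  if (is.null(center)) center <- bilayer_center(frame, top, center_weighting)
  epts <- frame$coords[edge$atoms, , drop = FALSE]
  keep <- vapply(polar, function(i) {
    min(mi_dist_point(frame$coords[i, ], epts, frame$box, dims = 1:2)) <=
      edge$lateral_cutoff
  }, TRUE)
  if (!any(keep)) return(0)
  occ <- occupied_slices(frame$coords[polar[keep], 3], center, grid)
  length(occ) / grid$n_slices
}

#' Defect series over a trajectory set
#'
#' Computes xi (and optionally per-edge xi) for every retained frame of every
#' replicate.
#'
#' @param traj an \code{edgepore_trajectory}.
#' @param grid slice grid.
#' @param edges optional named list of \code{edge_definition}s.
#' @param polar polar selection (default lipid + water oxygens).
#' @return data frame: replicate, frame_time_ps, xi, one column per edge.
#' @export
defect_series <- function(traj, grid = build_slice_grid(), edges = NULL,
                          polar = polar_selection(traj$topology)) {
  rows <- list()
  for (r in seq_along(traj$replicates)) {
    for (f in traj$replicates[[r]]) {
      row <- data.frame(replicate = r, frame_time_ps = f$time,
                        xi = frame_xi(f, traj$topology, grid, polar))
      for (e in edges)
        row[[paste0("xi_", e$label)]] <-
          edge_xi(f, traj$topology, grid, e, polar)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_slices") <- grid$n_slices
  out
}

#' Distribution of the defect coordinate over all replicates
#'
#' Frames from all replicates are combined and counted into one bin per
#' attainable xi value (k/n_slices, k = 0..n_slices); probabilities are
#' direct frequencies (counting, not estimation).  Per-replicate
#' distributions are retained to give the standard error of the mean across
#' replicates per bin.
#'
#' @param xi_values numeric vector of per-frame xi, or a list of such vectors
#'   (one per replicate).
#' @param n_slices number of slices defining the attainable values.
#' @return data frame: xi, p, sem, count; \code{sum(p) == 1}.
#' @export
xi_distribution <- function(xi_values, n_slices = 28) {
  if (!is.list(xi_values)) xi_values <- list(xi_values)
  if (!sum(lengths(xi_values))) stop("no frames given")
  bins <- (0:n_slices) / n_slices
  to_bin <- function(v) {
    k <- round(v * n_slices)
    if (any(abs(v * n_slices - k) > 1e-9))
      stop("xi values are not multiples of 1/n_slices; wrong n_slices?")
    tabulate(k + 1L, nbins = n_slices + 1L)
  }
  per_rep <- lapply(xi_values, to_bin)
  counts <- Reduce(`+`, per_rep)
  p <- counts / sum(counts)
  prep <- vapply(per_rep, function(cn) cn / sum(cn), numeric(n_slices + 1L))
  sem <- if (length(per_rep) > 1) apply(prep, 1, stats::sd) / sqrt(length(per_rep))
         else rep(0, n_slices + 1L)
  data.frame(xi = bins, p = p, sem = sem, count = counts)
}

#' Free-energy transform of a xi distribution
#'
#' dG_i = -R T ln(p_i) with R = 0.0083145 kJ/(mol K).  Bins with p = 0 are
#' undefined and returned as NA (flagged, never 0 or +/-Inf).
#'
#' @param p probability vector (or the data frame from
#'   \code{\link{xi_distribution}}, whose \code{p} column is used).
#' @param temperature temperature, K (default 300).
#' @return numeric vector of free energies, kJ/mol (NA where p = 0), or the
#'   input data frame with a \code{dG_kJmol} column appended.
#' @export
xi_free_energy <- function(p, temperature = 300) {
  if (temperature <= 0) stop("temperature must be > 0")
  df <- NULL
  if (is.data.frame(p)) { df <- p; p <- p$p }
  if (any(p < 0)) stop("negative probabilities")
  dg <- ifelse(p > 0, -RGAS * temperature * log(p), NA_real_)
  if (is.null(df)) dg else { df$dG_kJmol <- dg; df }
}
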