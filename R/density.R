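## Partial density profiles along the membrane normal, binned relative to
## the centre of the lipid atoms and averaged over replicates with SEM.

axial_profile <- function(z, value, sem, quantity, bin_width,
                          extra = NULL) {
  out <- data.frame(z = z, value = value, sem = sem)
  if (!is.null(extra)) out <- cbind(out, extra)
  attr(out, "quantity") <- quantity
  attr(out, "bin_width") <- bin_width
  class(out) <- c("axial_profile", "data.frame")
  out
}

## symmetric uniform bin edges covering [-half, half]
profile_edges <- function(half_range, bin_width) {
  n <- ceiling(round(half_range / bin_width, 9))
  seq(-n * bin_width, n * bin_width, by = bin_width)
}

default_half_range <- function(traj) max(traj$replicates[[1]][[1]]$box[3]) / 2

## bin index into edges ([lo, hi) per bin); NA outside range (dropped, not
## clamped)
axial_bin <- function(zrel, edges) {
  idx <- floor((zrel - edges[1]) / (edges[2] - edges[1])) + 1L
  idx[zrel < edges[1] | zrel >= edges[length(edges)]] <- NA_integer_
  as.integer(idx)
}

#' Partial density profile of a selection along the membrane normal
#'
#' Per frame, each selected atom contributes to the bin of (z - z_center),
#' where z_center is the centre of the lipid atoms.  Densities are
#' count (times mass, for mass weighting) / (bin_width * box_x * box_y),
#' averaged over frames within each replicate, then mean and SEM across
#' replicates.  Atoms beyond the profile range are dropped from that frame's
#' histogram (not clamped).
#'
#' @param traj an \code{edgepore_trajectory}.
#' @param selection atom index vector; an empty selection yields an all-zero
#'   profile with a warning.
#' @param bin_width bin width, nm (default 0.1).
#' @param weighting "number" or "mass".
#' @param half_range profile half-extent, nm (default half the box height).
#' @param center_weighting bilayer-centre weighting ("mass"/"geometric").
#' @return an \code{axial_profile} (quantity = number_density or
#'   mass_density); values in atoms/nm^3 (or u/nm^3).
#' @export
partial_density <- function(traj, selection, bin_width = 0.1,
                            weighting = c("number", "mass"),
                            half_range = NULL,
                            center_weighting = "mass") {
  weighting <- match.arg(weighting)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!length(selection)) {
    warning("empty selection: returning all-zero profile")
  }
  if (is.null(half_range)) half_range <- default_half_range(traj)
  edges <- profile_edges(half_range, bin_width)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w <- if (weighting == "mass") atom_mass(traj$topology$element[selection])
       else rep(1, length(selection))
  rep_means <- matrix(0, nb, length(traj$replicates))
  for (r in seq_along(traj$replicates)) {
    frames <- traj$replicates[[r]]
    acc <- numeric(nb)
    for (f in frames) {
      dens <- numeric(nb)
      if (length(selection)) {
        zc <- bilayer_center(f, traj$topology, center_weighting)
        idx <- axial_bin(f$coords[selection, 3] - zc, edges)
        ok <- !is.na(idx)
        if (any(ok)) {
          counts <- vapply(split(w[ok], idx[ok]), sum, 0)
          dens[as.integer(names(counts))] <-
            counts / (bin_width * f$box[1] * f$box[2])
        }
      }
      acc <- acc + dens
    }
    rep_means[, r] <- acc / length(frames)
  }
  mu <- rowMeans(rep_means)
  sem <- if (ncol(rep_means) > 1) apply(rep_means, 1, stats::sd) / sqrt(ncol(rep_means))
         else rep(0, nb)
  axial_profile(centers, mu, sem,
                quantity = paste0(weighting, "_density"),
                bin_width = bin_width)
}

#' Axial density of a protein residue range
#'
#' Convenience wrapper around \code{\link{partial_density}} with the
#' selection built from a residue range, e.g. residues 13-16 (the HHQK
#' domain) to locate the hydrophilic patch inside the bilayer.
#'
#' @inheritParams partial_density
#' @param residue_range integer vector of residue numbers.
#' @param representative "all_heavy" or "sidechain".
#' @export
residue_axial_density <- function(traj, residue_range,
                                  representative = c("all_heavy", "sidechain"),
                                  bin_width = 0.1, half_range = NULL) {
  representative <- match.arg(representative)
  sel <- atom_select(traj$topology, role = "protein",
                     residue = residue_range, heavy = TRUE)
  if (representative == "sidechain")
    sel <- intersect(sel, atom_select(traj$topology, subrole = "sidechain"))
  if (!length(sel)) warning("no atoms in residue range ",
                            paste(range(residue_range), collapse = "-"))
  partial_density(traj, sel, bin_width = bin_width, half_range = half_range)
}
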