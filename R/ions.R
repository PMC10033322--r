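## Ion first-hydration-shell composition, coordination profiles along the
## bilayer normal, crossing-event detection, and permeation free-energy
## profiles by Boltzmann inversion of the axial ion density.

SHELL_CATEGORIES <- c("water_O", "lipid_O", "protein_total",
                      "backbone_carbonyl_O_res9_21",
                      "H13_sidechain", "H14_sidechain", "Q15_sidechain")

## partner index sets for the shell categories (heavy atoms only).
## Protein subcategories follow the ion-coordination figure groups:
## backbone carbonyl oxygens of residues 9-21 (the beta1 strand),
## imidazole nitrogens of H13/H14, and the side-chain carbonyl O of Q15.
shell_partner_sets <- function(top) {
  his <- c("HIS", "HSD", "HSE")
  list(
    water_O = atom_select(top, role = "water", subrole = "water_O"),
    lipid_O = atom_select(top, role = "lipid", element = "O"),
    protein_total = atom_select(top, role = "protein", heavy = TRUE),
    backbone_carbonyl_O_res9_21 =
      atom_select(top, role = "protein", subrole = "carbonyl_O",
                  residue = 9:21, name = "O"),
    H13_sidechain = intersect(
      atom_select(top, role = "protein", residue = 13, name = c("ND1", "NE2")),
      which(top$residue_name %in% his)),
    H14_sidechain = intersect(
      atom_select(top, role = "protein", residue = 14, name = c("ND1", "NE2")),
      which(top$residue_name %in% his)),
    Q15_sidechain = intersect(
      atom_select(top, role = "protein", residue = 15, name = "OE1"),
      which(top$residue_name == "GLN")))
}

#' First-hydration-shell composition of one ion in one frame
#'
#' Counts heavy atoms of each partner category within the shell cutoff of the
#' ion under the minimum-image convention.  Categories: water oxygens, lipid
#' oxygens, all protein heavy atoms, backbone carbonyl O of residues 9-21,
#' H13/H14 imidazole nitrogens, Q15 side-chain carbonyl O.
#'
#' @param frame an \code{edgepore_frame}.
#' @param top topology.
#' @param ion_index row position of the ion atom.
#' @param cutoff shell cutoff, nm (default 0.35, inclusive).
#' @return named integer vector over the shell categories, with attributes
#'   \code{cutoff} and \code{ion_z}.
#' @export
shell_composition <- function(frame, top, ion_index, cutoff = 0.35) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(ion_index) != 1 || is.na(ion_index) ||
      ion_index < 1 || ion_index > nrow(top))
    stop("ion_index out of range")
  sets <- shell_partner_sets(top)
  x <- frame$coords[ion_index, ]
  counts <- vapply(sets, function(s) {
    s <- setdiff(s, ion_index)
    if (!length(s)) return(0L)
    d <- mi_dist_point(x, frame$coords[s, , drop = FALSE], frame$box)
    sum(d <= cutoff)
  }, 0L)
  structure(counts, cutoff = cutoff, ion_z = unname(x[3]))
}

#' Ion coordination profile along the bilayer normal
#'
#' Every (ion, frame) observation is binned by z - z_center; per-bin mean
#' shell counts are reported per category with SEM across replicates.  Bins
#' with zero observations are flagged missing (NA).
#'
#' @param traj an \code{edgepore_trajectory}.
#' @param ion_selection row positions of the ions to profile (e.g. all K).
#' @param bin_width bin width, nm (default 0.1).
#' @param cutoff shell cutoff, nm (default 0.35).
#' @param half_range profile half-extent, nm.
#' @return long data frame: z, category, value (mean coordination), sem,
#'   n_obs; class \code{coordination_profile}.
#' @export
coordination_profile <- function(traj, ion_selection, bin_width = 0.1,
                                 cutoff = 0.35, half_range = NULL) {
  if (is.null(half_range)) half_range <- default_half_range(traj)
  edges <- profile_edges(half_range, bin_width)
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  ncat <- length(SHELL_CATEGORIES)
  sums <- array(0, c(nb, ncat, length(traj$replicates)))
  nobs <- matrix(0L, nb, length(traj$replicates))
  for (r in seq_along(traj$replicates)) {
    for (f in traj$replicates[[r]]) {
      zc <- bilayer_center(f, traj$topology)
      for (ion in ion_selection) {
        comp <- shell_composition(f, traj$topology, ion, cutoff)
        b <- axial_bin(attr(comp, "ion_z") - zc, edges)
        if (is.na(b)) next
        sums[b, , r] <- sums[b, , r] + as.numeric(comp)
        nobs[b, r] <- nobs[b, r] + 1L
      }
    }
  }
  rep_mean <- sums
  for (r in seq_len(dim(sums)[3]))
    rep_mean[, , r] <- sums[, , r] / ifelse(nobs[, r] > 0, nobs[, r], NA)
  rows <- list()
  for (j in seq_len(ncat)) {
    m <- rep_mean[, j, , drop = FALSE][, 1, ]
    m <- matrix(m, nrow = nb)
    mu <- rowMeans(m, na.rm = TRUE)
    mu[rowSums(!is.na(m)) == 0] <- NA
    sem <- apply(m, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    })
    rows[[j]] <- data.frame(z = centers, category = SHELL_CATEGORIES[j],
                            value = mu, sem = sem, n_obs = rowSums(nobs))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coordination_profile", "data.frame")
  out
}

#' Detect ion membrane-crossing events
#'
#' Three-state machine per ion per replicate: bulk_up (z > h + m), slab
#' (|z| <= h), bulk_down (z < -(h + m)), with h = \code{slab_halfwidth} and
#' m = \code{bulk_margin} providing hysteresis against boundary chatter.  A
#' crossing is emitted when an ion goes bulk side -> slab -> opposite bulk
#' side without revisiting the origin side's bulk.
#'
#' @param traj an \code{edgepore_trajectory}.
#' @param ion_selection row positions of ions to track.
#' @param slab_halfwidth h, nm (default 1.4, half the 2.8 nm slab).
#' @param bulk_margin m, nm (default 0.4).
#' @return data frame: ion, replicate, entry_time, exit_time, direction
#'   ("up"/"down"); zero rows when no crossing occurs.
#' @export
crossing_events <- function(traj, ion_selection, slab_halfwidth = 1.4,
                            bulk_margin = 0.4) {
  h <- slab_halfwidth; m <- bulk_margin
  events <- list()
  for (r in seq_along(traj$replicates)) {
    frames <- traj$replicates[[r]]
    times <- vapply(frames, function(f) f$time, 0)
    for (ion in ion_selection) {
      z <- vapply(frames, function(f) f$coords[ion, 3], 0)
      zone <- ifelse(z > h + m, 1L, ifelse(z < -(h + m), -1L,
                     ifelse(abs(z) <= h, 0L, NA_integer_)))
      origin <- NA_integer_; entered <- FALSE; entry_t <- NA_real_
      for (i in seq_along(zone)) {
        zn <- zone[i]
        if (is.na(zn)) next
        if (zn == 0L) {
          if (!is.na(origin) && !entered) { entered <- TRUE; entry_t <- times[i] }
        } else if (!is.na(origin) && zn == -origin && entered) {
          events[[length(events) + 1L]] <-
            data.frame(ion = ion, replicate = r, entry_time = entry_t,
                       exit_time = times[i],
                       direction = if (origin == 1L) "down" else "up")
          origin <- zn; entered <- FALSE
        } else {
          origin <- zn; entered <- FALSE
        }
      }
    }
  }
  if (!length(events))
    return(data.frame(ion = integer(), replicate = integer(),
                      entry_time = numeric(), exit_time = numeric(),
                      direction = character()))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Permeation free-energy profile by Boltzmann inversion
#'
#' dG(z) = -R T ln(rho(z)/rho_bulk), where rho_bulk is the mean density over
#' the bulk window (both signs of z).  Empty or zero bins are flagged
#' undefined (NA), never infinite.
#'
#' @param profile an \code{axial_profile} of ion number density.
#' @param bulk_window two-sided |z| interval defining bulk, nm (default
#'   c(2.5, 3.5)).
#' @param temperature temperature, K (default 300).
#' @return an \code{axial_profile} with quantity "free_energy" (kJ/mol).
#' @export
permeation_free_energy <- function(profile, bulk_window = c(2.5, 3.5),
                                   temperature = 300) {
  if (temperature <= 0) stop("temperature must be > 0")
  in_bulk <- abs(profile$z) >= bulk_window[1] & abs(profile$z) <= bulk_window[2]
  if (!any(in_bulk)) stop("bulk window contains no bins")
  rho_bulk <- mean(profile$value[in_bulk])
  if (!is.finite(rho_bulk) || rho_bulk <= 0)
    stop("bulk density is zero; cannot normalize the free-energy profile")
  v <- profile$value
  dg <- ifelse(is.finite(v) & v > 0,
               -RGAS * temperature * log(v / rho_bulk), NA_real_)
  axial_profile(profile$z, dg, rep(NA_real_, length(dg)),
                quantity = "free_energy", bin_width = attr(profile, "bin_width"))
}
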