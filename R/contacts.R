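## Residue-resolved short-range contact analysis: a residue is in contact
## with a partner group in a frame when at least one heavy-atom pair is
## within the cutoff (0.5 nm by default) under the minimum-image convention.
## Frequency = fraction of frames in contact, averaged across replicates.

#' Per-frame residue contacts
#'
#' @param frame an \code{edgepore_frame}.
#' @param top topology.
#' @param residue_range protein residue numbers to analyse.
#' @param partner atom index vector of the partner group (hydrogens are
#'   excluded from both sides automatically).
#' @param cutoff heavy-atom distance cutoff, nm (default 0.5, inclusive).
#' @param method neighbour-search method passed to \code{\link{count_within}}.
#' @return named logical vector, one entry per residue in the range that has
#'   atoms; contact is boolean presence (>= 1 pair), not a pair count.
#' @export
frame_contacts <- function(frame, top, residue_range, partner, cutoff = 0.5,
                           method = "cell") {
  if (cutoff <= 0) stop("cutoff must be > 0")
  partner <- partner[top$element[partner] != "H"]
  res_atoms <- atom_select(top, role = "protein", residue = residue_range,
                           heavy = TRUE)
  res_ids <- sort(unique(top$residue_number[res_atoms]))
  out <- logical(length(res_ids))
  names(out) <- res_ids
  if (!length(partner) || !length(res_atoms)) return(out)
  cnt <- count_within(frame$coords[res_atoms, , drop = FALSE],
                      frame$coords[partner, , drop = FALSE],
                      cutoff, frame$box, method = method)
  hit <- tapply(cnt > 0, top$residue_number[res_atoms], any)
  out[names(hit)] <- as.logical(hit)
  out
}

#' Residue contact frequencies over a trajectory
#'
#' @param traj an \code{edgepore_trajectory}.
#' @param residue_range protein residue numbers.
#' @param partners named list of partner atom-index vectors (categories such
#'   as phosphate, choline, water, K, Cl), or a single index vector.
#' @param cutoff heavy-atom cutoff, nm.
#' @param method neighbour-search method.
#' @return contact map data frame: residue_number, residue_name, partner,
#'   frequency (in [0,1], mean across replicates with equal weight), sem.
#' @export
contact_frequency <- function(traj, residue_range, partners, cutoff = 0.5,
                              method = "cell") {
  if (!is.list(partners)) partners <- list(partner = partners)
  if (is.null(names(partners)))
    names(partners) <- paste0("partner", seq_along(partners))
  top <- traj$topology
  res_atoms <- atom_select(top, role = "protein", residue = residue_range)
  res_ids <- sort(unique(top$residue_number[res_atoms]))
  res_names <- vapply(res_ids, function(r)
    top$residue_name[top$residue_number == r & top$role == "protein"][1], "")
  out <- list()
  for (p in names(partners)) {
    freq_rep <- matrix(0, length(res_ids), length(traj$replicates))
    for (r in seq_along(traj$replicates)) {
      frames <- traj$replicates[[r]]
      hits <- matrix(FALSE, length(res_ids), length(frames))
      for (j in seq_along(frames))
        hits[, j] <- frame_contacts(frames[[j]], top, residue_range,
                                    partners[[p]], cutoff, method)[as.character(res_ids)]
      freq_rep[, r] <- rowMeans(hits)
    }
    mu <- rowMeans(freq_rep)
    sem <- if (ncol(freq_rep) > 1)
      apply(freq_rep, 1, stats::sd) / sqrt(ncol(freq_rep)) else rep(0, length(res_ids))
    out[[p]] <- data.frame(residue_number = res_ids, residue_name = res_names,
                           partner = p, frequency = mu, sem = sem)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contact_map", "data.frame")
  res
}

#' Standard partner categories for contact mapping
#'
#' Builds the partner selections of the contact-map figures: lipid
#' phosphate, choline, carbonyl/ester oxygens, water, K and Cl.
#'
#' @param top topology.
#' @return named list of atom index vectors (empty categories dropped).
#' @export
contact_partner_sets <- function(top) {
  sets <- list(
    phosphate = atom_select(top, role = "lipid", subrole = "phosphate"),
    choline   = atom_select(top, role = "lipid", subrole = "choline"),
    lipid_carbonyl = atom_select(top, role = "lipid",
                                 subrole = c("carbonyl_O", "ester_O")),
    water = atom_select(top, role = "water", subrole = "water_O"),
    K  = atom_select(top, role = "ion", subrole = "K"),
    Cl = atom_select(top, role = "ion", subrole = "Cl"))
  sets[lengths(sets) > 0]
}
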