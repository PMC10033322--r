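## Aggregate stability metrics: least-squares superposition RMSD of the
## transmembrane beta-strands (mainchain + C-beta), dihedral-based
## beta-structure content, and RMSD-based conformational pooling.

#' Build a superposition fit mask
#'
#' Mainchain (N, CA, C, O) plus C-beta atoms of a residue set, the standard
#' mask for transmembrane beta-strand RMSD.
#'
#' @param top topology.
#' @param residue integer vector of residue numbers (NULL = all protein).
#' @param chain optional chain filter.
#' @param atoms atom names included (default mainchain + CB).
#' @return integer vector of row positions (>= 3 required downstream).
#' @export
fit_mask <- function(top, residue = NULL, chain = NULL,
                     atoms = c("N", "CA", "C", "O", "CB")) {
  atom_select(top, role = "protein", residue = residue, chain = chain,
              name = atoms)
}

## rank check: collinear (or fewer than 3) points cannot fix a rotation
assert_not_degenerate <- function(x) {
  if (nrow(x) < 3) stop("degenerate fit mask: fewer than 3 atoms")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-12))
    stop("degenerate fit mask: atoms are collinear")
  invisible(TRUE)
}

#' Optimal-superposition RMSD
#'
#' Least-squares rigid-body superposition (Kabsch, proper rotation enforced:
#' no reflections) of \code{coords} onto \code{ref} over the mask, then RMSD
#' over the mask.  Symmetric in its two coordinate arguments and zero iff
#' the masked coordinates are congruent.
#'
#' @param coords N x 3 matrix or \code{edgepore_frame}.
#' @param ref reference coordinates (same form, same atom count).
#' @param mask integer index vector (default: all rows).
#' @return RMSD in nm (>= 0).
#' @export
superpose_rmsd <- function(coords, ref, mask = NULL) {
  if (inherits(coords, "edgepore_frame")) coords <- coords$coords
  if (inherits(ref, "edgepore_frame")) ref <- ref$coords
  if (is.null(mask)) mask <- seq_len(nrow(coords))
  x <- coords[mask, , drop = FALSE]
  y <- ref[mask, , drop = FALSE]
  if (nrow(x) != nrow(y)) stop("mask resolves to unequal atom counts")
  assert_not_degenerate(x)
  assert_not_degenerate(y)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))             # H = X^T Y
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- xc %*% t(rot)
  sqrt(mean(rowSums((fit - yc)^2)))
}

#' RMSD without superposition (fixed placement)
#'
#' @inheritParams superpose_rmsd
#' @return RMSD in nm.
#' @export
rmsd_nofit <- function(coords, ref, mask = NULL) {
  if (inherits(coords, "edgepore_frame")) coords <- coords$coords
  if (inherits(ref, "edgepore_frame")) ref <- ref$coords
  if (is.null(mask)) mask <- seq_len(nrow(coords))
  sqrt(mean(rowSums((coords[mask, , drop = FALSE] -
                     ref[mask, , drop = FALSE])^2)))
}

## torsion angle (degrees) for points p1-p2-p3-p4
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi angles per residue
#'
#' @param frame an \code{edgepore_frame}.
#' @param top topology.
#' @param residue_range residues to evaluate (default all protein residues).
#' @return data frame: chain, residue_number, phi, psi (degrees; NA where a
#'   flanking residue is missing, i.e. at chain termini).
#' @export
backbone_dihedrals <- function(frame, top, residue_range = NULL) {
  sel <- atom_select(top, role = "protein", name = c("N", "CA", "C"))
  bt <- top[sel, ]
  bt$row <- sel
  rows <- list()
  for (ch in unique(bt$chain_id)) {
    sub <- bt[bt$chain_id == ch, ]
    resid <- sort(unique(sub$residue_number))
    if (!is.null(residue_range)) resid <- intersect(resid, residue_range)
    get <- function(rn, nm) {
      i <- sub$row[sub$residue_number == rn & sub$name == nm]
      if (length(i) == 1) frame$coords[i, ] else NULL
    }
    for (rn in resid) {
      n <- get(rn, "N"); ca <- get(rn, "CA"); c <- get(rn, "C")
      cp <- get(rn - 1, "C"); nn <- get(rn + 1, "N")
      phi <- if (!is.null(cp) && !is.null(n) && !is.null(ca) && !is.null(c))
        dihedral_angle(cp, n, ca, c) else NA_real_
      psi <- if (!is.null(n) && !is.null(ca) && !is.null(c) && !is.null(nn))
        dihedral_angle(n, ca, c, nn) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(chain = ch, residue_number = rn, phi = phi, psi = psi)
    }
  }
  do.call(rbind, rows)
}

#' Extended beta-structure content
#'
#' Fraction of residues whose (phi, psi) fall in the extended-beta region:
#' phi in [-180, -45] and (psi in [45, 180] or psi in [-180, -150]).
#' Residues without both dihedrals (chain termini) are excluded from the
#' denominator.  A dihedral criterion is used (rather than an H-bond method
#' like DSSP) because it is well defined on idealized synthetic sheets.
#'
#' @inheritParams backbone_dihedrals
#' @return fraction in [0, 1] (NaN when no residue has both dihedrals).
#' @export
beta_content <- function(frame, top, residue_range = NULL) {
  d <- backbone_dihedrals(frame, top, residue_range)
  ok <- !is.na(d$phi) & !is.na(d$psi)
  d <- d[ok, ]
  if (!nrow(d)) return(NaN)
  in_beta <- d$phi >= -180 & d$phi <= -45 &
    ((d$psi >= 45 & d$psi <= 180) | (d$psi >= -180 & d$psi <= -150))
  mean(in_beta)
}

#' Pool trajectories by edge RMSD
#'
#' Three conformational pools from per-trajectory mean RMSD: pool I
#' (rmsd < t1), II (t1 <= rmsd < t2), III (rmsd >= t2).  The default upper
#' threshold 0.6 nm is the conduction boundary: edges beyond it do not
#' permeate ions.
#'
#' @param rmsd numeric vector of per-trajectory mean RMSD, nm.
#' @param thresholds two strictly increasing thresholds (t1, t2), nm;
#'   default c(0.3, 0.6).
#' @return factor with levels I, II, III and attribute "thresholds".
#' @export
pool_by_rmsd <- function(rmsd, thresholds = c(0.3, 0.6)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("thresholds must be two strictly increasing values")
  pool <- ifelse(rmsd < thresholds[1], "I",
                 ifelse(rmsd < thresholds[2], "II", "III"))
  structure(factor(pool, levels = c("I", "II", "III")),
            thresholds = thresholds)
}

#' Per-replicate RMSD time series against a reference structure
#'
#' @param traj an \code{edgepore_trajectory}.
#' @param reference reference frame (default: first frame of replicate 1).
#' @param mask fit mask (default: mainchain + CB of all protein residues).
#' @return data frame: replicate, frame_time_ps, rmsd_nm.
#' @export
rmsd_series <- function(traj, reference = NULL, mask = NULL) {
  if (is.null(reference)) reference <- traj$replicates[[1]][[1]]
  if (is.null(mask)) mask <- fit_mask(traj$topology)
  rows <- list()
  for (r in seq_along(traj$replicates))
    for (f in traj$replicates[[r]])
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, frame_time_ps = f$time,
                   rmsd_nm = superpose_rmsd(f, reference, mask))
  do.call(rbind, rows)
}
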