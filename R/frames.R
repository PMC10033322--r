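#' Construct a frame snapshot
#'
#' One time point of a trajectory: an N x 3 coordinate matrix in nm, the
#' orthorhombic box lengths in nm, and the time stamp in ps.  The membrane
#' normal is the third axis by convention.
#'
#' @param coords numeric N x 3 matrix, nm.
#' @param box numeric length-3 vector of box edges, nm (all > 0).
#' @param time time in ps.
#' @return an \code{edgepore_frame}.
#' @export
frame_snapshot <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "edgepore_frame")
}

#' @export
print.edgepore_frame <- function(x, ...) {
  cat(sprintf("<edgepore_frame> %d atoms, t = %g ps, box = %s nm\n",
              nrow(x$coords), x$time, paste(signif(x$box, 4), collapse = " x ")))
  invisible(x)
}

#' Bundle a topology with one or more replicate frame sequences
#'
#' All replicates share a single topology; frames within a replicate are
#' time-ordered.  \code{stride} records the ps between retained samples and
#' \code{discard} the ps of initial equilibration that were removed.
#'
#' @param topology shared \code{edgepore_topology}.
#' @param replicates list of lists of \code{edgepore_frame}s.
#' @param stride sampling interval, ps (default 100).
#' @param discard removed equilibration span, ps (default 5e5, i.e. 500 ns).
#' @return an \code{edgepore_trajectory}.
#' @export
trajectory_set <- function(topology, replicates, stride = 100,
                           discard = 500000) {
  if (!inherits(topology, "edgepore_topology")) stop("need an edgepore_topology")
  if (!length(replicates)) stop("need at least one replicate")
  natom <- nrow(topology)
  for (r in seq_along(replicates)) {
    frames <- replicates[[r]]
    if (!length(frames)) stop("replicate ", r, " is empty")
    times <- vapply(frames, function(f) f$time, 0)
    if (is.unsorted(times)) stop("frames in replicate ", r, " not time-ordered")
    for (f in frames)
      if (nrow(f$coords) != natom)
        stop("replicate ", r, ": frame atom count (", nrow(f$coords),
             ") != topology atom count (", natom, ")")
  }
  structure(list(topology = topology, replicates = replicates,
                 stride = stride, discard = discard),
            class = "edgepore_trajectory")
}

#' @export
print.edgepore_trajectory <- function(x, ...) {
  cat(sprintf("<edgepore_trajectory> %d replicate(s), %s frames, %d atoms\n",
              length(x$replicates),
              paste(vapply(x$replicates, length, 0L), collapse = "+"),
              nrow(x$topology)))
  invisible(x)
}

n_frames <- function(traj) sum(vapply(traj$replicates, length, 0L))

## --- minimum-image helpers (orthorhombic box) -------------------------------

## displacement components under the minimum-image convention
mi_delta <- function(d, L) d - L * round(d / L)

#' Minimum-image distances from one point to a set of points
#'
#' @param x numeric length-3 point (or length-2 when \code{dims = 1:2}).
#' @param pts matrix of points.
#' @param box box lengths.
#' @param dims which axes enter the distance (1:2 for lateral, 1:3 full).
#' @return numeric vector of distances, nm.
#' @keywords internal
mi_dist_point <- function(x, pts, box, dims = 1:3) {
  d2 <- 0
  for (k in dims) d2 <- d2 + mi_delta(pts[, k] - x[k], box[k])^2
  sqrt(d2)
}

## all-pairs minimum-image distance matrix between two coordinate sets
mi_cross_dist <- function(a, b, box, dims = 1:3) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in dims) {
    dk <- outer(a[, k], b[, k], "-")
    out <- out + mi_delta(dk, box[k])^2
  }
  sqrt(out)
}

#' Count neighbours within a cutoff (cell-list accelerated)
#'
#' For every row of \code{a}, counts rows of \code{b} within \code{cutoff}
#' (inclusive) under the minimum-image convention.  \code{method = "cell"}
#' bins \code{b} into a periodic cell grid with cells no smaller than the
#' cutoff and only visits the 27 neighbouring cells; \code{method = "brute"}
#' is the all-pairs reference used as an internal fallback when the box is
#' too small for a 3-cell-per-axis grid.
#'
#' @param a,b coordinate matrices (nm).
#' @param cutoff distance cutoff, nm (inclusive).
#' @param box box lengths, nm.
#' @param method "cell" or "brute".
#' @param dims axes entering the distance (default all three).
#' @return integer vector, one count per row of \code{a}.
#' @export
count_within <- function(a, b, cutoff, box, method = c("cell", "brute"),
                         dims = 1:3) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(b) == 0 || nrow(a) == 0) return(integer(nrow(a)))
  ncell <- pmax(1L, floor(box[dims] / cutoff))
  if (method == "brute" || any(ncell < 3L) || nrow(b) < 32L) {
    d <- mi_cross_dist(a, b, box, dims)
    return(as.integer(rowSums(d <= cutoff)))
  }
  ## periodic cell list over b
  cell_of <- function(x) {
    idx <- matrix(0L, nrow(x), length(dims))
    for (j in seq_along(dims)) {
      k <- dims[j]
      w <- x[, k] %% box[k]
      idx[, j] <- pmin(floor(w / (box[k] / ncell[j])), ncell[j] - 1L)
    }
    idx
  }
  key_of <- function(idx) {
    key <- idx[, 1]
    mult <- ncell[1]
    for (j in seq_along(dims)[-1]) {
      key <- key + idx[, j] * mult
      mult <- mult * ncell[j]
    }
    key + 1L
  }
  bidx <- cell_of(b)
  bkey <- key_of(bidx)
  buckets <- split(seq_len(nrow(b)), bkey)
  aidx <- cell_of(a)
  offs <- as.matrix(expand.grid(rep(list(-1:1), length(dims))))
  counts <- integer(nrow(a))
  for (i in seq_len(nrow(a))) {
    neigh <- t((t(offs) + aidx[i, ]) %% ncell)
    keys <- unique(key_of(neigh))
    cand <- unlist(buckets[as.character(keys)], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d <- mi_dist_point(a[i, dims, drop = TRUE], b[cand, , drop = FALSE],
                       box, dims = dims)
    counts[i] <- sum(d <= cutoff)
  }
  counts
}

#' Bilayer centre along the membrane normal
#'
#' Centre of the lipid atoms (z component), the reference for every axial
#' binning.  Mass weighting is the default to match common density-tool
#' semantics; a geometric centre is available as a switch.
#'
#' @param frame an \code{edgepore_frame}.
#' @param top the topology.
#' @param weighting "mass" or "geometric".
#' @return scalar z, nm.
#' @export
bilayer_center <- function(frame, top, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  sel <- atom_select(top, role = "lipid")
  if (!length(sel)) stop("no lipid atoms in topology; cannot locate bilayer")
  z <- frame$coords[sel, 3]
  if (weighting == "mass") {
    w <- atom_mass(top$element[sel])
    if (sum(w) <= 0) w <- rep(1, length(sel))
    sum(w * z) / sum(w)
  } else mean(z)
}
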