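## Scripted synthetic membrane/protein/solvent systems with exactly known
## ground truth for every statistic in the pipeline.  Nothing here is
## simulated: coordinates are constructed, so every planted quantity (xi per
## frame, per-edge xi, contact frequencies, shell compositions, crossing
## counts) is recovered exactly by the corresponding analysis operation.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic bilayer system
#'
#' Defaults mirror the simulated systems this generator emulates: planar
#' POPC-like bilayer with head groups near +/-2 nm, a 2.5 nm-scale aqueous
#' slab on each side, and KCl at 600 mM ionic strength in the water phase.
#' Ion counts follow from the water-slab volume:
#' n_pairs = round(0.6022 * c[mol/l] * V_water[nm^3]) (0.6022/nm^3 per
#' mol/l is Avogadro's number over 1e24 nm^3 per litre).
#'
#' @param n_lipids_per_leaflet pseudo-lipids per leaflet (default 36).
#' @param leaflet_z head-group |z|, nm (default 2.0).
#' @param box box lengths, nm (default c(6, 6, 9): 2.5 nm water slabs).
#' @param n_waters water oxygens (default 400).
#' @param ionic_strength mol/l (default 0.6).
#' @param seed RNG seed; generation is bit-reproducible.
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_lipids_per_leaflet = 36, leaflet_z = 2.0,
                           box = c(6, 6, 9), n_waters = 400,
                           ionic_strength = 0.6, seed = 1) {
  stopifnot(leaflet_z > 0, all(box > 0), box[3] / 2 > leaflet_z + 0.3)
  structure(list(n_lipids_per_leaflet = n_lipids_per_leaflet,
                 leaflet_z = leaflet_z, box = box, n_waters = n_waters,
                 ionic_strength = ionic_strength, seed = seed),
            class = "synthetic_spec")
}

## one pseudo-lipid: tagged heavy atoms only, polar oxygens kept outside the
## 2.8 nm hydrophobic core (|z| >= 1.62 nm at the default leaflet_z = 2)
LIPID_ATOM_Z <- data.frame(
  name = c("N", "C12", "P", "O11", "O12", "O21", "O22",
           "C22", "C23", "C24", "C25"),
  dz   = c(0.25, 0.18, 0, 0.05, -0.05, -0.35, -0.38,
           -0.7, -1.0, -1.3, -1.6),
  dx   = c(0.05, -0.05, 0, 0.08, -0.08, 0.06, -0.06,
           0.02, -0.02, 0.02, -0.02))

#' Generate a synthetic bilayer system
#'
#' Pseudo-lipids (phosphate/choline/ester/carbonyl oxygens + acyl carbons)
#' on a jittered grid in two mirror-symmetric leaflets around
#' \code{+/-leaflet_z}, water oxygens and K+/Cl- ions in the aqueous slabs.
#' The hydrophobic transmembrane core is initially free of polar atoms, so
#' the defect coordinate of the pristine system is exactly 0 and the lipid
#' mass centre sits at z = 0 by symmetry.
#'
#' @param spec a \code{synthetic_spec}.
#' @return an \code{edgepore_system}: list(topology, frame, spec).
#' @export
make_bilayer_system <- function(spec = synthetic_spec()) {
  lx <- spec$box[1]; ly <- spec$box[2]; lz <- spec$box[3]
  nl <- spec$n_lipids_per_leaflet
  ng <- ceiling(sqrt(nl))
  if (ng * (lx / ng) * 0.5 < 0.3)
    stop("packing error: too many lipids for the box footprint")
  with_seed(spec$seed, {
    sp <- lx / ng
    gx <- (rep(seq_len(ng), ng)[seq_len(nl)] - 0.5) * sp
    gy <- (rep(seq_len(ng), each = ng)[seq_len(nl)] - 0.5) * (ly / ng)
    jit <- matrix(stats::runif(2 * nl, -0.04, 0.04), ncol = 2)
    nm <- rn <- ch <- character(0); ri <- integer(0)
    xyz <- NULL
    na <- nrow(LIPID_ATOM_Z)
    res <- 0L
    for (leaf in c(1, -1)) {
      for (i in seq_len(nl)) {
        res <- res + 1L
        x <- gx[i] + jit[i, 1] + LIPID_ATOM_Z$dx
        y <- gy[i] + jit[i, 2] - LIPID_ATOM_Z$dx
        z <- leaf * (spec$leaflet_z + LIPID_ATOM_Z$dz)
        xyz <- rbind(xyz, cbind(x, y, z))
        nm <- c(nm, LIPID_ATOM_Z$name)
        rn <- c(rn, rep("POPC", na)); ri <- c(ri, rep(res, na))
        ch <- c(ch, rep("L", na))
      }
    }
    wz_lo <- spec$leaflet_z + 0.3
    wz_hi <- lz / 2 - 0.05
    nw <- spec$n_waters
    wside <- rep(c(1, -1), length.out = nw)
    wxyz <- cbind(stats::runif(nw, 0, lx), stats::runif(nw, 0, ly),
                  wside * stats::runif(nw, wz_lo, wz_hi))
    xyz <- rbind(xyz, wxyz)
    nm <- c(nm, rep("OW", nw)); rn <- c(rn, rep("SOL", nw))
    ri <- c(ri, res + seq_len(nw)); ch <- c(ch, rep("W", nw))
    res <- res + nw
    v_water <- lx * ly * 2 * (wz_hi - wz_lo)
    npair <- max(1L, as.integer(round(0.6022 * spec$ionic_strength * v_water)))
    iside <- rep(c(1, -1), length.out = 2 * npair)
    ixyz <- cbind(stats::runif(2 * npair, 0, lx),
                  stats::runif(2 * npair, 0, ly),
                  iside * stats::runif(2 * npair, wz_lo, wz_hi))
    xyz <- rbind(xyz, ixyz)
    nm <- c(nm, rep(c("K", "CL"), each = npair))
    rn <- c(rn, rep(c("K", "CL"), each = npair))
    ri <- c(ri, res + seq_len(2 * npair)); ch <- c(ch, rep("I", 2 * npair))
    top <- topology(name = nm, residue_name = rn, residue_number = ri,
                    chain_id = ch)
    structure(list(topology = top,
                   frame = frame_snapshot(xyz, spec$box, time = 0),
                   spec = spec),
              class = "edgepore_system")
  })
}

#' @export
print.edgepore_system <- function(x, ...) {
  print(x$topology); invisible(x)
}

#' Embed an oligomer model into a bilayer system
#'
#' The model is translated to the lateral box centre (membrane-spanning
#' around z = 0); lipids, waters and ions within \code{hole_radius} of the
#' model's lateral centre are removed so planted statistics stay exact.
#'
#' @param system an \code{edgepore_system}.
#' @param model an \code{oligomer_model}.
#' @param hole_radius lateral clearance radius, nm (default 1.6).
#' @return the combined \code{edgepore_system} (model atoms appended last);
#'   the model's strand/edge tables are re-indexed via attribute
#'   \code{"edges"}.
#' @export
embed_model <- function(system, model, hole_radius = 1.6) {
  lx <- system$frame$box[1]; ly <- system$frame$box[2]
  shift <- c(lx / 2, ly / 2, 0)
  mxyz <- sweep(model$frame$coords, 2, -shift)
  lat <- sqrt(mi_delta(system$frame$coords[, 1] - shift[1], lx)^2 +
              mi_delta(system$frame$coords[, 2] - shift[2], ly)^2)
  drop_res <- unique(system$topology$residue_number[lat < hole_radius])
  keep <- !system$topology$residue_number %in% drop_res
  top0 <- system$topology[keep, ]
  xyz0 <- system$frame$coords[keep, , drop = FALSE]
  newtop <- rbind(top0, model$topology)
  class(newtop) <- class(system$topology)
  rownames(newtop) <- NULL
  newtop$atom_index <- seq_len(nrow(newtop)) - 1L
  offset <- nrow(top0)
  edges <- lapply(model$edges, function(e) {
    e2 <- edge_definition(e$label, e$atoms + offset, e$lateral_cutoff)
    attr(e2, "strand_labels") <- attr(e, "strand_labels")
    e2
  })
  out <- structure(list(topology = newtop,
                        frame = frame_snapshot(rbind(xyz0, mxyz),
                                               system$frame$box, 0),
                        spec = system$spec),
                   class = "edgepore_system")
  attr(out, "edges") <- edges
  attr(out, "model_atoms") <- offset + seq_len(nrow(model$topology))
  out
}

## place a point avoiding existing coordinates (min separation), with
## jittered retries; planted atoms never collide within 0.05 nm
place_clear <- function(target, existing, box, min_sep = 0.05, tries = 60,
                        fixed_z = TRUE) {
  p <- target
  for (k in seq_len(tries)) {
    if (!nrow(existing) ||
        min(mi_dist_point(p, existing, box)) >= min_sep) return(p)
    amp <- 0.04 + 0.01 * k          # widen the jitter on repeated collisions
    p <- target + stats::runif(3, -amp, amp)
    if (fixed_z) p[3] <- target[3]  # never move a planted atom off its slice
  }
  stop("placement collision: could not place planted atom near (",
       paste(signif(target, 3), collapse = ", "), ")")
}

#' Plant a polar defect column
#'
#' Adds one water oxygen at the z-centre of each listed slice.  With an edge
#' given, each planted atom sits laterally within 0.3 nm of the edge-strand
#' heavy atom nearest in z; otherwise the column stands at the lateral box
#' centre.  The resulting \code{frame_xi} is exactly
#' \code{length(filled_slices)/n_slices} (and likewise \code{edge_xi} for
#' the targeted edge) because the core holds no other polar atoms.
#'
#' @param system an \code{edgepore_system}.
#' @param filled_slices integer slice indices (1-based, within the grid).
#' @param grid slice grid (default 2.8 nm / 0.1 nm).
#' @param edge optional \code{edge_definition} (indices into the system
#'   topology) to anchor the column to.
#' @return the augmented \code{edgepore_system}.
#' @export
plant_edge_defect <- function(system, filled_slices,
                              grid = build_slice_grid(), edge = NULL) {
  if (!length(filled_slices)) return(system)
  if (any(filled_slices < 1 | filled_slices > grid$n_slices))
    stop("slice index outside grid (1..", grid$n_slices, ")")
  z0 <- -grid$slab_thickness / 2
  zc <- z0 + (filled_slices - 0.5) * grid$increment
  lx <- system$frame$box[1]; ly <- system$frame$box[2]
  pts <- matrix(0, length(zc), 3)
  for (k in seq_along(zc)) {
    if (is.null(edge)) {
      anchor <- c(lx / 2 + 0.2, ly / 2, zc[k])
    } else {
      exyz <- system$frame$coords[edge$atoms, , drop = FALSE]
      j <- which.min(abs(exyz[, 3] - zc[k]))
      anchor <- c(exyz[j, 1] + 0.12, exyz[j, 2] + 0.05, zc[k])
    }
    pts[k, ] <- place_clear(anchor,
                            rbind(system$frame$coords, pts[seq_len(k - 1), , drop = FALSE]),
                            system$frame$box)
  }
  n0 <- nrow(system$topology)
  addtop <- topology(name = rep("OW", nrow(pts)),
                     residue_name = rep("SOL", nrow(pts)),
                     residue_number = max(system$topology$residue_number) +
                       seq_len(nrow(pts)),
                     chain_id = "D",
                     atom_index = n0 + seq_len(nrow(pts)) - 1L)
  newtop <- rbind(system$topology, addtop)
  class(newtop) <- class(system$topology)
  rownames(newtop) <- NULL
  out <- system
  out$topology <- newtop
  out$frame <- frame_snapshot(rbind(system$frame$coords, pts),
                              system$frame$box, system$frame$time)
  attr(out, "edges") <- attr(system, "edges")
  out
}

## ---- idealized beta sheets -------------------------------------------------

## NeRF atom placement: position D bonded to C with |CD| = r, angle B-C-D =
## theta (deg), dihedral A-B-C-D = phi (deg)
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-bc * cos(th) + m * sin(th) * cos(ph) - n * sin(th) * sin(ph))
}

## build one extended strand: backbone N, CA, C, O, CB per residue with
## prescribed (phi, psi); returns list of per-residue atom coordinate lists
build_strand_backbone <- function(n_res, phi = -139, psi = 135) {
  bNCA <- 0.1458; bCAC <- 0.1525; bCN <- 0.1329
  aNCAC <- 111; aCACN <- 116.6; aCNCA <- 121.9
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  C[1, ] <- CA[1, ] + bCAC * c(-cos(aNCAC * pi / 180), sin(aNCAC * pi / 180), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCN, aCACN, psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bNCA, aCNCA, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], bCAC, aNCAC, phi)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 0.1231, 120.5, psi - 180)
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 0.153, 110.5, -120)
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

## rotate coordinates so the CA principal axis lies along +z, centred at 0
align_strand_z <- function(atoms) {
  ca <- atoms$CA
  ctr <- colMeans(ca)
  v <- svd(sweep(ca, 2, ctr))$v[, 1]
  if (v[3] < 0) v <- -v
  ## rotation taking v -> e_z (Rodrigues)
  ez <- c(0, 0, 1)
  axis <- c(v[2] * ez[3] - v[3] * ez[2],
            v[3] * ez[1] - v[1] * ez[3],
            v[1] * ez[2] - v[2] * ez[1])
  s <- sqrt(sum(axis^2)); cth <- sum(v * ez)
  R <- diag(3)
  if (s > 1e-12) {
    k <- axis / s
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(acos(max(-1, min(1, cth)))) * K +
      (1 - cth) * (K %*% K)
  }
  lapply(atoms, function(m) sweep(m, 2, ctr) %*% t(R))
}

DEFAULT_STRAND_RES <- c(beta1 = 13L, beta2 = 12L, beta3 = 13L)
DEFAULT_STRAND_START <- c(beta1 = 9L, beta2 = 29L, beta3 = 29L)

#' Build an idealized membrane-spanning beta sheet
#'
#' Backbone (N, CA, C, O, CB) strands with canonical extended-beta dihedrals
#' (phi = -139, psi = 135), aligned along z (membrane-spanning) and stacked
#' along y at \code{strand_spacing}; alternate strands are flipped when
#' \code{antiparallel}.  Strand labels map to template residue numbering:
#' beta1 = 9-21, beta2 = 29-40, beta3 = 29-41.  \code{beta_content} of the
#' result is 1 by construction and it superposes onto itself at RMSD 0.
#'
#' @param n_strands number of strands (>= 2).
#' @param strand_labels labels recycled over strands (default
#'   beta1/beta2/beta3 cyclically).
#' @param chains chain id per strand (default one chain per strand).
#' @param rise unused placeholder kept for API symmetry (the backbone
#'   geometry fixes the rise); reserved.
#' @param strand_spacing inter-strand spacing along y, nm (default 0.48).
#' @param antiparallel alternate strand directions (default TRUE).
#' @param residue_name residue type used for all residues (default "ALA").
#' @return an \code{oligomer_model}.
#' @export
make_ideal_sheet <- function(n_strands = 6,
                             strand_labels = NULL, chains = NULL,
                             rise = 0.34, strand_spacing = 0.48,
                             antiparallel = TRUE, residue_name = "ALA") {
  if (n_strands < 2) stop("need at least 2 strands")
  if (is.null(strand_labels))
    strand_labels <- rep(c("beta1", "beta2", "beta3"),
                         length.out = n_strands)
  if (is.null(chains)) chains <- LETTERS[seq_len(n_strands)]
  nm <- rn <- ch <- character(0); ri <- integer(0)
  xyz <- NULL
  strands <- data.frame(label = strand_labels, chain = chains,
                        res_start = NA_integer_, res_end = NA_integer_,
                        stringsAsFactors = FALSE)
  for (s in seq_len(n_strands)) {
    lab <- strand_labels[s]
    nres <- DEFAULT_STRAND_RES[[lab]]
    r0 <- DEFAULT_STRAND_START[[lab]]
    atoms <- align_strand_z(build_strand_backbone(nres))
    flip <- antiparallel && s %% 2 == 0
    place <- function(m) {
      if (flip) { m[, 1] <- -m[, 1]; m[, 3] <- -m[, 3] }
      m[, 2] <- m[, 2] + (s - 1) * strand_spacing
      m
    }
    for (i in seq_len(nres)) {
      for (an in c("N", "CA", "C", "O", "CB")) {
        xyz <- rbind(xyz, place(atoms[[an]])[i, ])
        nm <- c(nm, an); rn <- c(rn, residue_name)
        ri <- c(ri, r0 + i - 1L); ch <- c(ch, chains[s])
      }
    }
    strands$res_start[s] <- r0
    strands$res_end[s] <- r0 + nres - 1L
  }
  xyz <- sweep(xyz, 2, colMeans(xyz))
  top <- topology(name = nm, residue_name = rn, residue_number = ri,
                  chain_id = ch)
  oligomer_model(top, xyz, strands)
}

#' Idealized six-stranded tetramer sheet (template arrangement)
#'
#' Strand order beta1-beta2-beta3-beta3-beta2-beta1 across the sheet with
#' hairpin chains (A: beta1+beta2, B/C: beta3 core, D: beta2+beta1), the
#' arrangement of the solid-state-NMR tetramer fold this package's models
#' are patterned on.  Both sheet edges are beta1 strands.
#'
#' @param strand_spacing inter-strand spacing, nm.
#' @return an \code{oligomer_model} with 6 strands and 4 chains.
#' @export
ideal_tetramer_sheet <- function(strand_spacing = 0.48) {
  make_ideal_sheet(n_strands = 6,
                   strand_labels = c("beta1", "beta2", "beta3",
                                     "beta3", "beta2", "beta1"),
                   chains = c("A", "A", "B", "C", "D", "D"),
                   strand_spacing = strand_spacing)
}

## ---- scripted trajectories -------------------------------------------------

SHELL_TEMPLATE_ATOMS <- list(
  water_O = list(name = "OW", resname = "SOL"),
  lipid_O = list(name = "O22", resname = "POPC"),
  backbone_carbonyl_O_res9_21 = list(name = "O", resname = "ALA",
                                     residue = 10L),
  H13_sidechain = list(name = "ND1", resname = "HIS", residue = 13L),
  H14_sidechain = list(name = "ND1", resname = "HIS", residue = 14L),
  Q15_sidechain = list(name = "OE1", resname = "GLN", residue = 15L))

## near-uniform unit directions (golden spiral) for shell placement
sphere_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  th <- acos(1 - 2 * i / n)
  ph <- pi * (1 + sqrt(5)) * i
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Generate a scripted ion-permeation trajectory
#'
#' Each planned ion follows a prescribed z-path at a fixed lateral anchor,
#' carrying a co-moving first shell of planted partner atoms at 0.3 nm
#' (inside the 0.35 nm shell cutoff).  Base-system atoms within
#' \code{clear_radius} of any anchor are removed so the planted shell is the
#' exact shell: \code{shell_composition}, \code{coordination_profile} and
#' \code{crossing_events} recover the plan exactly.
#'
#' @param system an \code{edgepore_system}.
#' @param plan list of ion plans; each a list with \code{x}, \code{y}
#'   (lateral anchor, nm), \code{z} (numeric vector, one value per frame)
#'   and \code{shell} (named counts over the shell categories, e.g.
#'   \code{c(water_O = 5, Q15_sidechain = 1)}).  May be empty.
#' @param times frame times, ps (default \code{100 * seq_along(z) }).
#' @param clear_radius lateral clearance around each anchor, nm.
#' @return list: \code{traj} (an \code{edgepore_trajectory}, one replicate),
#'   \code{ion_rows} (row positions of the scripted ions), \code{plan}.
#' @export
make_permeation_series <- function(system, plan, times = NULL,
                                   clear_radius = 0.8) {
  box <- system$frame$box
  n_frames <- if (length(plan)) length(plan[[1]]$z) else
    if (!is.null(times)) length(times) else 5L
  if (is.null(times)) times <- 100 * (seq_len(n_frames) - 1)
  for (p in plan) {
    if (length(p$z) != n_frames)
      stop("all ion z-paths must share one frame count")
    if (any(abs(p$z) > box[3] / 2))
      stop("ion z-path leaves the box")
  }
  keep <- rep(TRUE, nrow(system$topology))
  for (p in plan) {
    lat <- sqrt(mi_delta(system$frame$coords[, 1] - p$x, box[1])^2 +
                mi_delta(system$frame$coords[, 2] - p$y, box[2])^2)
    keep <- keep & lat >= clear_radius
  }
  top0 <- system$topology[keep, ]
  xyz0 <- system$frame$coords[keep, , drop = FALSE]
  nm <- rn <- ch <- character(0); ri <- integer(0)
  res0 <- if (nrow(top0)) max(top0$residue_number) else 0L
  ion_rows <- integer(length(plan))
  shell_of <- vector("list", length(plan))
  for (k in seq_along(plan)) {
    p <- plan[[k]]
    ion_rows[k] <- nrow(top0) + length(nm) + 1L
    nm <- c(nm, "K"); rn <- c(rn, "K"); ch <- c(ch, "S")
    res0 <- res0 + 1L; ri <- c(ri, res0)
    shell <- p$shell[p$shell > 0]
    sh <- list()
    for (cat in names(shell)) {
      tmpl <- SHELL_TEMPLATE_ATOMS[[cat]]
      if (is.null(tmpl)) stop("unknown shell category '", cat, "'")
      for (j in seq_len(shell[[cat]])) {
        nm <- c(nm, tmpl$name); rn <- c(rn, tmpl$resname); ch <- c(ch, "S")
        if (is.null(tmpl$residue)) { res0 <- res0 + 1L; ri <- c(ri, res0) }
        else ri <- c(ri, tmpl$residue)
        sh[[length(sh) + 1L]] <- cat
      }
    }
    shell_of[k] <- list(unlist(sh))
  }
  if (length(nm)) {
    addtop <- topology(name = nm, residue_name = rn, residue_number = ri,
                       chain_id = ch, warn_unknown = FALSE)
    newtop <- rbind(top0, addtop)
  } else newtop <- top0
  class(newtop) <- class(system$topology)
  rownames(newtop) <- NULL
  newtop$atom_index <- seq_len(nrow(newtop)) - 1L
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    add <- NULL
    for (k in seq_along(plan)) {
      p <- plan[[k]]
      ion <- c(p$x, p$y, p$z[f])
      add <- rbind(add, ion)
      nsh <- length(shell_of[[k]])
      if (nsh) {
        dirs <- sphere_dirs(nsh)
        ## verify planted shell spacing (>= 0.05 nm)
        pts <- sweep(dirs * 0.3, 2, ion, `+`)
        if (nsh > 1 && min(stats::dist(pts)) < 0.05)
          stop("shell collision: too many shell atoms for one ion")
        add <- rbind(add, pts)
      }
    }
    coords <- rbind(xyz0, add)
    frames[[f]] <- frame_snapshot(coords, box, times[f])
  }
  traj <- trajectory_set(newtop, list(frames), stride = diff(times[1:2]),
                         discard = 0)
  list(traj = traj, ion_rows = ion_rows, plan = plan)
}

#' Generate a scripted contact trajectory
#'
#' Adds one probe lipid phosphorus atom that sits 0.3 nm from the first
#' heavy atom of \code{residue} on the listed frames and 3 nm away (lateral)
#' otherwise, so the planted per-residue contact frequency to the phosphate
#' category is exactly \code{length(contact_frames)/n_frames}.
#'
#' @param system an \code{edgepore_system} containing protein atoms.
#' @param residue target residue number.
#' @param n_frames frames per replicate.
#' @param contact_frames integer frame indices (1-based) in contact.
#' @param n_replicates number of identical replicates (default 1).
#' @return an \code{edgepore_trajectory} with attribute
#'   \code{"probe_row"}.
#' @export
make_contact_series <- function(system, residue, n_frames, contact_frames,
                                n_replicates = 1) {
  target <- atom_select(system$topology, role = "protein",
                        residue = residue, heavy = TRUE)
  if (!length(target)) stop("residue ", residue, " has no protein atoms")
  anchor <- system$frame$coords[target[1], ]
  n0 <- nrow(system$topology)
  addtop <- topology(name = "P", residue_name = "POPC",
                     residue_number = max(system$topology$residue_number) + 1L,
                     chain_id = "X", atom_index = n0)
  newtop <- rbind(system$topology, addtop)
  class(newtop) <- class(system$topology)
  rownames(newtop) <- NULL
  near <- anchor + c(0.3, 0, 0)
  far <- anchor + c(3, 0, 0)
  frames <- lapply(seq_len(n_frames), function(f) {
    probe <- if (f %in% contact_frames) near else far
    frame_snapshot(rbind(system$frame$coords, probe),
                   system$frame$box, time = (f - 1) * 100)
  })
  traj <- trajectory_set(newtop, rep(list(frames), n_replicates),
                         stride = 100, discard = 0)
  attr(traj, "probe_row") <- n0 + 1L
  traj
}
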