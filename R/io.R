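## Readers/writers for the two supported coordinate dialects:
##  - multi-MODEL PDB (Angstrom on disk, converted to nm in memory)
##  - frame_table: tab-separated atom_index name residue_name residue_number
##    chain role subrole x y z (nm), frames separated by
##    "#FRAME t=<ps> box=<lx> <ly> <lz>" header lines.

FRAME_TABLE_COLS <- c("atom_index", "name", "residue_name", "residue_number",
                      "chain", "role", "subrole", "x", "y", "z")

parse_pdb_lines <- function(lines, path = "<pdb>") {
  atom_mask <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  box <- c(10, 10, 10)
  cry <- which(startsWith(lines, "CRYST1"))
  if (length(cry)) {
    l <- lines[cry[1]]
    box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33))) / 10
    if (anyNA(box) || any(box <= 0)) box <- c(10, 10, 10)
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  atom_idx <- which(atom_mask)
  if (!length(atom_idx)) stop("no ATOM/HETATM records in ", path)
  if (length(model_starts) <= 1) {
    groups <- list(atom_idx)
  } else {
    grp <- findInterval(atom_idx, model_starts)
    groups <- split(atom_idx, grp)
  }
  parse_block <- function(rows) {
    ls <- lines[rows]
    bad <- nchar(ls) < 54
    if (any(bad))
      stop("unparseable PDB line ", rows[which(bad)[1]], " in ", path,
           ": too short for coordinate columns")
    x <- as.numeric(substr(ls, 31, 38))
    y <- as.numeric(substr(ls, 39, 46))
    z <- as.numeric(substr(ls, 47, 54))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("unparseable coordinates at PDB line ",
           rows[which(is.na(x + y + z))[1]], " in ", path)
    list(name = trimws(substr(ls, 13, 16)),
         resn = trimws(substr(ls, 18, 20)),
         resi = as.integer(trimws(substr(ls, 23, 26))),
         chain = substr(ls, 22, 22),
         elem = trimws(substr(ls, 77, 78)),
         coords = cbind(x, y, z) / 10)
  }
  first <- parse_block(groups[[1]])
  elem <- first$elem
  if (all(elem == "")) elem <- NULL else elem[elem == ""] <- guess_element(first$name[elem == ""])
  top <- topology(name = first$name, residue_name = first$resn,
                  residue_number = first$resi, chain_id = first$chain,
                  element = elem)
  frames <- vector("list", length(groups))
  frames[[1]] <- frame_snapshot(first$coords, box, time = 0)
  if (length(groups) > 1) {
    for (g in 2:length(groups)) {
      blk <- parse_block(groups[[g]])
      if (nrow(blk$coords) != nrow(top))
        stop("MODEL ", g, " in ", path, " has ", nrow(blk$coords),
             " atoms, expected ", nrow(top))
      frames[[g]] <- frame_snapshot(blk$coords, box, time = (g - 1))
    }
  }
  list(topology = top, frames = frames)
}

#' Write a structure (or trajectory) as multi-MODEL PDB
#'
#' Coordinates are written in Angstrom (internal nm times 10) with a CRYST1
#' record carrying the box.
#'
#' @param top topology.
#' @param frames a single \code{edgepore_frame} or list of frames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(top, frames, path) {
  if (inherits(frames, "edgepore_frame")) frames <- list(frames)
  box <- frames[[1]]$box * 10
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     box[1], box[2], box[3]), con)
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]$coords * 10
    rec <- ifelse(top$role == "protein", "ATOM", "HETATM")
    writeLines(sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       rec, (seq_len(nrow(top)) - 1L) %% 99999 + 1L,
                       substr(top$name, 1, 4), substr(top$residue_name, 1, 3),
                       substr(top$chain_id, 1, 1), top$residue_number %% 10000,
                       xyz[, 1], xyz[, 2], xyz[, 3], top$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in the frame_table dialect
#'
#' Tab-separated columns \code{atom_index name residue_name residue_number
#' chain role subrole x y z} (nm); each frame is preceded by a header line
#' \code{#FRAME t=<ps> box=<lx> <ly> <lz>}.  Coordinates are printed with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param top topology.
#' @param frames frame or list of frames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_frame_table <- function(top, frames, path) {
  if (inherits(frames, "edgepore_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("#FRAME t=%.17g box=%.17g %.17g %.17g",
                       f$time, f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%d\t%s\t%s\t%d\t%s\t%s\t%s\t%.17g\t%.17g\t%.17g",
                       top$atom_index, top$name, top$residue_name,
                       top$residue_number, top$chain_id, top$role,
                       top$subrole, f$coords[, 1], f$coords[, 2],
                       f$coords[, 3]), con)
  }
  invisible(path)
}

read_frame_table_file <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#FRAME"))
  if (!length(hdr)) stop("no #FRAME header in ", path)
  parse_hdr <- function(l) {
    t <- as.numeric(sub(".*t=([^ ]+).*", "\\1", l))
    bx <- as.numeric(strsplit(sub(".*box=", "", l), "[ \t]+")[[1]])
    if (is.na(t) || length(bx) != 3 || anyNA(bx))
      stop("unparseable #FRAME header: ", l)
    list(time = t, box = bx)
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  top <- NULL
  frames <- vector("list", length(hdr))
  for (g in seq_along(hdr)) {
    meta <- parse_hdr(lines[hdr[g]])
    body <- lines[(hdr[g] + 1L):ends[g]]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 10))
      stop("frame_table format error in ", path, " line ",
           hdr[g] + which(nf != 10)[1], ": expected 10 tab-separated fields")
    m <- matrix(unlist(parts), ncol = 10, byrow = TRUE)
    xyz <- cbind(as.numeric(m[, 8]), as.numeric(m[, 9]), as.numeric(m[, 10]))
    if (anyNA(xyz))
      stop("frame_table coordinate parse error in ", path, " frame ", g)
    if (is.null(top)) {
      top <- topology(name = m[, 2], residue_name = m[, 3],
                      residue_number = as.integer(m[, 4]), chain_id = m[, 5],
                      atom_index = as.integer(m[, 1]),
                      role = m[, 6], subrole = m[, 7], warn_unknown = FALSE)
    } else if (nrow(m) != nrow(top)) {
      stop("frame ", g, " in ", path, " has ", nrow(m), " atoms, expected ",
           nrow(top))
    }
    frames[[g]] <- frame_snapshot(xyz, meta$box, meta$time)
  }
  list(topology = top, frames = frames)
}

#' Read a single structure
#'
#' @param path file path.
#' @param dialect "pdb" or "frame_table".
#' @return list with \code{topology} and \code{frame} (the first frame).
#' @export
read_structure <- function(path, dialect = c("pdb", "frame_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- if (dialect == "pdb") parse_pdb_lines(readLines(path), path)
            else read_frame_table_file(path)
  list(topology = parsed$topology, frame = parsed$frames[[1]])
}

## equality check used to verify replicates share one topology
same_topology <- function(a, b) {
  cols <- c("name", "residue_name", "residue_number", "chain_id", "role",
            "subrole")
  if (nrow(a) != nrow(b)) return(FALSE)
  for (cl in cols) if (!identical(a[[cl]], b[[cl]])) return(FALSE)
  TRUE
}

first_topology_diff <- function(a, b) {
  if (nrow(a) != nrow(b)) return(sprintf("atom counts differ (%d vs %d)", nrow(a), nrow(b)))
  for (i in seq_len(nrow(a)))
    if (!identical(unlist(a[i, c(2, 4:8)]), unlist(b[i, c(2, 4:8)])))
      return(sprintf("atom %d (%s %s%d vs %s %s%d)", i,
                     a$name[i], a$residue_name[i], a$residue_number[i],
                     b$name[i], b$residue_name[i], b$residue_number[i]))
  "identical"
}

#' Read one or more trajectory files into a trajectory set
#'
#' Frames with \code{time < discard} are removed, the remainder subsampled to
#' \code{stride} (relative to the first retained frame); replicate order is
#' path order.  All files must share an identical topology.
#'
#' @param paths character vector of files, one replicate each.
#' @param stride sampling interval, ps.
#' @param discard initial span to drop, ps.
#' @param dialect "pdb" or "frame_table".
#' @return an \code{edgepore_trajectory}.
#' @export
read_trajectory <- function(paths, stride = 100, discard = 500000,
                            dialect = c("frame_table", "pdb")) {
  dialect <- match.arg(dialect)
  top <- NULL
  reps <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    parsed <- if (dialect == "pdb") parse_pdb_lines(readLines(paths[i]), paths[i])
              else read_frame_table_file(paths[i])
    if (is.null(top)) top <- parsed$topology
    else if (!same_topology(top, parsed$topology))
      stop("topology mismatch in ", paths[i], ": first difference at ",
           first_topology_diff(top, parsed$topology))
    frames <- parsed$frames
    times <- vapply(frames, function(f) f$time, 0)
    keep <- times >= discard
    if (!any(keep))
      stop("replicate ", paths[i], ": no frames remain after discarding ",
           discard, " ps (span ", max(times), " ps)")
    frames <- frames[keep]; times <- times[keep]
    if (stride > 0) {
      sel <- abs(((times - times[1]) %% stride)) < 1e-9
      frames <- frames[sel]
    }
    reps[[i]] <- frames
  }
  trajectory_set(top, reps, stride = stride, discard = discard)
}
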