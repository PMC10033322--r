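## Beta-sheet oligomer model construction: the model-identifier grammar
## (<SizeWord>-<k>pe-<composition>), rigid-body assembly of beta-sandwich
## models from a sheet template, and derivation of truncation isoforms by
## strand deletion.

SIZE_WORDS <- c(Di = 2L, Tri = 3L, Tetra = 4L, Penta = 5L, Hexa = 6L,
                Octa = 8L)

#' Parse an oligomer model identifier
#'
#' Identifiers take the form \code{<SizeWord>-<k>pe-<composition>}, e.g.
#' \code{"Penta-1pe-3.3.2"} (a pentamer with one side-by-side beta1-strand
#' pair edge and strand composition 3.3.2) or \code{"Tetra-0pe-2OTK"}
#' (template-derived composition code).  The composition digit order is kept
#' as given (the grammar does not fix which digit counts which strand class).
#'
#' @param text identifier string.
#' @return a \code{model_id} list: size_word, size, pair_edges, composition
#'   (integer vector) or template (string).
#' @export
parse_model_id <- function(text) {
  stopifnot(length(text) == 1, is.character(text))
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(parts) < 3)
    stop("malformed model id '", text,
         "': expected <SizeWord>-<k>pe-<composition>")
  size_word <- parts[1]
  if (!size_word %in% names(SIZE_WORDS))
    stop("malformed model id '", text, "': unknown size word '", size_word, "'")
  pe <- parts[2]
  if (!grepl("^[0-9]+pe$", pe))
    stop("malformed model id '", text, "': bad pair-edge token '", pe, "'")
  comp_text <- paste(parts[-(1:2)], collapse = "-")
  out <- list(size_word = size_word,
              size = unname(SIZE_WORDS[size_word]),
              pair_edges = as.integer(sub("pe$", "", pe)))
  segs <- strsplit(comp_text, ".", fixed = TRUE)[[1]]
  if (all(grepl("^[0-9]+$", segs))) {
    out$composition <- as.integer(segs)
    out$template <- NULL
  } else if (length(segs) == 1 && grepl("^[0-9A-Za-z]+$", segs)) {
    out$composition <- NULL
    out$template <- segs
  } else {
    stop("malformed model id '", text, "': bad composition token '",
         comp_text, "'")
  }
  structure(out, class = "model_id")
}

#' Format a model identifier
#'
#' Inverse of \code{\link{parse_model_id}}; parse-format is the identity on
#' well-formed identifiers.
#'
#' @param id a \code{model_id}.
#' @return identifier string.
#' @export
format_model_id <- function(id) {
  comp <- if (!is.null(id$composition)) paste(id$composition, collapse = ".")
          else id$template
  sprintf("%s-%dpe-%s", id$size_word, id$pair_edges, comp)
}

#' @export
print.model_id <- function(x, ...) {
  cat(sprintf("<model_id> %s (size %d, %d pair edge(s))\n",
              format_model_id(x), x$size, x$pair_edges))
  invisible(x)
}

#' Construct an oligomer model
#'
#' A labeled beta-sheet assembly: topology + coordinates, a strand table
#' (label in beta1/beta2/beta3, chain, residue span), and edge definitions
#' recomputed from the outermost strands.  In template numbering beta1 spans
#' residues within 9-21, beta2 within 29-40, beta3 within 29-41.
#'
#' @param top topology.
#' @param coords N x 3 coordinate matrix, nm.
#' @param strands data frame with columns label, chain, res_start, res_end.
#' @param model_id optional \code{model_id}.
#' @param box box lengths for the carrier frame (default 20 nm cube).
#' @return an \code{oligomer_model}.
#' @export
oligomer_model <- function(top, coords, strands, model_id = NULL,
                           box = c(20, 20, 20)) {
  stopifnot(nrow(coords) == nrow(top))
  bounds <- list(beta1 = c(9L, 21L), beta2 = c(29L, 40L), beta3 = c(29L, 41L))
  for (i in seq_len(nrow(strands))) {
    b <- bounds[[strands$label[i]]]
    if (is.null(b))
      stop("unknown strand label '", strands$label[i], "'")
    if (strands$res_start[i] < b[1] || strands$res_end[i] > b[2])
      stop("strand ", i, " (", strands$label[i], ") residue span ",
           strands$res_start[i], "-", strands$res_end[i],
           " outside template bounds ", b[1], "-", b[2])
  }
  m <- structure(list(topology = top,
                      frame = frame_snapshot(coords, box),
                      strands = strands, model_id = model_id),
                 class = "oligomer_model")
  m$edges <- compute_edges(m)
  m
}

#' @export
print.oligomer_model <- function(x, ...) {
  cat(sprintf("<oligomer_model> %d strands, %d chains, %d atoms%s\n",
              nrow(x$strands), length(unique(x$strands$chain)),
              nrow(x$topology),
              if (!is.null(x$model_id))
                paste0(" [", format_model_id(x$model_id), "]") else ""))
  for (e in x$edges)
    cat(sprintf("  edge %s: strands %s\n", e$label,
                paste(attr(e, "strand_labels"), collapse = "+")))
  invisible(x)
}

strand_atom_rows <- function(model, s) {
  st <- model$strands[s, ]
  atom_select(model$topology, chain = st$chain,
              residue = st$res_start:st$res_end, heavy = TRUE)
}

## Edges = outermost strands along the sheet stacking direction (y).
## Sheets/layers are separated along x; each edge collects, per layer, the
## strand closest to that y extreme, so a sandwich edge is a strand pair.
compute_edges <- function(model, lateral_cutoff = 1.0, layer_gap = 0.35) {
  ns <- nrow(model$strands)
  if (!ns) return(list())
  xm <- ym <- numeric(ns)
  for (s in seq_len(ns)) {
    rows <- strand_atom_rows(model, s)
    xm[s] <- mean(model$frame$coords[rows, 1])
    ym[s] <- mean(model$frame$coords[rows, 2])
  }
  ## group strands into layers by gaps in x
  ord <- order(xm)
  layer <- integer(ns); lid <- 1L; layer[ord[1]] <- 1L
  for (k in seq_along(ord)[-1]) {
    if (xm[ord[k]] - xm[ord[k - 1]] > layer_gap) lid <- lid + 1L
    layer[ord[k]] <- lid
  }
  pick <- function(side) {
    members <- integer(0)
    for (l in unique(layer)) {
      idx <- which(layer == l)
      members <- c(members,
                   idx[if (side == "lo") which.min(ym[idx]) else which.max(ym[idx])])
    }
    sort(members)
  }
  lo <- pick("lo"); hi <- pick("hi")
  mk <- function(members, label) {
    atoms <- sort(unlist(lapply(members, strand_atom_rows, model = model)))
    e <- edge_definition(label, atoms, lateral_cutoff)
    attr(e, "strands") <- members
    attr(e, "strand_labels") <- model$strands$label[members]
    e
  }
  list(edgeA = mk(lo, "edgeA"), edgeB = mk(hi, "edgeB"))
}

#' Count side-by-side beta1-strand pair edges of a model
#'
#' An edge counts as a beta1 pair edge when it consists of at least two
#' strands, all labeled beta1 (one from each sheet layer).
#'
#' @param model an \code{oligomer_model}.
#' @return integer count.
#' @export
count_beta1_pair_edges <- function(model) {
  sum(vapply(model$edges, function(e) {
    labs <- attr(e, "strand_labels")
    length(labs) >= 2 && all(labs == "beta1")
  }, TRUE))
}

#' Assemble a beta-sandwich from a sheet template
#'
#' Generates a second copy of the template by a rigid-body transform and
#' packs it against the first: \code{face_to_face_AP} rotates the copy 180
#' degrees about the membrane normal (z) before the lateral translation,
#' \code{face_to_back_P} translates only (preserving strand direction
#' vectors).  Copy chains are relabeled uniquely; a minimum inter-copy
#' heavy-atom distance below \code{clash_min} is an assembly error reporting
#' the closest pair.
#'
#' @param template an \code{oligomer_model} (a single sheet).
#' @param packing "face_to_face_AP" or "face_to_back_P".
#' @param offset lateral translation along x, nm (> 0).
#' @param clash_min minimum allowed inter-copy heavy-atom distance, nm.
#' @return an \code{oligomer_model} with twice the strands and chains.
#' @export
assemble_sandwich <- function(template,
                              packing = c("face_to_face_AP", "face_to_back_P"),
                              offset = 1.0, clash_min = 0.25) {
  packing <- match.arg(packing)
  if (offset <= 0) stop("offset must be > 0")
  xyz <- template$frame$coords
  copy <- xyz
  if (packing == "face_to_face_AP") {
    copy[, 1] <- -copy[, 1]
    copy[, 2] <- -copy[, 2]
  }
  copy[, 1] <- copy[, 1] + offset
  ## clash check between copies (plain euclidean; models live outside a box)
  h1 <- which(template$topology$element != "H")
  d <- mi_cross_dist(xyz[h1, , drop = FALSE], copy[h1, , drop = FALSE],
                     box = c(1e6, 1e6, 1e6))
  if (min(d) < clash_min) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "assembly clash: atoms %d and %d(copy) at %.3f nm (< %.2f nm)",
      h1[ij[1]], h1[ij[2]], min(d), clash_min))
  }
  top <- template$topology
  used <- unique(top$chain_id)
  avail <- setdiff(c(LETTERS, letters), used)
  if (length(avail) < length(used)) stop("too many chains to relabel")
  remap <- stats::setNames(avail[seq_along(used)], used)
  top2 <- top
  top2$chain_id <- unname(remap[top$chain_id])
  top2$atom_index <- top2$atom_index + max(top$atom_index) + 1L
  newtop <- rbind(top, top2)
  class(newtop) <- class(top)
  strands2 <- template$strands
  strands2$chain <- unname(remap[strands2$chain])
  oligomer_model(newtop, rbind(xyz, copy),
                 rbind(template$strands, strands2),
                 model_id = NULL, box = template$frame$box)
}

#' Delete strands from an oligomer model
#'
#' Atoms of the deleted strands are removed; chains that lose all their
#' strands are removed entirely; edges are recomputed from the new outermost
#' strands.  Requesting a strand that does not exist is an error (never a
#' silent no-op), as is deleting every strand.
#'
#' @param model an \code{oligomer_model}.
#' @param strands strand labels (e.g. "beta1", removing all strands with
#'   that label) or integer strand-table row indices.
#' @return the reduced \code{oligomer_model}.
#' @export
delete_strands <- function(model, strands) {
  tab <- model$strands
  if (is.character(strands)) {
    unknown <- setdiff(strands, tab$label)
    if (length(unknown))
      stop("no strand with label '", unknown[1], "' in model")
    idx <- which(tab$label %in% strands)
  } else {
    idx <- as.integer(strands)
    if (any(idx < 1 | idx > nrow(tab)))
      stop("strand index out of range: ", paste(idx[idx < 1 | idx > nrow(tab)],
                                                collapse = ", "))
  }
  if (length(idx) >= nrow(tab)) stop("cannot delete all strands of a model")
  drop_atoms <- sort(unique(unlist(lapply(idx, function(s) {
    st <- tab[s, ]
    atom_select(model$topology, chain = st$chain,
                residue = st$res_start:st$res_end)
  }))))
  keep_atoms <- setdiff(seq_len(nrow(model$topology)), drop_atoms)
  keep_tab <- tab[-idx, , drop = FALSE]
  ## drop chains that lost all strands
  dead_chains <- setdiff(unique(tab$chain[idx]), unique(keep_tab$chain))
  if (length(dead_chains))
    keep_atoms <- keep_atoms[!model$topology$chain_id[keep_atoms] %in% dead_chains]
  top <- model$topology[keep_atoms, ]
  class(top) <- class(model$topology)
  rownames(top) <- NULL
  rownames(keep_tab) <- NULL
  oligomer_model(top, model$frame$coords[keep_atoms, , drop = FALSE],
                 keep_tab, model_id = NULL, box = model$frame$box)
}

#' Write a model sidecar (strands + edges) as JSON
#'
#' The sidecar carries chain, residue range and label per strand, plus the
#' edge membership, for consumption by the defect module's edge definitions.
#'
#' @param model an \code{oligomer_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_sidecar <- function(model, path) {
  side <- list(
    model_id = if (!is.null(model$model_id)) format_model_id(model$model_id)
               else NA,
    strands = model$strands,
    edges = lapply(model$edges, function(e)
      list(label = e$label, lateral_cutoff = e$lateral_cutoff,
           strands = attr(e, "strands"),
           strand_labels = attr(e, "strand_labels"))))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model sidecar and rebuild edge definitions against a topology
#'
#' @param path sidecar JSON path.
#' @param top topology the edges should index into.
#' @return list with \code{strands} (data frame) and \code{edges} (named
#'   list of \code{edge_definition}s).
#' @export
read_model_sidecar <- function(path, top) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  strands <- as.data.frame(side$strands)
  edges <- lapply(side$edges, function(e) {
    members <- as.integer(e$strands)
    atoms <- sort(unique(unlist(lapply(members, function(s) {
      st <- strands[s, ]
      atom_select(top, chain = st$chain, residue = st$res_start:st$res_end,
                  heavy = TRUE)
    }))))
    ed <- edge_definition(e$label, atoms, e$lateral_cutoff)
    attr(ed, "strands") <- members
    attr(ed, "strand_labels") <- strands$label[members]
    ed
  })
  names(edges) <- vapply(edges, function(e) e$label, "")
  list(strands = strands, edges = edges)
}
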