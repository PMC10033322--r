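## Flat analysis configuration and end-to-end orchestration.  Every default
## constant of the analysis protocol lives here and nowhere else.

CONFIG_DEFAULTS <- list(
  slab_thickness = 2.8,        # nm, hydrophobic transmembrane slab
  slice_increment = 0.1,       # nm, defect slice thickness (28 slices)
  contact_cutoff = 0.5,        # nm, heavy-atom residue contacts
  shell_cutoff = 0.35,         # nm, ion first hydration shell
  temperature = 300,           # K, free-energy transforms
  stride = 100,                # ps between retained samples
  discard = 500000,            # ps of initial equilibration removed
  density_bin = 0.1,           # nm, axial profile bin width
  edge_lateral_cutoff = 1.0,   # nm, per-edge defect attribution
  bulk_window_lo = 2.5,        # nm, |z| bulk window for Boltzmann inversion
  bulk_window_hi = 3.5,
  pool_threshold_1 = 0.3,      # nm, pool I/II boundary
  pool_threshold_2 = 0.6,      # nm, pool II/III boundary (conduction limit)
  seed = 1
)

#' Analysis configuration
#'
#' A single flat document of every tunable constant, with defaults anchored
#' to the analysis protocol (2.8 nm slab in 0.1 nm slices, 0.5 nm contact
#' and 0.35 nm shell cutoffs, 300 K, 100 ps stride, 500 ns discard, 0.6 nm
#' conduction RMSD boundary).  Unknown fields are rejected.
#'
#' @param ... overrides of the defaults (see \code{config_defaults()}).
#' @return an \code{edgepore_config} list.
#' @export
edgepore_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over)
  lens <- c("slab_thickness", "slice_increment", "contact_cutoff",
            "shell_cutoff", "density_bin", "edge_lateral_cutoff")
  for (f in lens) if (cfg[[f]] <= 0) stop("config field ", f, " must be > 0")
  if (cfg$temperature <= 0) stop("temperature must be > 0")
  if (cfg$pool_threshold_2 <= cfg$pool_threshold_1)
    stop("pool thresholds must be strictly increasing")
  structure(cfg, class = "edgepore_config")
}

#' @export
print.edgepore_config <- function(x, ...) {
  cat("<edgepore_config>\n")
  for (f in names(CONFIG_DEFAULTS))
    cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Default configuration values
#' @return named list of defaults.
#' @export
config_defaults <- function() CONFIG_DEFAULTS

#' Write / read a configuration (lossless JSON round trip)
#'
#' @param cfg an \code{edgepore_config}.
#' @param path file path.
#' @return \code{path} / the configuration.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(edgepore_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

cfg_digest <- function(cfg) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

tsv_write <- function(df, path, cfg = NULL, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) writeLines(paste0("# units: ", units), con)
  if (!is.null(cfg)) writeLines(paste0("# config: ", cfg_digest(cfg)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Loads the trajectory manifest, computes the defect series and
#' distribution, density profiles, contact map, ion coordination profile,
#' crossing events, RMSD series and pool assignment, and writes one TSV per
#' stage plus a JSON run manifest (config digest, input hashes, package
#' version).  Identical inputs and config give byte-identical outputs; any
#' stage error aborts the run and removes partial outputs.
#'
#' @param config an \code{edgepore_config}.
#' @param manifest character vector of trajectory files (one replicate
#'   each), frame_table dialect.
#' @param out_dir output directory (created).
#' @param sidecar optional model sidecar JSON (enables per-edge defect
#'   output and the edge RMSD mask).
#' @param reference optional reference structure path (frame_table) for
#'   RMSD; default first frame of the first replicate.
#' @return invisible list of output paths.
#' @export
run_pipeline <- function(config, manifest, out_dir, sidecar = NULL,
                         reference = NULL) {
  if (!length(manifest)) stop("manifest lists no replicates")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "load"
  res <- try({
    traj <- read_trajectory(manifest, stride = config$stride,
                            discard = config$discard)
    top <- traj$topology
    edges <- NULL
    if (!is.null(sidecar))
      edges <- read_model_sidecar(sidecar, top)$edges
    grid <- build_slice_grid(config$slab_thickness, config$slice_increment)

    stage <- "defect"
    ds <- defect_series(traj, grid, edges = edges)
    p <- file.path(out_dir, "defect.tsv")
    tsv_write(ds, p, config, "xi dimensionless; time ps")
    written <- c(written, p)
    xi_by_rep <- split(ds$xi, ds$replicate)
    dist <- xi_free_energy(xi_distribution(xi_by_rep, grid$n_slices),
                           config$temperature)
    p <- file.path(out_dir, "distribution.tsv")
    tsv_write(dist, p, config, "p dimensionless; dG kJ/mol")
    written <- c(written, p)

    stage <- "density"
    dens_dir <- file.path(out_dir, "density")
    dir.create(dens_dir, showWarnings = FALSE)
    dens_sets <- list(
      water = atom_select(top, role = "water", subrole = "water_O"),
      polar_lipid = atom_select(top, role = "lipid", element = "O"),
      phosphate = atom_select(top, role = "lipid", subrole = "phosphate"),
      K = atom_select(top, role = "ion", subrole = "K"),
      Cl = atom_select(top, role = "ion", subrole = "Cl"))
    for (s in names(dens_sets)) {
      if (!length(dens_sets[[s]])) next
      prof <- partial_density(traj, dens_sets[[s]],
                              bin_width = config$density_bin)
      p <- file.path(dens_dir, paste0(s, ".tsv"))
      tsv_write(prof, p, config, "z nm; value atoms/nm^3")
      written <- c(written, p)
    }

    stage <- "contacts"
    prot_res <- sort(unique(top$residue_number[top$role == "protein"]))
    if (length(prot_res)) {
      cm <- contact_frequency(traj, prot_res, contact_partner_sets(top),
                              cutoff = config$contact_cutoff)
      p <- file.path(out_dir, "contacts.tsv")
      tsv_write(cm, p, config, "frequency dimensionless")
      written <- c(written, p)
    }

    stage <- "ions"
    kions <- atom_select(top, role = "ion", subrole = "K")
    if (length(kions)) {
      cp <- coordination_profile(traj, kions,
                                 bin_width = config$density_bin,
                                 cutoff = config$shell_cutoff)
      p <- file.path(out_dir, "coordination.tsv")
      tsv_write(cp, p, config, "z nm; value mean coordination")
      written <- c(written, p)
      ce <- crossing_events(traj, kions,
                            slab_halfwidth = config$slab_thickness / 2)
      p <- file.path(out_dir, "crossings.tsv")
      tsv_write(ce, p, config, "times ps")
      written <- c(written, p)
    }

    stage <- "rmsd"
    if (length(prot_res)) {
      ref <- if (!is.null(reference)) {
        rs <- read_structure(reference, "frame_table")
        rs$frame
      } else traj$replicates[[1]][[1]]
      mask <- if (!is.null(edges) && length(edges))
        sort(unique(intersect(unlist(lapply(edges, `[[`, "atoms")),
                              fit_mask(top))))
        else fit_mask(top)
      rs <- rmsd_series(traj, ref, mask)
      p <- file.path(out_dir, "rmsd.tsv")
      tsv_write(rs, p, config, "rmsd nm")
      written <- c(written, p)
      per_rep <- tapply(rs$rmsd_nm, rs$replicate, mean)
      pools <- pool_by_rmsd(as.numeric(per_rep),
                            c(config$pool_threshold_1, config$pool_threshold_2))
      pt <- data.frame(replicate = as.integer(names(per_rep)),
                       mean_rmsd_nm = as.numeric(per_rep),
                       pool = as.character(pools))
      p <- file.path(out_dir, "pools.tsv")
      tsv_write(pt, p, config, "rmsd nm; pool I/II/III")
      written <- c(written, p)
    }

    stage <- "manifest"
    run <- list(config = unclass(config), config_digest = cfg_digest(config),
                inputs = as.list(tools::md5sum(manifest)),
                outputs = basename(written),
                package_version = as.character(utils::packageVersion("edgepore")))
    p <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(run, p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    unlink(written)
    stop("pipeline aborted at stage '", stage, "': ",
         attr(res, "condition")$message)
  }
  message("pipeline complete: ", length(written), " outputs in ", out_dir)
  invisible(written)
}
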