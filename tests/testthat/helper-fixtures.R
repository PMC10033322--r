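# Shared fixtures: everything is generated in code at test time.

# small bilayer system (quietly cached per seed within a test run)
fix_system <- local({
  cache <- list()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_bilayer_system(synthetic_spec(seed = seed))
    cache[[key]]
  }
})

fix_sheet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ideal_tetramer_sheet()
    cache
  }
})

# bilayer with the tetramer sheet embedded (edges attached as attribute)
fix_embedded <- local({
  cache <- list()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- embed_model(fix_system(seed), fix_sheet())
    cache[[key]]
  }
})

# single-frame trajectory from a system
sys_traj <- function(sys, n_frames = 1, n_replicates = 1) {
  frames <- lapply(seq_len(n_frames) - 1, function(i) {
    f <- sys$frame; f$time <- i * 100; f
  })
  trajectory_set(sys$topology, rep(list(frames), n_replicates),
                 stride = 100, discard = 0)
}

# independent O(N^2) brute-force neighbour count (test-local oracle,
# deliberately not sharing code with the package's search)
oracle_count_within <- function(a, b, cutoff, box) {
  n <- nrow(a)
  out <- integer(n)
  for (i in seq_len(n)) {
    c2 <- 0L
    for (j in seq_len(nrow(b))) {
      d2 <- 0
      for (k in 1:3) {
        dk <- a[i, k] - b[j, k]
        dk <- dk - box[k] * round(dk / box[k])
        d2 <- d2 + dk * dk
      }
      if (sqrt(d2) <= cutoff) c2 <- c2 + 1L
    }
    out[i] <- c2
  }
  out
}

# brute-force xi oracle: per slice, scan all polar atoms by direct z test
oracle_xi <- function(frame, top, grid, polar, center) {
  z0 <- center - grid$slab_thickness / 2
  occupied <- 0
  for (s in seq_len(grid$n_slices)) {
    lo <- z0 + (s - 1) * grid$increment
    hi <- z0 + s * grid$increment
    hit <- FALSE
    for (i in polar) {
      z <- frame$coords[i, 3]
      if (z > lo && z <= hi) { hit <- TRUE; break }
    }
    if (hit) occupied <- occupied + 1
  }
  occupied / grid$n_slices
}

# tiny hand-built topology around a single ion, for shell tests
shell_fixture <- function(partners) {
  # partners: data.frame(name, resname, residue, x, y, z)
  nm <- c("K", partners$name)
  rn <- c("K", partners$resname)
  ri <- c(1L, partners$residue)
  top <- suppressWarnings(
    topology(nm, rn, ri, chain_id = "A", warn_unknown = FALSE))
  xyz <- rbind(c(0, 0, 0), as.matrix(partners[, c("x", "y", "z")]))
  list(top = top, frame = frame_snapshot(xyz + 5, c(10, 10, 10)))
}
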