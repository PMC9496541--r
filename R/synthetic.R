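# Synthetic test scenes: ground-truth C-alpha traces built from
# secondary-structure blocks, simulated density maps, noisy predicted
# contacts, and ideal fragments. Every other module is testable offline
# against these scenes, and every scene is reproducible from its seed.

#' Generate a ground-truth C-alpha trace from secondary-structure blocks
#'
#' Helices use a 1.5 A rise and 100 degree twist per residue, with the
#' radius derived so consecutive C-alpha are exactly 3.8 A apart
#' (2.28 A, the canonical alpha-helix geometry); strands are near-linear
#' zigzags with a 3.3 A rise; coils are self-avoiding 3.8 A random steps.
#' Blocks are connected with exact 3.8 A junctions, and the whole chain
#' is self-avoiding (no non-adjacent pair closer than 3.0 A).
#'
#' @param blocks data.frame with columns `type` ("helix", "strand",
#'   "coil") and `length` (residues), or a character shorthand like
#'   `c("helix:20", "coil:5")`.
#' @param rng_seed optional integer seed (uses the current RNG stream
#'   when NULL).
#' @param max_retries placement retries per block before giving up.
#' @return n x 3 coordinate matrix.
#' @export
make_structure <- function(blocks, rng_seed = NULL, max_retries = 500,
                           clearance = 6.5) {
  if (is.character(blocks)) {
    parts <- strsplit(blocks, ":")
    blocks <- data.frame(type = vapply(parts, `[[`, "", 1L),
                         length = as.integer(vapply(parts, `[[`, "", 2L)))
  }
  stopifnot(sum(blocks$length) >= 10L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  chain <- NULL
  for (b in seq_len(nrow(blocks))) {
    local <- switch(blocks$type[b],
                    helix = helix_block(blocks$length[b]),
                    strand = strand_block(blocks$length[b]),
                    coil = NULL,
                    stop("unknown block type: ", blocks$type[b]))
    # Sample several self-avoiding placements and keep the most compact
    # one (smallest mean distance to the existing chain centroid), so
    # chains collapse into globular folds with realistic long-range
    # contact counts rather than extended random arrangements.
    best <- NULL; best_score <- Inf; n_valid <- 0L
    for (try in seq_len(max_retries)) {
      cand <- if (is.null(local)) {
        place_coil(chain, blocks$length[b], clearance)
      } else {
        place_block(chain, local)
      }
      if (is.null(cand)) next
      if (!self_avoiding(rbind(chain, cand), clearance = clearance)) next
      n_valid <- n_valid + 1L
      score <- if (is.null(chain)) 0
               else mean(sqrt(rowSums(sweep(cand, 2L, colMeans(chain))^2)))
      if (score < best_score) { best <- cand; best_score <- score }
      if (n_valid >= 12L || is.null(chain)) break
    }
    if (is.null(best))
      stop("self-avoidance failure placing block ", b,
           " (", blocks$type[b], ":", blocks$length[b],
           "); try another rng_seed")
    chain <- rbind(chain, best)
  }
  chain
}

# canonical alpha-helix with exact 3.8 A consecutive spacing
helix_block <- function(len, rise = 1.5, twist = 100 * pi / 180) {
  chord <- sqrt(3.8^2 - rise^2)
  radius <- chord / (2 * sin(twist / 2))
  t <- seq_len(len) - 1
  cbind(radius * cos(t * twist), radius * sin(t * twist), t * rise)
}

# near-linear beta-strand zigzag with exact 3.8 A spacing
strand_block <- function(len, rise = 3.3) {
  perp <- sqrt(3.8^2 - rise^2)
  t <- seq_len(len) - 1
  cbind((t %% 2) * perp, rep(0, len), t * rise)
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  z <- random_unit()
  a <- random_unit()
  x <- a - sum(a * z) * z
  x <- x / sqrt(sum(x^2))
  cbind(x, pracma_cross(z, x), z)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotate a canonical block and attach its first bead 3.8 A from the chain end
place_block <- function(chain, local) {
  R <- random_rotation()
  rotated <- local %*% t(R)
  rotated <- sweep(rotated, 2L, rotated[1, ])
  start <- if (is.null(chain)) c(0, 0, 0) else chain[nrow(chain), ] + 3.8 * random_unit()
  sweep(rotated, 2L, start, "+")
}

# self-avoiding random walk with 3.8 A steps and directional persistence
place_coil <- function(chain, len, clearance = 6.5) {
  prev <- if (is.null(chain)) c(0, 0, 0) else chain[nrow(chain), ]
  dir <- random_unit()
  pts <- matrix(0, len, 3L)
  for (k in seq_len(len)) {
    ok <- FALSE
    for (try in 1:50) {
      d <- dir + 0.9 * random_unit()
      d <- d / sqrt(sum(d^2))
      p <- prev + 3.8 * d
      ref <- rbind(chain, if (k > 1) pts[seq_len(k - 1), , drop = FALSE])
      clash <- if (is.null(ref) || nrow(ref) == 0) FALSE else {
        dd <- sqrt(rowSums(sweep(ref, 2L, p)^2))
        sep <- nrow(ref) + 1L - seq_len(nrow(ref))
        any(dd[sep > 1] < 3.0) || any(dd[sep >= 6] < clearance)
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    pts[k, ] <- p
    prev <- p
    dir <- d
  }
  pts
}

# No non-adjacent pair closer than `min_dist`, and no sequence-distant
# pair (separation >= clearance_sep) closer than `clearance`: the first
# keeps the walk physical, the second keeps packed secondary-structure
# elements far enough apart (> ~6 A) that a map simulated at ~3 A
# resolution still resolves them, while their contacts stay inside the
# 8 A cutoff.
self_avoiding <- function(coords, min_dist = 3.0, clearance = 6.5,
                          clearance_sep = 6) {
  d <- as.matrix(dist(coords))
  sep <- abs(row(d) - col(d))
  all(d[sep > 1] >= min_dist) && all(d[sep >= clearance_sep] >= clearance)
}

#' Simulate a density map from C-alpha traces
#'
#' The map is a sum of isotropic Gaussians centered at each bead with
#' `sigma = resolution / (2 sqrt(2 ln 2))`, so the simulated FWHM equals
#' the nominal resolution. The grid is padded at least `pad` Angstrom
#' beyond the structure. Optional additive Gaussian noise is expressed as
#' a fraction of the peak density.
#'
#' @param chains list of n x 3 coordinate matrices (or a single matrix).
#' @param resolution nominal resolution (A); must be at least 2 voxels.
#' @param voxel grid spacing (A); 1.32 mirrors typical deposited maps.
#' @param noise_sd additive Gaussian noise, as a fraction of the peak.
#' @param pad grid padding beyond the structure (A).
#' @param name map identifier.
#' @return a [density_map()].
#' @export
simulate_map <- function(chains, resolution = 3.0, voxel = 1.32,
                         noise_sd = 0, pad = 5, name = "synthetic") {
  if (is.matrix(chains)) chains <- list(chains)
  beads <- do.call(rbind, chains)
  stopifnot(resolution >= 2 * voxel)
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  lo <- apply(beads, 2L, min) - pad
  hi <- apply(beads, 2L, max) + pad
  d <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  vals <- array(0, dim = d)
  reach <- 4 * sigma
  for (b in seq_len(nrow(beads))) {
    p <- beads[b, ]
    li <- pmax(1L, ceiling((p - reach - lo) / voxel) + 1L)
    hi_i <- pmin(d, floor((p + reach - lo) / voxel) + 1L)
    if (any(li > hi_i)) next
    ii <- li[1]:hi_i[1]; jj <- li[2]:hi_i[2]; kk <- li[3]:hi_i[3]
    gx <- exp(-((lo[1] + (ii - 1) * voxel) - p[1])^2 / (2 * sigma^2))
    gy <- exp(-((lo[2] + (jj - 1) * voxel) - p[2])^2 / (2 * sigma^2))
    gz <- exp(-((lo[3] + (kk - 1) * voxel) - p[3])^2 / (2 * sigma^2))
    vals[ii, jj, kk] <- vals[ii, jj, kk] + outer(outer(gx, gy), gz)
  }
  if (noise_sd > 0)
    vals <- vals + array(rnorm(length(vals), sd = noise_sd * max(vals)), dim = d)
  density_map(vals, voxel_size = voxel, origin = lo, name = name)
}

#' Emulate co-evolution contact predictions from a ground-truth trace
#'
#' True contacts (distance cutoff, minimum separation 5) are retained
#' independently with probability `sensitivity` and assigned confidence
#' values uniform in `[0.5, 1.0]`; false pairs are added at
#' `fp_rate x (number of true contacts)` with confidences uniform in
#' `[0.5, 0.7]`.
#'
#' @param coords n x 3 ground-truth C-alpha coordinates.
#' @param sensitivity fraction of true contacts kept.
#' @param fp_rate false positives as a fraction of the true contact
#'   count.
#' @param rng_seed optional integer seed.
#' @param cutoff,min_separation contact definition.
#' @return a [predicted_contacts()].
#' @export
make_predicted_contacts <- function(coords, sensitivity = 0.8, fp_rate = 0.05,
                                    rng_seed = NULL, cutoff = 8,
                                    min_separation = 5) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0, fp_rate <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(coords)
  true_cm <- contacts_from_coords(coords, cutoff = cutoff,
                                  min_separation = min_separation)
  keep <- runif(nrow(true_cm$pairs)) < sensitivity
  ti <- true_cm$pairs[keep, 1]; tj <- true_cm$pairs[keep, 2]
  tp <- runif(length(ti), 0.5, 1.0)
  n_fp <- round(fp_rate * nrow(true_cm$pairs))
  fi <- fj <- integer(0); fp <- numeric(0)
  if (n_fp > 0) {
    true_key <- paste(true_cm$pairs[, 1], true_cm$pairs[, 2])
    got <- 0L
    while (got < n_fp) {
      a <- sample.int(n, n_fp)
      b <- sample.int(n, n_fp)
      lo_ <- pmin(a, b); hi_ <- pmax(a, b)
      ok <- hi_ - lo_ >= min_separation &
        !(paste(lo_, hi_) %in% c(true_key, paste(fi, fj)))
      take <- which(ok)[seq_len(min(sum(ok), n_fp - got))]
      fi <- c(fi, lo_[take]); fj <- c(fj, hi_[take])
      got <- length(fi)
    }
    fp <- runif(n_fp, 0.5, 0.7)
  }
  predicted_contacts(n, c(ti, fi), c(tj, fj), c(tp, fp))
}

#' Cut a ground-truth trace into ideal fragments
#'
#' The trace is partitioned into consecutive fragments whose lengths are
#' drawn uniformly in `length_range`; coordinates are copied verbatim and
#' each fragment is stored in a random orientation (recorded in
#' `true_start` / `flipped`), mirroring reconstruction experiments with
#' perfect fragments.
#'
#' @param trace n x 3 ground-truth C-alpha coordinates.
#' @param length_range integer `c(min, max)` fragment length.
#' @param rng_seed optional integer seed.
#' @return list of `ca_fragment` with `true_start` (1-based index of the
#'   fragment's first bead in trace order) and `flipped` fields.
#' @export
make_ideal_fragments <- function(trace, length_range = c(10, 30),
                                 rng_seed = NULL) {
  stopifnot(length_range[2] >= length_range[1], length_range[1] >= 5)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- nrow(trace)
  lens <- integer(0)
  while (sum(lens) < n) {
    lens <- c(lens, sample(length_range[1]:length_range[2], 1L))
  }
  lens[length(lens)] <- n - sum(head(lens, -1))
  if (lens[length(lens)] < length_range[1] && length(lens) > 1L) {
    lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
    lens <- head(lens, -1)
  }
  starts <- cumsum(c(1L, head(lens, -1)))
  lapply(seq_along(lens), function(k) {
    idx <- starts[k]:(starts[k] + lens[k] - 1L)
    flip <- runif(1) < 0.5
    xyz <- trace[if (flip) rev(idx) else idx, , drop = FALSE]
    structure(list(xyz = xyz, id = k, true_start = starts[k], flipped = flip),
              class = "ca_fragment")
  })
}

#' Generate a complete synthetic scene
#'
#' Chains are built from a default helix/strand/coil block layout of
#' about `n_residues` residues each, translated apart so their densities
#' do not merge, blurred into a shared map, and given noisy predicted
#' contacts. The scene is bit-reproducible from (`params`, `rng_seed`).
#'
#' @param n_chains number of chains.
#' @param rng_seed integer seed.
#' @param resolution,voxel,noise_sd map simulation parameters.
#' @param sensitivity,fp_rate predicted-contact noise parameters.
#' @param blocks optional block layout (see [make_structure()]), either
#'   one layout shared by all chains or a list of per-chain layouts. The
#'   default cycles three distinct ~100-residue folds (helix-rich,
#'   strand-rich, alternating), so chains are distinguishable by their
#'   contact maps -- as the subunits of a real heteromer are.
#' @param chain_gap minimum bounding-box separation between chains (A);
#'   large enough that the blurred densities do not merge.
#' @return object of class `synthetic_scene`: `chains` (coordinate
#'   matrices), `sequences`, `map`, `predicted`
#'   ([predicted_contacts()] per chain), `params`.
#' @export
make_scene <- function(n_chains = 3, rng_seed = 0, resolution = 3.0,
                       voxel = 1.32, noise_sd = 0, sensitivity = 0.8,
                       fp_rate = 0.05, blocks = NULL, chain_gap = 16) {
  if (is.null(blocks))
    blocks <- default_layouts()
  if (!is.list(blocks)) blocks <- list(blocks)
  set.seed(rng_seed)
  chains <- list()
  offset <- 0
  for (k in seq_len(n_chains)) {
    layout <- blocks[[(k - 1L) %% length(blocks) + 1L]]
    ch <- NULL
    for (attempt in 1:20) {
      ch <- tryCatch(make_structure(layout), error = function(e) NULL)
      if (!is.null(ch)) break
    }
    if (is.null(ch))
      stop("could not build a self-avoiding chain for layout ", k,
           " with rng_seed ", rng_seed)
    ch <- sweep(ch, 2L, apply(ch, 2L, min))     # move to positive octant
    ch[, 1] <- ch[, 1] + offset
    offset <- max(ch[, 1]) + chain_gap
    chains[[k]] <- ch
  }
  names(chains) <- LETTERS[seq_len(n_chains)]
  sequences <- vapply(chains, function(ch)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                 nrow(ch), replace = TRUE), collapse = ""), "")
  predicted <- lapply(chains, make_predicted_contacts,
                      sensitivity = sensitivity, fp_rate = fp_rate)
  map <- simulate_map(chains, resolution = resolution, voxel = voxel,
                      noise_sd = noise_sd,
                      name = sprintf("scene_seed%d", rng_seed))
  structure(list(chains = chains, sequences = sequences, map = map,
                 predicted = predicted,
                 params = list(rng_seed = rng_seed, resolution = resolution,
                               voxel = voxel, noise_sd = noise_sd,
                               sensitivity = sensitivity, fp_rate = fp_rate,
                               blocks = blocks, chain_gap = chain_gap)),
            class = "synthetic_scene")
}

# three distinct ~100-residue folds so per-chain contact maps differ
default_layouts <- function() {
  list(c("helix:18", "coil:4", "helix:18", "coil:4", "strand:8",
         "coil:4", "helix:18", "coil:4", "helix:18", "coil:4"),
       c("strand:6", "coil:3", "strand:6", "coil:3", "helix:14", "coil:4",
         "strand:6", "coil:3", "strand:6", "coil:3", "helix:14", "coil:4",
         "strand:6", "coil:3", "strand:6", "coil:3", "helix:10"),
       c("helix:10", "coil:3", "strand:7", "coil:3", "helix:10", "coil:3",
         "strand:7", "coil:3", "helix:10", "coil:3", "strand:7", "coil:3",
         "helix:10", "coil:3", "strand:7", "coil:3", "helix:8"))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d chains (%s residues), %.1f A map, seed %d\n",
              length(x$chains),
              paste(vapply(x$chains, nrow, 1L), collapse = "/"),
              x$params$resolution, x$params$rng_seed))
  invisible(x)
}

#' Write a scene to disk in the pipeline's input dialects
#'
#' Emits the MRC map, per-chain ground-truth CA-only PDB files, RR
#' contact files, a FASTA of the chain sequences, and a JSON manifest.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mrc(scene$map, file.path(dir, "map.mrc"))
  for (k in seq_along(scene$chains)) {
    id <- names(scene$chains)[k]
    xyz <- scene$chains[[k]]
    writeLines(c(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), id, seq_len(nrow(xyz)),
      xyz[, 1], xyz[, 2], xyz[, 3]), "END"),
      file.path(dir, sprintf("truth_%s.pdb", id)))
    pc <- scene$predicted[[k]]
    writeLines(c("PFRMAT RR",
                 sprintf("%d %d 0 8 %.4f", pc$entries$i, pc$entries$j,
                         pc$entries$prob), "END"),
               file.path(dir, sprintf("contacts_%s.rr", id)))
  }
  writeLines(unlist(lapply(names(scene$sequences), function(id)
    c(paste0(">", id), scene$sequences[[id]]))),
    file.path(dir, "sequences.fasta"))
  jsonlite::write_json(scene$params, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
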