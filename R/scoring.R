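# Model-quality diagnostics: a sliding-window contact-overlap profile
# (which predicted contacts does the model satisfy, locally?), the
# segment Manders' overlap coefficient (local map-model density fit), and
# C-alpha deviation / RMSD against a reference structure.

#' Windowed contact-overlap profile
#'
#' For each residue r, the predicted contacts with at least one endpoint
#' inside the window `[r - w, r + w]` (w = (window-1)/2) are collected;
#' the value at r is the fraction of those present in the model's contact
#' map, or NA when no predicted contact touches the window.
#'
#' @param model_cm,predicted_cm [contact_map()] objects on the same
#'   residue scale.
#' @param window odd window size in residues.
#' @param endpoint_rule `"any"` (default) counts contacts with at least
#'   one endpoint in the window; `"both"` requires both.
#' @return numeric vector of length n (NA where undefined), with
#'   attribute `window`.
#' @export
windowed_overlap <- function(model_cm, predicted_cm, window = 11,
                             endpoint_rule = c("any", "both")) {
  endpoint_rule <- match.arg(endpoint_rule)
  if (model_cm$n != predicted_cm$n)
    stop("contact maps have different residue counts")
  if (window %% 2 == 0) stop("window must be odd")
  n <- predicted_cm$n
  w <- (window - 1) / 2
  p <- predicted_cm$pairs
  in_model <- if (nrow(p) > 0)
    paste(p[, 1], p[, 2]) %in% paste(model_cm$pairs[, 1], model_cm$pairs[, 2])
  else logical(0)
  vapply(seq_len(n), function(r) {
    if (nrow(p) == 0) return(NA_real_)
    ini <- abs(p[, 1] - r) <= w
    inj <- abs(p[, 2] - r) <= w
    sel <- if (endpoint_rule == "any") ini | inj else ini & inj
    if (!any(sel)) return(NA_real_)
    mean(in_model[sel])
  }, 0)
}

#' Segment Manders' overlap coefficient (SMOC) profile
#'
#' For each residue r, the density of the `window`-residue segment around
#' r is simulated on the experimental grid (an isotropic Gaussian at each
#' bead with `sigma = sim_resolution / (2 sqrt(2 ln 2))`, i.e. FWHM equal
#' to the nominal resolution) and compared with the experimental density
#' over the segment footprint (voxels within 3 sigma of any segment
#' bead) by Manders' overlap coefficient
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, with experimental negatives
#' clamped to zero. Scale-invariant in the experimental map.
#'
#' @param model_xyz n x 3 registered C-alpha positions (NA rows allowed).
#' @param map a [density_map()].
#' @param window odd window size in residues.
#' @param sim_resolution simulated resolution (A).
#' @param resid residue index per row of `model_xyz` (defaults to row
#'   number); windows slide over this index.
#' @return numeric vector over `sort(unique(resid))` positions (NA where
#'   the footprint is empty), with attribute `resid`.
#' @export
smoc <- function(model_xyz, map, window = 11, sim_resolution = 3.0,
                 resid = NULL) {
  model_xyz <- matrix(as.numeric(model_xyz), ncol = 3L)
  if (is.null(resid)) resid <- seq_len(nrow(model_xyz))
  if (window %% 2 == 0) stop("window must be odd")
  sigma <- sim_resolution / (2 * sqrt(2 * log(2)))
  w <- (window - 1) / 2
  rs <- sort(unique(resid))
  xexp <- pmax(map$values, 0)
  vals <- vapply(rs, function(r) {
    sel <- which(abs(resid - r) <= w & stats::complete.cases(model_xyz))
    if (length(sel) == 0L) return(NA_real_)
    fp <- gaussian_footprint(model_xyz[sel, , drop = FALSE], map, sigma)
    if (length(fp$vox) == 0L) return(NA_real_)
    x <- xexp[fp$vox]
    y <- fp$sim
    den <- sqrt(sum(x^2) * sum(y^2))
    if (den == 0) return(NA_real_)
    sum(x * y) / den
  }, 0)
  attr(vals, "resid") <- rs
  vals
}

# voxels within 3*sigma of any bead, plus the simulated Gaussian density
gaussian_footprint <- function(beads, map, sigma) {
  d <- dim(map$values)
  reach <- 3 * sigma
  sim <- numeric(0)
  vox_all <- integer(0)
  for (b in seq_len(nrow(beads))) {
    p <- beads[b, ]
    lo <- pmax(1L, ceiling((p - reach - map$origin) / map$voxel_size) + 1L)
    hi <- pmin(d, floor((p + reach - map$origin) / map$voxel_size) + 1L)
    if (any(lo > hi)) next
    g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
    xyz <- grid_to_xyz(map, g)
    r2 <- rowSums(sweep(xyz, 2L, p, "-")^2)
    keep <- r2 <= reach^2
    if (!any(keep)) next
    vox <- (g[keep, 3] - 1L) * d[1] * d[2] + (g[keep, 2] - 1L) * d[1] + g[keep, 1]
    val <- exp(-r2[keep] / (2 * sigma^2))
    m <- match(vox, vox_all)
    new <- is.na(m)
    if (any(new)) {
      vox_all <- c(vox_all, vox[new])
      sim <- c(sim, val[new])
    }
    if (any(!new)) sim[m[!new]] <- sim[m[!new]] + val[!new]
  }
  list(vox = vox_all, sim = sim)
}

#' Per-residue C-alpha deviation against a reference
#'
#' Registered model beads are paired with the reference C-alpha carrying
#' the same residue label; the profile is the Euclidean distance per
#' registered residue and the summary is the mean over registered
#' residues.
#'
#' @param chain a `chain_model` with a register (see
#'   [register_sequence()]).
#' @param ref_xyz m x 3 reference C-alpha coordinates.
#' @param ref_resid residue number per reference row.
#' @param superpose if TRUE, the model is rigidly superposed onto the
#'   reference (Kabsch) over the common residues before measuring.
#' @return list with `profile` (data.frame resid, deviation) and `mean`.
#' @export
ca_deviation <- function(chain, ref_xyz, ref_resid = seq_len(nrow(ref_xyz)),
                         superpose = FALSE) {
  if (is.null(chain$register)) stop("chain has no register; run register_sequence first")
  real <- which(stats::complete.cases(chain$coords))
  mod_xyz <- chain$coords[real, , drop = FALSE]
  reg <- chain$register
  ok <- !is.na(reg) & reg %in% ref_resid
  if (!any(ok)) stop("no residues in common between model register and reference")
  m <- mod_xyz[ok, , drop = FALSE]
  r <- ref_xyz[match(reg[ok], ref_resid), , drop = FALSE]
  if (superpose) m <- kabsch_superpose(m, r)
  dev <- sqrt(rowSums((m - r)^2))
  list(profile = data.frame(resid = reg[ok], deviation = dev),
       mean = mean(dev))
}

# least-squares rigid superposition of x onto y
kabsch_superpose <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2L, cx); y0 <- sweep(y, 2L, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(x0 %*% t(R), 2L, cy, "+")
}

#' Register-free fragment accuracy
#'
#' For every fragment bead, the distance to the nearest reference
#' C-alpha; the accuracy is the root mean square over all beads.
#' Fragments carry no register, so the pairing is nearest-neighbor.
#'
#' @param fragments list of `ca_fragment`.
#' @param ref_xyz m x 3 reference C-alpha coordinates.
#' @return RMS nearest-neighbor distance (A), with per-bead distances as
#'   attribute `dists`.
#' @export
fragment_accuracy <- function(fragments, ref_xyz) {
  stopifnot(length(fragments) >= 1L)
  beads <- do.call(rbind, lapply(fragments, `[[`, "xyz"))
  nn <- cpp_nearest(beads, matrix(as.numeric(ref_xyz), ncol = 3L))
  out <- sqrt(mean(nn$dist^2))
  attr(out, "dists") <- nn$dist
  out
}

#' Write a per-residue profile as TSV
#'
#' @param values numeric profile (e.g. from [windowed_overlap()] or
#'   [smoc()]).
#' @param path output path.
#' @param chain chain identifier written in the first column.
#' @param resid residue indices (defaults to `attr(values, "resid")` or
#'   position).
#' @return `path`, invisibly.
#' @export
write_profile <- function(values, path, chain = "A", resid = NULL) {
  if (is.null(resid)) resid <- attr(values, "resid")
  if (is.null(resid)) resid <- seq_along(values)
  write.table(data.frame(chain = chain, resid = resid, value = as.numeric(values)),
              path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
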