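# Density-weighted grid graph and its minimum spanning tree: the map
# skeletonization stage. High-density voxels become vertices, 26-neighbor
# pairs become edges weighted by the inverse density product, so the MST
# hugs the density ridges (the putative backbone).

#' Edge weight between two density values
#'
#' The weight of the grid-graph edge joining voxels of density `d_i` and
#' `d_j` is the inverse of the product of the two densities, so paths
#' through high density are cheap.
#'
#' @param d_i,d_j positive density values (vectorized).
#' @return `1 / (d_i * d_j)`.
#' @export
edge_weight <- function(d_i, d_j) {
  if (any(d_i <= 0) || any(d_j <= 0))
    stop("edge_weight is undefined for non-positive densities; ",
         "threshold the map before building the graph")
  1 / (d_i * d_j)
}

#' Build the weighted 26-neighbor grid graph of a density map
#'
#' Voxels with density strictly above `density_threshold` become vertices;
#' every pair of retained voxels whose grid indices differ by at most one
#' along each axis becomes an edge, weighted by [edge_weight()].
#'
#' @param map a [density_map()].
#' @param density_threshold vertex inclusion threshold (map units). See
#'   [auto_threshold()] for the volume heuristic.
#' @return An object of class `grid_graph` with elements `ijk` (n x 3
#'   grid indices), `xyz` (n x 3 Angstrom coordinates), `density`,
#'   `edges` (m x 2 vertex indices, lexicographic), `weights`, and the
#'   originating map metadata.
#' @export
build_grid_graph <- function(map, density_threshold) {
  d <- dim(map$values)
  keep <- which(map$values > density_threshold)   # linear indices, grid order
  if (length(keep) == 0L)
    stop("no voxel exceeds density_threshold = ", density_threshold,
         "; lower the threshold")
  ijk <- arrayInd(keep, d)
  n <- length(keep)
  vid <- array(0L, dim = d)
  vid[keep] <- seq_len(n)
  dens <- map$values[keep]

  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[offsets %*% c(1, 3, 9) > 0, , drop = FALSE] # 13 half-space
  ei <- ej <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    nb <- sweep(ijk, 2L, offsets[o, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
          nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    j <- integer(n)
    j[ok] <- vid[nb[ok, , drop = FALSE]]
    hit <- which(j > 0L)
    ei[[o]] <- hit
    ej[[o]] <- j[hit]
  }
  ei <- unlist(ei); ej <- unlist(ej)
  edges <- cbind(pmin(ei, ej), pmax(ei, ej))
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  structure(
    list(ijk = ijk, xyz = grid_to_xyz(map, ijk), density = dens,
         edges = edges, weights = edge_weight(dens[edges[, 1]], dens[edges[, 2]]),
         dim = d, voxel_size = map$voxel_size, origin = map$origin,
         threshold = density_threshold, name = map$name),
    class = "grid_graph")
}

#' @export
print.grid_graph <- function(x, ...) {
  cat(sprintf("<grid_graph '%s'> %d vertices, %d edges (threshold %.4g)\n",
              x$name, nrow(x$ijk), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Density threshold from the expected protein volume
#'
#' The deposited contour level of a map is rarely known, so the default
#' threshold retains a voxel volume of about `volume_factor` times the
#' expected protein volume (1.21 A^3 per Dalton of sequence mass,
#' approximated as 110 Da per residue when only residue counts are known).
#'
#' @param map a [density_map()].
#' @param n_residues total residue count over all chains in the map.
#' @param volume_factor retained volume / expected protein volume.
#' @return a density threshold (map units).
#' @export
auto_threshold <- function(map, n_residues, volume_factor = 1.5) {
  target_vol <- volume_factor * 1.21 * 110 * n_residues     # A^3
  n_keep <- min(length(map$values) - 1,
                max(2, round(target_vol / prod(map$voxel_size))))
  frac <- n_keep / length(map$values)
  as.numeric(quantile(map$values, probs = 1 - frac, names = FALSE))
}

#' Minimum spanning forest by Kruskal's algorithm
#'
#' Edges are taken in increasing weight; equal weights are broken by the
#' lexicographic order of the endpoint indices so the tree is
#' bit-reproducible. One tree is produced per connected component.
#'
#' @param graph a `grid_graph` (or any list with `edges`, `weights`,
#'   `xyz`, `density`).
#' @return An object of class `spanning_tree`: the input vertices plus the
#'   selected `edges` (and their `weights`).
#' @export
kruskal_mst <- function(graph) {
  n <- nrow(graph$xyz)
  if (n < 1L) stop("graph has no vertices")
  e <- graph$edges
  ord <- order(graph$weights, e[, 1], e[, 2])
  e <- e[ord, , drop = FALSE]
  w <- graph$weights[ord]
  keep <- cpp_kruskal_keep(n, e[, 1], e[, 2])
  structure(
    list(xyz = graph$xyz, ijk = graph$ijk, density = graph$density,
         edges = e[keep, , drop = FALSE], weights = w[keep],
         name = graph$name),
    class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree '%s'> %d vertices, %d edges, total weight %.6g\n",
              x$name, nrow(x$xyz), nrow(x$edges), sum(x$weights)))
  invisible(x)
}

#' Prune a spanning forest to maximum vertex degree three
#'
#' A C-alpha is covalently bonded to at most three non-hydrogen atoms, so
#' the skeleton is cleaned until no vertex has more than three incident
#' edges. At each over-degree vertex, whole incident branches are removed,
#' smallest first (by vertex count, then summed density, then smallest
#' vertex index), never interior edges of kept paths.
#'
#' @param tree a `spanning_tree`.
#' @return a `spanning_tree` with maximum degree 3; vertices are
#'   re-indexed compactly.
#' @export
prune_to_degree3 <- function(tree) {
  n <- nrow(tree$xyz)
  if (nrow(tree$edges) == 0L) return(tree)
  keep <- cpp_prune_degree3(n, tree$edges[, 1], tree$edges[, 2], tree$density)
  subset_tree(tree, keep)
}

# keep a vertex subset of a spanning forest, dropping dangling edges
subset_tree <- function(tree, keep) {
  newid <- integer(nrow(tree$xyz))
  newid[keep] <- seq_len(sum(keep))
  e <- tree$edges
  ekeep <- keep[e[, 1]] & keep[e[, 2]]
  structure(
    list(xyz = tree$xyz[keep, , drop = FALSE],
         ijk = if (!is.null(tree$ijk)) tree$ijk[keep, , drop = FALSE],
         density = tree$density[keep],
         edges = cbind(newid[e[ekeep, 1]], newid[e[ekeep, 2]]),
         weights = tree$weights[ekeep],
         name = tree$name),
    class = "spanning_tree")
}

#' Split a forest into connected components
#'
#' Components with fewer than `min_vertices` vertices are treated as noise
#' and discarded.
#'
#' @param tree a `spanning_tree`.
#' @param min_vertices minimum component size to keep.
#' @return list of `spanning_tree` objects, largest first.
#' @export
tree_components <- function(tree, min_vertices = 10) {
  n <- nrow(tree$xyz)
  comp <- component_labels(n, tree$edges)
  sizes <- tabulate(comp)
  ids <- order(sizes, decreasing = TRUE)
  ids <- ids[sizes[ids] >= min_vertices]
  lapply(ids, function(k) subset_tree(tree, comp == k))
}

# connected-component labels from an edge list (vectorized label sweep)
component_labels <- function(n, edges) {
  lab <- seq_len(n)
  if (nrow(edges) > 0L) repeat {
    l1 <- pmin(lab[edges[, 1]], lab[edges[, 2]])
    changed <- FALSE
    for (col in 1:2) {
      m <- tapply(l1, edges[, col], min)
      idx <- as.integer(names(m))
      upd <- lab[idx] > m
      if (any(upd)) { lab[idx[upd]] <- m[upd]; changed <- TRUE }
    }
    # propagate label of label
    repeat {
      l2 <- lab[lab]
      if (identical(l2, lab)) break
      lab <- l2; changed <- TRUE
    }
    if (!changed) break
  }
  match(lab, sort(unique(lab)))
}

#' Write a spanning tree as pseudo-atom PDB with CONECT records
#'
#' @param tree a `spanning_tree`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_tree_pdb <- function(tree, path) {
  n <- nrow(tree$xyz)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000, seq_len(n) %% 10000,
    tree$xyz[, 1], tree$xyz[, 2], tree$xyz[, 3])
  con <- sprintf("CONECT%5d%5d", tree$edges[, 1] %% 100000,
                 tree$edges[, 2] %% 100000)
  writeLines(c(lines, con, "END"), path)
  invisible(path)
}

#' Write a forest's edge list as text
#'
#' Columns: vertex indices `i j`, endpoint coordinates, edge weight.
#'
#' @param tree a `spanning_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_edges <- function(tree, path) {
  df <- data.frame(i = tree$edges[, 1], j = tree$edges[, 2],
                   xi = tree$xyz[tree$edges[, 1], 1],
                   yi = tree$xyz[tree$edges[, 1], 2],
                   zi = tree$xyz[tree$edges[, 1], 3],
                   xj = tree$xyz[tree$edges[, 2], 1],
                   yj = tree$xyz[tree$edges[, 2], 2],
                   zj = tree$xyz[tree$edges[, 2], 3],
                   weight = tree$weights)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
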