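test_that("edge weight is the inverse density product and rejects d <= 0", {
  expect_equal(edge_weight(2.0, 4.0), 0.125)
  expect_equal(edge_weight(1.0, 1.0), 1.0)
  expect_error(edge_weight(0.0, 3.0), "non-positive")
  expect_error(edge_weight(2.0, -1.0), "non-positive")
})

test_that("grid graph vertices and 26-neighbor edges follow the threshold", {
  m <- density_map(array(5, dim = c(2, 2, 2)), voxel_size = 1)
  # 2x2x1 slab: 4 surviving voxels form K4 in the 26-neighborhood
  m$values[, , 2] <- 0
  g <- build_grid_graph(m, 1)
  expect_equal(nrow(g$ijk), 4L)
  expect_equal(nrow(g$edges), 6L)

  # 3-voxel line with a weak middle voxel: ends are not neighbors
  vals <- array(0, dim = c(3, 2, 2))
  vals[, 1, 1] <- c(5, 0.01, 5)
  line <- density_map(vals, voxel_size = 1)
  g2 <- build_grid_graph(line, 1)
  expect_equal(nrow(g2$ijk), 2L)
  expect_equal(nrow(g2$edges), 0L)

  expect_error(build_grid_graph(line, 100), "lower the threshold")
})

test_that("edge set equals brute-force neighbor enumeration on random grids", {
  set.seed(1)
  for (rep in 1:5) {
    vals <- array(runif(64), dim = c(4, 4, 4))
    m <- density_map(vals, voxel_size = 1.5)
    thr <- 0.4
    g <- build_grid_graph(m, thr)
    keep <- which(vals > thr)
    ijk <- arrayInd(keep, c(4, 4, 4))
    cnt <- 0L
    if (length(keep) >= 2) {
      for (a in seq_len(nrow(ijk) - 1)) {
        for (b in (a + 1):nrow(ijk)) {
          if (all(abs(ijk[a, ] - ijk[b, ]) <= 1)) cnt <- cnt + 1L
        }
      }
    }
    expect_equal(nrow(g$edges), cnt)
    expect_true(all(g$weights > 0))
    # weights recomputed from endpoint densities
    expect_equal(g$weights,
                 1 / (g$density[g$edges[, 1]] * g$density[g$edges[, 2]]))
  }
})

test_that("raising the threshold never adds vertices", {
  set.seed(2)
  m <- density_map(array(runif(125), dim = c(5, 5, 5)), voxel_size = 1)
  thresholds <- c(0.1, 0.3, 0.5, 0.7)
  sizes <- vapply(thresholds, function(t)
    nrow(build_grid_graph(m, t)$ijk), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("Kruskal recovers the enumerated minimum on a K4 with known densities", {
  # densities a=1,b=2,c=3,d=4 on a 2x2x1 slab: weights ab=1/2, ac=1/3,
  # ad=1/4, bc=1/6, bd=1/8, cd=1/12
  m <- density_map(array(c(1, 2, 3, 4, 0, 0, 0, 0), dim = c(2, 2, 2)),
                   voxel_size = 1)
  g <- build_grid_graph(m, 0.5)
  t <- kruskal_mst(g)
  expect_equal(nrow(t$edges), 3L)
  expect_equal(sum(t$weights), 11 / 24, tolerance = 1e-12)
  # the chosen edges are cd, bd, ad (vertices in grid order a=1,b=2,c=3,d=4)
  got <- apply(t$edges, 1, paste, collapse = "-")
  expect_setequal(got, c("3-4", "2-4", "1-4"))
  # and enumeration agrees
  expect_equal(sum(t$weights), oracle_mst_weight(4, g$edges, g$weights))
})

test_that("a tree-shaped graph is its own minimum spanning tree", {
  set.seed(3)
  n <- 9
  edges <- rand_tree_deg3(n)
  g <- as_grid_graph(list(n = n, edges = edges,
                          weights = runif(nrow(edges), 1, 5)))
  t <- kruskal_mst(g)
  expect_equal(nrow(t$edges), n - 1L)
  expect_equal(sort(apply(t$edges, 1, paste, collapse = "-")),
               sort(apply(edges, 1, paste, collapse = "-")))
})

test_that("Kruskal matches an independent algorithm on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(4)
  for (rep in 1:20) {
    g <- rand_connected_graph(sample(5:9, 1), extra = 6)
    t <- kruskal_mst(as_grid_graph(g))
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    igraph::E(ig)$weight <- g$weights
    mst <- igraph::mst(ig)
    expect_equal(sum(t$weights),
                 sum(igraph::E(mst)$weight), tolerance = 1e-12)
  }
})

test_that("degree-3 pruning removes whole branches and bounds every degree", {
  # star with center degree 5: two leaves removed, center kept at degree 3
  edges <- cbind(rep(1L, 5), 2:6)
  tree <- structure(list(xyz = matrix(seq_len(6), 6, 3), ijk = NULL,
                         density = c(10, 5, 4, 3, 2, 1),
                         edges = edges, weights = rep(1, 5), name = "star"),
                    class = "spanning_tree")
  pruned <- prune_to_degree3(tree)
  expect_equal(nrow(pruned$xyz), 4L)
  deg <- tabulate(c(pruned$edges[, 1], pruned$edges[, 2]), nrow(pruned$xyz))
  expect_equal(max(deg), 3L)
  # lowest-density branches (leaves 5 and 6) went first
  expect_setequal(pruned$density, c(10, 5, 4, 3))

  # path graphs are untouched
  pe <- cbind(1:5, 2:6)
  path <- structure(list(xyz = matrix(seq_len(6), 6, 3), ijk = NULL,
                         density = rep(1, 6), edges = pe,
                         weights = rep(1, 5), name = "path"),
                    class = "spanning_tree")
  expect_equal(nrow(prune_to_degree3(path)$xyz), 6L)
})

test_that("forest bookkeeping holds at every stage on random trees", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    g <- rand_connected_graph(n, extra = 5)
    t <- kruskal_mst(as_grid_graph(g))
    expect_equal(nrow(t$edges), n - 1L)          # connected input
    p <- prune_to_degree3(t)
    npruned <- nrow(p$xyz)
    comp <- emthread:::component_labels(npruned, p$edges)
    expect_equal(nrow(p$edges), npruned - max(comp))
    deg <- tabulate(c(p$edges[, 1], p$edges[, 2]), npruned)
    expect_true(all(deg <= 3))
  }
})

test_that("tree_components splits a forest and drops small components", {
  edges <- rbind(cbind(1:11, 2:12), cbind(13:15, 14:16))  # 12-path + 4-path
  tree <- structure(list(xyz = matrix(seq_len(16), 16, 3), ijk = NULL,
                         density = rep(1, 16), edges = edges,
                         weights = rep(1, nrow(edges)), name = "forest"),
                    class = "spanning_tree")
  comps <- tree_components(tree, min_vertices = 10)
  expect_length(comps, 1L)
  expect_equal(nrow(comps[[1]]$xyz), 12L)
  comps2 <- tree_components(tree, min_vertices = 3)
  expect_length(comps2, 2L)
})

test_that("auto threshold tracks the requested protein volume", {
  set.seed(6)
  m <- density_map(array(runif(8000), dim = c(20, 20, 20)), voxel_size = 2)
  thr <- auto_threshold(m, n_residues = 50, volume_factor = 1.5)
  n_keep <- sum(m$values > thr)
  target <- 1.5 * 1.21 * 110 * 50 / 8
  expect_lt(abs(n_keep - target) / target, 0.05)
})
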