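# polyline -> spanning_tree helper: a single path with given points
path_tree <- function(pts) {
  n <- nrow(pts)
  structure(list(xyz = pts, ijk = NULL, density = rep(1, n),
                 edges = cbind(seq_len(n - 1), 2:n),
                 weights = rep(1, n - 1), name = "p"),
            class = "spanning_tree")
}

test_that("bead regularization resamples polylines at 3.8 A arc length", {
  # straight 11.4 A polyline -> beads at 0, 3.8, 7.6, 11.4
  pts <- cbind(seq(0, 11.4, length.out = 7), 0, 0)
  bg <- regularize_beads(path_tree(pts))
  expect_equal(nrow(bg$xyz), 4L)
  expect_equal(sort(bg$xyz[, 1]), c(0, 3.8, 7.6, 11.4), tolerance = 1e-9)
  expect_false(any(bg$flagged))

  # 3.0 A polyline -> endpoints only, flagged under-spaced
  short <- cbind(c(0, 1.5, 3.0), 0, 0)
  bg2 <- regularize_beads(path_tree(short))
  expect_equal(nrow(bg2$xyz), 2L)
  expect_true(all(bg2$flagged))

  # L-shaped polyline, two 7.6 A legs: 5 beads, arc spacing exactly 3.8,
  # chord spacing at most 3.8
  L <- rbind(cbind(seq(0, 7.6, 1.9), 0, 0),
             cbind(7.6, seq(1.9, 7.6, 1.9), 0))
  bg3 <- regularize_beads(path_tree(L))
  expect_equal(nrow(bg3$xyz), 5L)
  ord <- order(bg3$xyz[, 1] + bg3$xyz[, 2])
  chords <- sqrt(rowSums(diff(bg3$xyz[ord, ])^2))
  expect_true(all(chords <= 3.8 + 1e-9))
  expect_false(any(bg3$flagged))
})

test_that("fork pruning removes short arms and splits at large forks", {
  # arms (10, 10, 2), Tp = 5: the 2-bead arm is deleted and the two long
  # arms stay joined through the fork bead -> one 21-bead fragment
  y <- make_y_graph(c(10, 10, 2))
  out <- prune_forks(y, Tp = 5)
  deg <- tabulate(c(out$edges[, 1], out$edges[, 2]), nrow(out$xyz))
  expect_true(all(deg <= 2))
  frags <- extract_fragments(out, 1)
  expect_length(frags, 1L)
  expect_equal(nrow(frags[[1]]$xyz), 21L)

  # arms (10, 10, 8), Tp = 5: fork bead deleted, three fragments
  y2 <- make_y_graph(c(10, 10, 8))
  out2 <- prune_forks(y2, Tp = 5)
  frags2 <- extract_fragments(out2, 1)
  expect_length(frags2, 3L)
  expect_setequal(vapply(frags2, function(f) nrow(f$xyz), 1L), c(10L, 10L, 8L))
})

test_that("fork pruning is idempotent on unbranched graphs", {
  y <- prune_forks(make_y_graph(c(6, 6, 2)), Tp = 5)
  again <- prune_forks(y, Tp = 5)
  expect_equal(again$xyz, y$xyz)
  expect_equal(again$edges, y$edges)
})

test_that("fork pruning matches the independent rule reimplementation", {
  set.seed(11)
  tested <- 0
  while (tested < 60) {
    n <- sample(6:12, 1)
    edges <- rand_tree_deg3(n)
    if (is.null(edges)) next
    deg <- tabulate(c(edges[, 1], edges[, 2]), n)
    if (sum(deg == 3) < 1 || sum(deg == 3) > 3) next
    tested <- tested + 1
    Tp <- sample(2:5, 1)
    bg <- as_bead_graph(n, edges)
    kept_impl <- sort(emthread::prune_forks(bg, Tp)$xyz[, 1])
    kept_oracle <- sort(oracle_prune_forks(n, edges, Tp))
    expect_equal(kept_impl, kept_oracle,
                 info = sprintf("n=%d Tp=%d", n, Tp))
  }
})

test_that("fragment extraction keeps maximal paths above the length floor", {
  # 30-bead path + 3-bead path
  edges <- rbind(cbind(1:29, 2:30), cbind(31:32, 32:33))
  bg <- as_bead_graph(33, edges)
  frags <- extract_fragments(bg, 5)
  expect_length(frags, 1L)
  expect_equal(nrow(frags[[1]]$xyz), 30L)
  # boundary: exactly the minimum survives
  bg2 <- as_bead_graph(5, cbind(1:4, 2:5))
  expect_length(extract_fragments(bg2, 5), 1L)
  expect_error(extract_fragments(bg2, 6), "fragment")
})

test_that("twig trimming drops sub-residue spurs but keeps real branches", {
  # path 1..8 spaced 3.8 with a 1 A spur on vertex 4
  pts <- rbind(cbind(3.8 * (0:7), 0, 0), c(3.8 * 3, 1.0, 0))
  tree <- structure(list(xyz = pts, ijk = NULL, density = rep(1, 9),
                         edges = rbind(cbind(1:7, 2:8), c(4, 9)),
                         weights = rep(1, 8), name = "t"),
                    class = "spanning_tree")
  trimmed <- emthread:::trim_twigs(tree, min_length = 3.0)
  expect_equal(nrow(trimmed$xyz), 8L)
  # a 7.6 A spur survives
  pts2 <- rbind(pts[1:8, ], c(3.8 * 3, 3.8, 0), c(3.8 * 3, 7.6, 0))
  tree2 <- structure(list(xyz = pts2, ijk = NULL, density = rep(1, 10),
                          edges = rbind(cbind(1:7, 2:8), c(4, 9), c(9, 10)),
                          weights = rep(1, 9), name = "t2"),
                     class = "spanning_tree")
  expect_equal(nrow(emthread:::trim_twigs(tree2, 3.0)$xyz), 10L)
})

test_that("tracing a clean synthetic scene covers the ground truth", {
  scene <- make_scene(n_chains = 1, rng_seed = 5,
                      blocks = tiny_fold_blocks)
  cfg <- emthread_config(n_residues = nrow(scene$chains[[1]]))
  tr <- run_trace(scene$map, cfg)
  beads <- do.call(rbind, lapply(tr$fragments, `[[`, "xyz"))
  nn <- emthread:::cpp_nearest(scene$chains[[1]], beads)
  expect_gt(mean(nn$dist <= 1.5), 0.75)
  expect_lt(mean(nn$dist), 1.5)
  # spacing concentrates at the canonical C-alpha step
  sp <- unlist(lapply(tr$fragments, function(f) sqrt(rowSums(diff(f$xyz)^2))))
  expect_lt(abs(median(sp) - 3.8), 0.5)
  expect_gt(mean(abs(sp - 3.8) <= 1.2), 0.9)
  expect_true(all(sp < 6) && all(sp > 1.8))
})
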