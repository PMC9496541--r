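# straight fragment along +x starting at `at`
line_frag <- function(id, n, at = c(0, 0, 0)) {
  structure(list(xyz = cbind(at[1] + 3.8 * (seq_len(n) - 1), at[2], at[3]),
                 id = id), class = "ca_fragment")
}

test_that("candidate neighbors respect the join distance and orientations", {
  f <- line_frag(1, 5)                       # ends at x = 15.2
  g <- line_frag(2, 5, at = c(15.2 + 7, 0, 0))
  cand <- candidate_neighbors(list(f, g), join_distance = 11)
  # colinear fragments, 7 A end gap: joinable head-to-tail in exactly two
  # of the oriented combinations (1fwd -> 2fwd and 2rev -> 1rev)
  expect_equal(nrow(cand), 2L)
  key <- paste(cand$from_id, cand$from_orient, cand$to_id, cand$to_orient)
  expect_setequal(key, c("1 forward 2 forward", "2 reversed 1 reversed"))

  far <- line_frag(2, 5, at = c(15.2 + 12, 0, 0))
  expect_equal(nrow(candidate_neighbors(list(f, far), 11)), 0L)
})

test_that("candidate neighbors equal the brute-force end-distance check", {
  set.seed(31)
  frags <- lapply(1:4, function(k)
    structure(list(xyz = matrix(rnorm(15, sd = 8), 5, 3), id = k),
              class = "ca_fragment"))
  cand <- candidate_neighbors(frags, 11)
  brute <- 0L
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    for (oa in 1:2) for (ob in 1:2) {
      xa <- if (oa == 1) frags[[a]]$xyz else frags[[a]]$xyz[5:1, ]
      xb <- if (ob == 1) frags[[b]]$xyz else frags[[b]]$xyz[5:1, ]
      if (sqrt(sum((xa[5, ] - xb[1, ])^2)) <= 11) brute <- brute + 1L
    }
  }
  expect_equal(nrow(cand), brute)
})

test_that("join gaps insert the right number of placeholder positions", {
  f <- line_frag(1, 5)
  g <- line_frag(2, 5, at = c(15.2 + 11.4, 0, 0))   # 11.4 A end gap
  cc <- concat_fragments(list(f, g), c(1, 2), c("forward", "forward"))
  expect_equal(nrow(cc$coords), 12L)                # 2 placeholders
  expect_equal(sum(is.na(cc$coords[, 1])), 2L)
  expect_equal(cc$origin$pos, c(1:5, 8:12))
})

test_that("a single-fragment pool yields that fragment in its best direction", {
  set.seed(32)
  trace <- make_structure(tiny_fold_blocks)
  pred <- filter_predicted(make_predicted_contacts(trace, 1, 0), 0)
  frag <- structure(list(xyz = trace, id = 1L), class = "ca_fragment")
  ch <- grow_chain(list(frag), pred)
  expect_equal(ch$ids, 1L)
  expect_equal(ch$orients, "forward")
  expect_equal(ch$score, nrow(pred$pairs))          # perfect self match
})

test_that("ideal fragments reassemble into the ground-truth chain", {
  set.seed(33)
  trace <- make_structure(tiny_fold_blocks)
  frags <- make_ideal_fragments(trace, c(10, 25))
  pred <- filter_predicted(make_predicted_contacts(trace, 1, 0), 0)
  ch <- grow_chain(frags, pred)
  expect_equal(sort(ch$ids), seq_along(frags))
  # recovered order and orientations reproduce the truth: every real bead
  # sits exactly on its ground-truth position, in order
  real <- which(stats::complete.cases(ch$coords))
  expect_equal(nrow(ch$coords), nrow(trace))
  expect_equal(ch$coords[real, ], trace[real, ], tolerance = 1e-9)
})

test_that("greedy growth never scores below its seed and beats no extension", {
  set.seed(34)
  trace <- make_structure(tiny_fold_blocks)
  frags <- make_ideal_fragments(trace, c(10, 25))
  pred <- filter_predicted(make_predicted_contacts(trace, 0.9, 0.05), 0)
  seed_best <- max(vapply(frags, function(f) {
    a <- contacts_from_coords(f$xyz, 8, 5)
    align_contact_maps(a, pred)$score
  }, 0))
  ch <- grow_chain(frags, pred)
  expect_gte(ch$score, seed_best)
})

test_that("greedy growth attains the exhaustive best on small ideal pools", {
  set.seed(35)
  trace <- make_structure(c("helix:14", "coil:4", "helix:14", "coil:4",
                            "strand:6"))
  frags <- make_ideal_fragments(trace, c(12, 20))
  expect_lte(length(frags), 4L)
  pred <- filter_predicted(make_predicted_contacts(trace, 1, 0), 0)
  params <- assembly_params()
  ids <- vapply(frags, `[[`, 1L, "id")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (k in seq_along(ids)) {
    for (sub in as.data.frame(utils::combn(ids, k))) {
      for (ord in perms(sub)) {
        n_or <- length(ord)
        for (mask in seq_len(2^n_or) - 1L) {
          orients <- ifelse(bitwAnd(mask, 2^(seq_len(n_or) - 1)) > 0,
                            "reversed", "forward")
          s <- emthread:::score_chain_tuple(frags, ord, orients, pred, params)
          if (s > best) best <- s
        }
      }
    }
  }
  ch <- grow_chain(frags, pred)
  expect_equal(ch$score, best, tolerance = 1e-9)
})

test_that("the merge cache returns bit-identical scores to recomputation", {
  set.seed(36)
  trace <- make_structure(tiny_fold_blocks)
  frags <- make_ideal_fragments(trace, c(10, 20))
  pred <- filter_predicted(make_predicted_contacts(trace, 0.8, 0.05), 0)
  cache <- new_merge_cache()
  with_cache <- grow_chain(frags, pred, cache = cache)
  no_cache <- grow_chain(frags, pred, cache = NULL)
  expect_identical(with_cache$score, no_cache$score)
  expect_identical(with_cache$ids, no_cache$ids)
  # cached entries replay exactly
  params <- assembly_params()
  for (key in ls(cache)) {
    ids_or <- as.integer(strsplit(key, ",")[[1]])
    expect_identical(cache[[key]],
                     emthread:::score_chain_tuple(
                       frags, abs(ids_or),
                       ifelse(ids_or > 0, "forward", "reversed"),
                       pred, params))
  }
})

test_that("multi-chain building commits disjoint chains by decreasing score", {
  set.seed(37)
  scene <- make_scene(n_chains = 2, rng_seed = 37, sensitivity = 1, fp_rate = 0)
  frags <- c(make_ideal_fragments(scene$chains[[1]], c(10, 25)),
             make_ideal_fragments(scene$chains[[2]], c(10, 25)))
  frags <- lapply(seq_along(frags), function(k) {
    f <- frags[[k]]; f$id <- k; f
  })
  preds <- lapply(scene$predicted, filter_predicted, p_min = 0)
  built <- build_all_chains(frags, preds)
  ids_used <- lapply(built$chains, `[[`, "ids")
  expect_equal(anyDuplicated(unlist(ids_used)), 0L)
  scores <- vapply(built$chains, `[[`, 0, "score")
  expect_true(all(diff(scores) <= 1e-9))
  # each committed chain's fragments belong to its own ground truth
  truth_all <- do.call(rbind, scene$chains)
  owner <- rep(names(scene$chains), vapply(scene$chains, nrow, 1L))
  for (cid in names(built$chains)) {
    beads <- built$chains[[cid]]$coords
    beads <- beads[stats::complete.cases(beads), , drop = FALSE]
    nn <- emthread:::cpp_nearest(beads, truth_all)
    expect_true(all(owner[nn$index] == cid))
  }
})

test_that("sequence registration is the identity for a self-consistent chain", {
  set.seed(38)
  trace <- make_structure(tiny_fold_blocks)
  pred <- filter_predicted(make_predicted_contacts(trace, 1, 0), 0)
  frag <- structure(list(xyz = trace, id = 1L), class = "ca_fragment")
  ch <- grow_chain(list(frag), pred)
  ch <- register_sequence(ch, pred, strrep("A", nrow(trace)))
  reg <- ch$register
  sup <- which(!is.na(reg))
  expect_equal(reg[sup], sup)
  expect_gt(length(sup) / nrow(trace), 0.9)
  expect_error(register_sequence(ch, pred, "SHORT"), "does not match")
})

test_that("alignment-gap fragmentation cuts only at gaps beyond the floor", {
  set.seed(39)
  trace <- make_structure(tiny_fold_blocks)
  pred <- filter_predicted(make_predicted_contacts(trace, 1, 0), 0)
  # deleting 6 interior residues leaves one >4-residue alignment gap
  cut6 <- trace[-(31:36), ]
  frags <- fragment_by_alignment_gaps(cut6, pred, gap_min = 4)
  expect_length(frags, 2L)
  expect_equal(nrow(frags[[1]]$xyz) + nrow(frags[[2]]$xyz), nrow(cut6))
  # a 4-residue deletion is at the boundary: strictly more than 4 required
  cut4 <- trace[-(31:34), ]
  expect_length(fragment_by_alignment_gaps(cut4, pred, gap_min = 4), 1L)
  # no gaps at all
  expect_length(fragment_by_alignment_gaps(trace, pred, gap_min = 4), 1L)
})

test_that("map segmentation assigns voxels to the nearest chain within radius", {
  set.seed(40)
  c1 <- cbind(3.8 * (0:9), 0, 0)
  c2 <- cbind(3.8 * (0:9), 30, 0)
  map <- simulate_map(list(c1, c2), resolution = 4, voxel = 2)
  chains <- list(A = list(coords = c1, unassigned = FALSE),
                 B = list(coords = c2, unassigned = FALSE))
  masks <- segment_map(map, chains, radius = 5, threshold = 0.05)
  expect_named(masks, c("A", "B"))
  # disjoint and faithful to brute-force nearest-bead assignment
  both <- masks$A$values > 0 & masks$B$values > 0
  expect_false(any(both))
  vox <- which(map$values > 0.05)
  xyz <- grid_to_xyz(map, arrayInd(vox, dim(map$values)))
  dA <- emthread:::cpp_nearest(xyz, c1)$dist
  dB <- emthread:::cpp_nearest(xyz, c2)$dist
  brute <- ifelse(pmin(dA, dB) > 5, 0L, ifelse(dA <= dB, 1L, 2L))
  got <- ifelse(masks$A$values[vox] > 0, 1L,
                ifelse(masks$B$values[vox] > 0, 2L, 0L))
  expect_equal(got, brute)
  # original densities preserved where assigned
  expect_true(all(masks$A$values[masks$A$values > 0] ==
                  map$values[masks$A$values > 0]))
})
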