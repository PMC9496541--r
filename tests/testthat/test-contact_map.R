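test_that("contact maps from coordinates honor cutoff and separation", {
  # residues 1 and 6 at 7 A with min separation 5 -> contact
  coords <- matrix(0, 6, 3)
  coords[, 1] <- c(0, 100, 200, 300, 400, 7)
  cm <- contacts_from_coords(coords, cutoff = 8, min_separation = 5)
  expect_equal(cm$pairs, matrix(c(1L, 6L), 1))

  # 3 collinear points spaced 3.8: all separations < 5 -> empty
  line <- cbind(c(0, 3.8, 7.6), 0, 0)
  expect_equal(nrow(contacts_from_coords(line, 8, 5)$pairs), 0L)

  # ideal helix vs brute-force all-pairs distances
  h <- emthread:::helix_block(20)
  cm2 <- contacts_from_coords(h, cutoff = 8, min_separation = 3)
  d <- as.matrix(dist(h))
  expected <- which(upper.tri(d) & d <= 8 & abs(row(d) - col(d)) >= 3,
                    arr.ind = TRUE)
  expect_equal(nrow(cm2$pairs), nrow(expected))
  expect_setequal(paste(cm2$pairs[, 1], cm2$pairs[, 2]),
                  paste(expected[, 1], expected[, 2]))
})

test_that("reversing the chain relabels the contact map consistently", {
  set.seed(21)
  coords <- emthread:::place_coil(NULL, 30)
  cm <- contacts_from_coords(coords, 8, 3)
  cmr <- contacts_from_coords(coords[30:1, ], 8, 3)
  flipped <- cbind(31L - cm$pairs[, 2], 31L - cm$pairs[, 1])
  expect_setequal(paste(cmr$pairs[, 1], cmr$pairs[, 2]),
                  paste(flipped[, 1], flipped[, 2]))
})

test_that("probability filtering keeps exactly the confident contacts", {
  pred <- predicted_contacts(15, c(1, 2), c(9, 12), c(0.9, 0.4))
  expect_equal(filter_predicted(pred, 0.5)$pairs, matrix(c(1L, 9L), 1))
  expect_equal(nrow(filter_predicted(pred, 0.0)$pairs), 2L)
  set.seed(22)
  n <- 40
  pr <- predicted_contacts(n, sample(1:20, 30, TRUE), sample(21:40, 30, TRUE),
                           runif(30))
  kept <- filter_predicted(pr, 0.5)
  expect_equal(nrow(kept$pairs),
               nrow(unique(pr$entries[pr$entries$prob >= 0.5, c("i", "j")])))
})

test_that("RR parsing roundtrips through the writer dialects", {
  tmp <- tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "TARGET T000", "MODEL 1",
               "1 9 0 8 0.93", "2 12 0 8 0.41", "3 15 0 8 0.77", "END"), tmp)
  pred <- read_rr(tmp, n = 20)
  expect_equal(pred$n, 20L)
  expect_equal(pred$entries$prob, c(0.93, 0.41, 0.77))
  # 3-column variant
  writeLines(c("1 9 0.93", "3 15 0.77"), tmp)
  expect_equal(nrow(read_rr(tmp)$entries), 2L)
})

test_that("self-alignment is the identity with no gap penalty", {
  set.seed(23)
  A <- rand_contact_map(12, 0.4)
  al <- align_contact_maps(A, A)
  expect_equal(al$score, nrow(A$pairs))
  sup <- which(al$mapping > 0)
  expect_equal(al$mapping[sup], sup)
})

test_that("alignment recovers an index shift exactly", {
  set.seed(24)
  A <- rand_contact_map(10, 0.4)
  k <- 4L
  B <- contact_map(18, A$pairs + k)
  al <- align_contact_maps(A, B)
  expect_equal(al$score, nrow(A$pairs))
  carries <- sort(unique(as.vector(A$pairs)))
  expect_equal(al$mapping[carries], carries + k)
})

test_that("alignment equals exhaustive search on random small maps", {
  set.seed(25)
  tested <- 0
  while (tested < 40) {
    A <- rand_contact_map(sample(4:8, 1), 0.3)
    B <- rand_contact_map(sample(4:8, 1), 0.3)
    if (nrow(A$pairs) == 0 || nrow(B$pairs) == 0) next
    tested <- tested + 1
    expect_equal(align_contact_maps(A, B)$score,
                 oracle_best_alignment(A, B), tolerance = 1e-9)
  }
})

test_that("the reported score is self-consistent with its mapping", {
  set.seed(26)
  for (rep in 1:10) {
    A <- rand_contact_map(15, 0.3)
    B <- rand_contact_map(18, 0.3)
    if (nrow(A$pairs) == 0 || nrow(B$pairs) == 0) next
    al <- align_contact_maps(A, B)
    expect_equal(al$score, alignment_objective(al$mapping, A, B),
                 tolerance = 1e-9)
    sup <- which(al$mapping > 0)
    if (length(sup) > 1) expect_true(all(diff(al$mapping[sup]) > 0))
  }
})

test_that("alignment score is invariant under consistent relabeling", {
  set.seed(27)
  A <- rand_contact_map(10, 0.4)
  B <- rand_contact_map(10, 0.4)
  sA <- align_contact_maps(A, B)$score
  A2 <- contact_map(13, A$pairs + 3L)
  B2 <- contact_map(13, B$pairs + 3L)
  expect_equal(align_contact_maps(A2, B2)$score, sA, tolerance = 1e-9)
})

test_that("degenerate alignments return the empty mapping at score zero", {
  A <- contact_map(6, matrix(c(1L, 4L), 1))
  B <- contact_map(6, matrix(integer(0), 0, 2))
  al <- align_contact_maps(A, B)
  expect_equal(al$score, 0)
  expect_true(all(al$mapping == 0L))
})

test_that("overlap fraction counts satisfied predicted contacts", {
  model <- contact_map(20, rbind(c(1, 9), c(3, 15), c(4, 18)))
  pred <- contact_map(20, rbind(c(1, 9), c(2, 12), c(3, 15)))
  expect_equal(overlap_fraction(model, pred), 2 / 3)
  expect_equal(overlap_fraction(model, model), 1.0)
  expect_equal(overlap_fraction(contact_map(20, rbind(c(5, 11))), pred), 0.0)
  expect_true(is.na(overlap_fraction(model, contact_map(20, matrix(integer(0), 0, 2)))))
  expect_error(overlap_fraction(model, contact_map(19, rbind(c(1, 9)))),
               "different residue counts")
})
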