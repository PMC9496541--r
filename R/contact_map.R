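# Contact maps and their alignment. A contact map is the set of residue
# pairs whose C-alpha atoms are within a distance cutoff (8 A here);
# predicted contacts from co-evolution carry a probability and are
# binarized at 0.5. Aligning the contact map of a growing trace against
# the predicted map registers the sequence and scores the threading.

#' Contact map constructor
#'
#' @param n residue count.
#' @param pairs 2-column matrix of 1-based residue index pairs (stored
#'   unordered, i < j).
#' @return object of class `contact_map`.
#' @export
contact_map <- function(n, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    if (any(pairs[, 1] < 1L) || any(pairs[, 2] > n))
      stop("contact indices out of [1, n]")
    if (any(pairs[, 1] == pairs[, 2]))
      stop("self-contacts are not allowed")
    pairs <- unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
  }
  structure(list(n = as.integer(n), pairs = pairs), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> n = %d, %d contacts\n", x$n, nrow(x$pairs)))
  invisible(x)
}

#' Contact map from C-alpha coordinates
#'
#' Pair (i, j) is a contact iff `|i - j| >= min_separation` and the
#' Euclidean distance is at most `cutoff`. Rows of `coords` that are NA
#' (e.g. unobserved join-gap placeholders in a concatenated chain) never
#' form contacts but keep their index, so the map stays on a residue-true
#' scale.
#'
#' @param coords ordered n x 3 matrix of C-alpha positions (A).
#' @param cutoff contact distance cutoff (A).
#' @param min_separation minimum sequence separation; 5 discards the
#'   trivially local contacts that carry no fold information.
#' @return a [contact_map()].
#' @export
contacts_from_coords <- function(coords, cutoff = 8, min_separation = 5) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 coordinates")
  ok <- which(stats::complete.cases(coords))
  if (length(ok) < 2L) return(contact_map(n, matrix(integer(0), 0, 2)))
  d <- as.matrix(dist(coords[ok, , drop = FALSE]))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  pairs <- cbind(ok[hit[, 1]], ok[hit[, 2]])
  pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) >= min_separation, , drop = FALSE]
  contact_map(n, pairs)
}

#' Predicted contacts with probabilities
#'
#' @param n residue count.
#' @param i,j residue indices (i < j after normalization).
#' @param prob per-pair probability in `[0, 1]`.
#' @return object of class `predicted_contacts`.
#' @export
predicted_contacts <- function(n, i, j, prob) {
  ii <- pmin(as.integer(i), as.integer(j))
  jj <- pmax(as.integer(i), as.integer(j))
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  if (length(ii) && (any(ii < 1L) || any(jj > n))) stop("indices out of [1, n]")
  structure(list(n = as.integer(n),
                 entries = data.frame(i = ii, j = jj, prob = as.numeric(prob))),
            class = "predicted_contacts")
}

#' Binarize predicted contacts at a probability threshold
#'
#' @param pred a [predicted_contacts()].
#' @param p_min minimum probability; 0.5 is the conventional cutoff for
#'   turning co-evolution scores into binary contacts.
#' @return a [contact_map()].
#' @export
filter_predicted <- function(pred, p_min = 0.5) {
  keep <- pred$entries$prob >= p_min
  contact_map(pred$n, cbind(pred$entries$i[keep], pred$entries$j[keep]))
}

#' Read a CASP RR contact file
#'
#' Accepts the five-column RR dialect (`i j d_low d_high probability`) and
#' a plain three-column variant (`i j probability`); header/sequence lines
#' are skipped. The residue count is taken from `n` or, failing that,
#' from the largest index seen.
#'
#' @param path RR file path.
#' @param n residue count (recommended: the chain's sequence length).
#' @return a [predicted_contacts()].
#' @export
read_rr <- function(path, n = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  rows <- Filter(function(t) length(t) %in% c(3L, 5L) &&
                   !anyNA(suppressWarnings(as.numeric(t))), toks)
  if (length(rows) == 0L) stop("no contact rows found in ", path)
  m <- do.call(rbind, lapply(rows, as.numeric))
  prob <- m[, ncol(m)]
  if (is.null(n)) n <- max(m[, 1:2])
  predicted_contacts(n, m[, 1], m[, 2], prob)
}

#' Write a contact map as three-column text
#'
#' @param cm a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path) {
  df <- data.frame(i = cm$pairs[, 1], j = cm$pairs[, 2], contact = 1L)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Align two contact maps
#'
#' Iterative double dynamic programming in the spirit of map_align: the
#' alignment maximizes the number (and separation similarity) of
#' overlapping contacts while penalizing internal gaps with affine costs;
#' leading and trailing gaps are free. A matched contact pair with
#' sequence separations `s_A`, `s_B` contributes
#' `min(1, s_A/s_B, s_B/s_A)`, so contacts of similar range pair
#' preferentially. The returned score is always recomputed from the
#' mapping (matched-contact scores plus internal gap penalties), so it is
#' self-consistent with `alignment_objective()`.
#'
#' @param A,B [contact_map()] objects (A is typically the model trace, B
#'   the predicted map).
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @param max_iterations,tolerance outer-iteration controls.
#' @return object of class `contact_alignment`: `mapping` (integer vector
#'   of length `A$n`; 0 = unaligned), `score`, `iterations`.
#' @export
align_contact_maps <- function(A, B, gap_open = -1.0, gap_extend = -0.1,
                               max_iterations = 20, tolerance = 1e-6) {
  stopifnot(inherits(A, "contact_map"), inherits(B, "contact_map"))
  if (nrow(A$pairs) == 0L || nrow(B$pairs) == 0L) {
    return(structure(list(mapping = integer(A$n), score = 0, iterations = 0L,
                          gap_open = gap_open, gap_extend = gap_extend),
                     class = "contact_alignment"))
  }
  res <- cpp_align_maps(A$n, B$n, A$pairs, B$pairs,
                        gap_open, gap_extend, max_iterations, tolerance)
  structure(list(mapping = res$mapping, score = res$score,
                 iterations = res$iterations,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "contact_alignment")
}

#' @export
print.contact_alignment <- function(x, ...) {
  cat(sprintf("<contact_alignment> %d positions aligned, score %.4f (%d iterations)\n",
              sum(x$mapping > 0), x$score, x$iterations))
  invisible(x)
}

#' Alignment objective for a given mapping
#'
#' The score of a strictly monotone partial mapping from positions of `A`
#' to positions of `B`: the sum of separation-similarity scores over
#' contact pairs of `A` whose images form contacts of `B`, plus affine
#' penalties for internal gaps (free end gaps). Used for score
#' self-consistency checks and by the brute-force oracle in the tests.
#'
#' @param mapping integer vector of length `A$n` (0 = unaligned),
#'   strictly increasing on its support.
#' @param A,B [contact_map()] objects.
#' @param gap_open,gap_extend affine gap penalties.
#' @return numeric score.
#' @export
alignment_objective <- function(mapping, A, B, gap_open = -1.0, gap_extend = -0.1) {
  sup <- which(mapping > 0)
  if (length(sup) == 0L) return(0)
  if (any(diff(mapping[sup]) <= 0)) stop("mapping must be strictly increasing")
  bkey <- paste(B$pairs[, 1], B$pairs[, 2])
  score <- 0
  if (nrow(A$pairs) > 0) {
    mi <- mapping[A$pairs[, 1]]
    mj <- mapping[A$pairs[, 2]]
    ok <- mi > 0 & mj > 0
    if (any(ok)) {
      sA <- A$pairs[ok, 2] - A$pairs[ok, 1]
      sB <- abs(mj[ok] - mi[ok])
      matched <- paste(pmin(mi[ok], mj[ok]), pmax(mi[ok], mj[ok])) %in% bkey
      score <- sum((pmin(sA, sB) / pmax(sA, sB))[matched])
    }
  }
  gp <- function(d) ifelse(d > 0, gap_open + gap_extend * (d - 1), 0)
  if (length(sup) > 1L) {
    dA <- diff(sup) - 1L
    dB <- diff(mapping[sup]) - 1L
    score <- score + sum(gp(dA)) + sum(gp(dB))
  }
  score
}

#' Fraction of predicted contacts satisfied by a model
#'
#' @param model,predicted [contact_map()] objects on the same residue
#'   scale.
#' @return `|predicted intersect model| / |predicted|`; `NA` when
#'   `predicted` is empty (undefined, never reported as 0).
#' @export
overlap_fraction <- function(model, predicted) {
  if (model$n != predicted$n)
    stop("contact maps have different residue counts (", model$n,
         " vs ", predicted$n, ")")
  if (nrow(predicted$pairs) == 0L) return(NA_real_)
  mkey <- paste(model$pairs[, 1], model$pairs[, 2])
  mean(paste(predicted$pairs[, 1], predicted$pairs[, 2]) %in% mkey)
}
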