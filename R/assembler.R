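# Contact-guided fragment assembly. Fragments carry no N-to-C direction,
# so both orientations of every fragment are tested; chains grow greedily
# from the best-scoring seed fragment by appending/prepending spatial
# neighbors whenever the contact-map alignment score against the chain's
# predicted contacts improves. Building every chain from the shared pool
# and committing the best-scoring one first segments the map into
# subunits as a by-product.

frag_coords <- function(fragment, orientation = "forward") {
  if (orientation == "forward") fragment$xyz
  else fragment$xyz[rev(seq_len(nrow(fragment$xyz))), , drop = FALSE]
}

#' Candidate joinable fragment pairs
#'
#' Oriented pair `f -> g` is a candidate iff the tail of `f` (in its
#' orientation) lies within `join_distance` of the head of `g` (in its
#' orientation). 11 A spans a missing loop of about two residues.
#'
#' @param fragments list of `ca_fragment`.
#' @param join_distance maximum end-to-end gap (A).
#' @return data.frame with columns `from_id`, `from_orient`, `to_id`,
#'   `to_orient`, `gap` (A).
#' @export
candidate_neighbors <- function(fragments, join_distance = 11) {
  stopifnot(length(fragments) >= 1L)
  ends <- fragment_ends(fragments)
  out <- list()
  for (a in seq_len(nrow(ends$tab))) {
    for (b in seq_len(nrow(ends$tab))) {
      if (ends$tab$id[a] == ends$tab$id[b]) next
      g <- sqrt(sum((ends$tail[a, ] - ends$head[b, ])^2))
      if (g <= join_distance)
        out[[length(out) + 1L]] <- data.frame(
          from_id = ends$tab$id[a], from_orient = ends$tab$orient[a],
          to_id = ends$tab$id[b], to_orient = ends$tab$orient[b], gap = g)
    }
  }
  if (length(out) == 0L)
    return(data.frame(from_id = integer(0), from_orient = character(0),
                      to_id = integer(0), to_orient = character(0),
                      gap = numeric(0)))
  do.call(rbind, out)
}

fragment_ends <- function(fragments) {
  tab <- expand.grid(id = vapply(fragments, function(f) as.integer(f$id), 1L),
                     orient = c("forward", "reversed"),
                     stringsAsFactors = FALSE)
  head_m <- matrix(0, nrow(tab), 3L)
  tail_m <- matrix(0, nrow(tab), 3L)
  by_id <- setNames(fragments, vapply(fragments, function(f) as.integer(f$id), 1L))
  for (r in seq_len(nrow(tab))) {
    xyz <- frag_coords(by_id[[as.character(tab$id[r])]], tab$orient[r])
    head_m[r, ] <- xyz[1, ]
    tail_m[r, ] <- xyz[nrow(xyz), ]
  }
  list(tab = tab, head = head_m, tail = tail_m)
}

#' Concatenate oriented fragments into padded chain coordinates
#'
#' Between consecutive fragments with an end gap of `g` Angstrom,
#' `round(g / spacing) - 1` NA placeholder rows are inserted so the
#' chain's contact map stays on a residue-true index scale.
#'
#' @param fragments list of `ca_fragment` (the pool).
#' @param ids,orients ordered fragment ids and orientations.
#' @param spacing residue spacing used to convert gap length to residues.
#' @return list with `coords` (padded n x 3, NA rows at joins) and
#'   `origin` (data.frame: padded position, fragment id, bead index
#'   within the oriented fragment).
#' @export
concat_fragments <- function(fragments, ids, orients, spacing = 3.8) {
  by_id <- setNames(fragments, vapply(fragments, function(f) as.integer(f$id), 1L))
  coords <- NULL
  origin <- list()
  for (k in seq_along(ids)) {
    xyz <- frag_coords(by_id[[as.character(ids[k])]], orients[k])
    if (!is.null(coords)) {
      g <- sqrt(sum((coords[nrow(coords), ] - xyz[1, ])^2))
      npad <- max(0L, as.integer(round(g / spacing)) - 1L)
      if (npad > 0)
        coords <- rbind(coords, matrix(NA_real_, npad, 3L))
    }
    start <- if (is.null(coords)) 0L else nrow(coords)
    coords <- rbind(coords, xyz)
    origin[[k]] <- data.frame(pos = start + seq_len(nrow(xyz)),
                              frag_id = ids[k], bead = seq_len(nrow(xyz)))
  }
  list(coords = coords, origin = do.call(rbind, origin))
}

#' A cache for fragment-merging alignment scores
#'
#' Tentative chain scores are memoized on the ordered oriented-fragment
#' tuple; hits return bit-identical scores to recomputation.
#'
#' @return an environment usable as the `cache` argument of
#'   [grow_chain()] and [build_all_chains()].
#' @export
new_merge_cache <- function() new.env(parent = emptyenv())

chain_tuple_key <- function(ids, orients) {
  paste(ifelse(orients == "forward", ids, -ids), collapse = ",")
}

score_chain_tuple <- function(fragments, ids, orients, predicted, params,
                              cache = NULL) {
  key <- chain_tuple_key(ids, orients)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  cc <- concat_fragments(fragments, ids, orients, spacing = params$spacing)
  cm <- contacts_from_coords(cc$coords, cutoff = params$contact_cutoff,
                             min_separation = params$min_separation)
  score <- align_contact_maps(cm, predicted,
                              gap_open = params$gap_open,
                              gap_extend = params$gap_extend,
                              max_iterations = params$align_max_iterations,
                              tolerance = params$align_tolerance)$score
  if (!is.null(cache)) cache[[key]] <- score
  score
}

assembly_params <- function(contact_cutoff = 8, min_separation = 5,
                            spacing = 3.8, join_distance = 11,
                            gap_open = -1.0, gap_extend = -0.1,
                            align_max_iterations = 20, align_tolerance = 1e-6) {
  list(contact_cutoff = contact_cutoff, min_separation = min_separation,
       spacing = spacing, join_distance = join_distance,
       gap_open = gap_open, gap_extend = gap_extend,
       align_max_iterations = align_max_iterations,
       align_tolerance = align_tolerance)
}

#' Grow one chain greedily from a fragment pool
#'
#' The seed is the single oriented fragment with the best contact-map
#' alignment score against the chain's predicted contacts (ties: lowest
#' id, forward first). At each step every unused candidate neighbor is
#' tentatively appended at the tail or prepended at the head in both
#' orientations; the best-scoring extension is kept unless it would
#' lower the current score. Score-neutral extensions are accepted
#' (secondary-structure segments often carry no min-separation contacts
#' of their own), with ties resolved toward the spatially closest join.
#' Growth stops when every extension would lower the score, when all
#' combinations have been tested, or after `max_iterations` accepted
#' extensions. All tentative scores go through the cache.
#'
#' @param fragments list of `ca_fragment` (the available pool).
#' @param predicted a [contact_map()] of predicted contacts for this
#'   chain.
#' @param params an [assembly_params()] list.
#' @param cache a [new_merge_cache()] (or NULL to disable caching).
#' @param max_iterations cap on accepted growth steps; default
#'   `10 * length(fragments)`.
#' @return object of class `chain_model`: `ids`, `orients`, `score`,
#'   `coords` (padded), `origin`, `unassigned` flag.
#' @export
grow_chain <- function(fragments, predicted, params = assembly_params(),
                       cache = new_merge_cache(), max_iterations = NULL) {
  stopifnot(length(fragments) >= 1L, inherits(predicted, "contact_map"))
  if (nrow(predicted$pairs) == 0L)
    return(empty_chain_model())
  if (is.null(max_iterations)) max_iterations <- 10L * length(fragments)
  ends <- fragment_ends(fragments)
  all_ids <- vapply(fragments, function(f) as.integer(f$id), 1L)

  # seed
  seed_scores <- vapply(seq_len(nrow(ends$tab)), function(r)
    score_chain_tuple(fragments, ends$tab$id[r], ends$tab$orient[r],
                      predicted, params, cache), 0)
  ord <- order(-seed_scores, ends$tab$id,
               match(ends$tab$orient, c("forward", "reversed")))
  best_r <- ord[1]
  if (seed_scores[best_r] <= 0) return(empty_chain_model())
  ids <- ends$tab$id[best_r]
  orients <- ends$tab$orient[best_r]
  score <- seed_scores[best_r]

  steps <- 0L
  repeat {
    if (steps >= max_iterations) break
    cc_now <- concat_fragments(fragments, ids, orients, params$spacing)
    chain_head <- cc_now$coords[match(TRUE, stats::complete.cases(cc_now$coords)), ]
    real <- which(stats::complete.cases(cc_now$coords))
    chain_tail <- cc_now$coords[real[length(real)], ]
    cand <- list()
    for (r in seq_len(nrow(ends$tab))) {
      gid <- ends$tab$id[r]
      if (gid %in% ids) next
      # append: chain tail -> head of g
      gap_app <- sqrt(sum((chain_tail - ends$head[r, ])^2))
      if (gap_app <= params$join_distance)
        cand[[length(cand) + 1L]] <- list(ids = c(ids, gid),
                                          orients = c(orients, ends$tab$orient[r]),
                                          id = gid, orient = ends$tab$orient[r],
                                          side = 1L, gap = gap_app)
      # prepend: tail of g -> chain head
      gap_pre <- sqrt(sum((ends$tail[r, ] - chain_head)^2))
      if (gap_pre <= params$join_distance)
        cand[[length(cand) + 1L]] <- list(ids = c(gid, ids),
                                          orients = c(ends$tab$orient[r], orients),
                                          id = gid, orient = ends$tab$orient[r],
                                          side = 2L, gap = gap_pre)
    }
    if (length(cand) == 0L) break
    sc <- vapply(cand, function(x)
      score_chain_tuple(fragments, x$ids, x$orients, predicted, params, cache), 0)
    # ties: prefer the spatially closest join (the true continuation is
    # one residue step away), then append side, lowest id, forward
    pick <- order(-sc,
                  vapply(cand, `[[`, 0, "gap"),
                  vapply(cand, `[[`, 1L, "side"),
                  vapply(cand, `[[`, 1L, "id"),
                  match(vapply(cand, `[[`, "", "orient"), c("forward", "reversed")))[1]
    # Accept score-neutral extensions too: secondary-structure segments
    # often carry no min-separation contacts of their own, so a correct
    # extension can leave the score unchanged until the next segment
    # closes a long-range contact. Each fragment is consumed at most
    # once, so growth still terminates.
    if (sc[pick] < score) break
    ids <- cand[[pick]]$ids
    orients <- cand[[pick]]$orients
    score <- sc[pick]
    steps <- steps + 1L
    if (length(ids) == length(all_ids)) break
  }
  cc <- concat_fragments(fragments, ids, orients, params$spacing)
  structure(list(ids = ids, orients = orients, score = score,
                 coords = cc$coords, origin = cc$origin,
                 register = NULL, sequence = NULL, chain_id = NULL,
                 unassigned = FALSE),
            class = "chain_model")
}

empty_chain_model <- function() {
  structure(list(ids = integer(0), orients = character(0), score = -Inf,
                 coords = matrix(numeric(0), 0, 3), origin = NULL,
                 register = NULL, sequence = NULL, chain_id = NULL,
                 unassigned = TRUE),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  if (x$unassigned) { cat("<chain_model> unassigned\n"); return(invisible(x)) }
  cat(sprintf("<chain_model%s> %d fragments (%s), score %.4f, %d beads (%d padded)\n",
              if (is.null(x$chain_id)) "" else paste0(" ", x$chain_id),
              length(x$ids),
              paste(ifelse(x$orients == "forward", x$ids, -x$ids), collapse = ","),
              x$score, nrow(x$origin), nrow(x$coords)))
  invisible(x)
}

#' Build and commit all chains from a shared fragment pool
#'
#' A tentative chain is grown for every chain id from the current pool;
#' the highest-scoring one is committed and its fragments removed; the
#' remaining chains are rebuilt from the reduced pool, until every chain
#' is committed. Committed chains are mutually fragment-disjoint -- this
#' is the contact-driven segmentation of the map.
#'
#' @param fragments list of `ca_fragment`.
#' @param predicted_per_chain named list of [contact_map()] objects, one
#'   per chain id.
#' @param params an [assembly_params()] list.
#' @param caches optional named list of [new_merge_cache()] environments,
#'   one per chain id (scores depend on the chain's predicted map, so
#'   caches are never shared across chains).
#' @return list with `chains` (named list of `chain_model`, in commit
#'   order) and `leftover` (unused fragments).
#' @export
build_all_chains <- function(fragments, predicted_per_chain,
                             params = assembly_params(),
                             caches = NULL) {
  stopifnot(length(predicted_per_chain) >= 1L,
            !is.null(names(predicted_per_chain)))
  if (is.null(caches)) {
    caches <- lapply(predicted_per_chain, function(x) new_merge_cache())
  }
  pool <- fragments
  pending <- names(predicted_per_chain)
  chains <- list()
  while (length(pending) > 0L) {
    tentative <- lapply(pending, function(cid) {
      if (length(pool) == 0L) return(empty_chain_model())
      grow_chain(pool, predicted_per_chain[[cid]], params, caches[[cid]])
    })
    scores <- vapply(tentative, `[[`, 0, "score")
    best <- order(-scores, pending)[1]
    ch <- tentative[[best]]
    ch$chain_id <- pending[best]
    if (ch$unassigned)
      warning("chain ", pending[best], " has no assignable fragments")
    chains[[pending[best]]] <- ch
    pool <- Filter(function(f) !(f$id %in% ch$ids), pool)
    pending <- pending[-best]
  }
  list(chains = chains, leftover = pool)
}

#' Register a sequence onto a chain model
#'
#' The final contact-map alignment of the chain against its predicted
#' contacts provides the correspondence between bead positions and
#' sequence positions; beads outside the mapping carry no register.
#'
#' @param chain a `chain_model`.
#' @param predicted the chain's predicted [contact_map()].
#' @param sequence amino-acid string; its length must equal
#'   `predicted$n`.
#' @param params an [assembly_params()] list.
#' @return the chain with `register` (integer per real bead, NA where
#'   unregistered), `sequence`, and `score` updated.
#' @export
register_sequence <- function(chain, predicted, sequence,
                              params = assembly_params()) {
  if (nchar(sequence) != predicted$n)
    stop("sequence length (", nchar(sequence),
         ") does not match predicted contact map size (", predicted$n, ")")
  if (chain$unassigned || nrow(chain$coords) == 0L) {
    chain$register <- integer(0)
    chain$sequence <- sequence
    return(chain)
  }
  cm <- contacts_from_coords(chain$coords, cutoff = params$contact_cutoff,
                             min_separation = params$min_separation)
  al <- align_contact_maps(cm, predicted, gap_open = params$gap_open,
                           gap_extend = params$gap_extend,
                           max_iterations = params$align_max_iterations,
                           tolerance = params$align_tolerance)
  real <- which(stats::complete.cases(chain$coords))
  reg <- al$mapping[real]
  reg[reg == 0L] <- NA_integer_
  chain$register <- reg
  chain$sequence <- sequence
  chain$score <- al$score
  chain$unassigned <- all(is.na(reg))
  chain
}

#' Fragment an externally supplied trace at contact-alignment gaps
#'
#' The trace's contact map is aligned to the predicted map; the trace is
#' cut wherever the alignment skips strictly more than `gap_min` residues
#' (on either the trace or the sequence side). Used iteratively with
#' [grow_chain()] to correct mis-threaded manual traces.
#'
#' @param trace_xyz ordered n x 3 C-alpha coordinates.
#' @param predicted the chain's predicted [contact_map()].
#' @param gap_min cut only at gaps strictly longer than this (residues).
#' @param params an [assembly_params()] list.
#' @param min_fragment_beads drop resulting pieces shorter than this.
#' @return list of `ca_fragment`.
#' @export
fragment_by_alignment_gaps <- function(trace_xyz, predicted, gap_min = 4,
                                       params = assembly_params(),
                                       min_fragment_beads = 5) {
  trace_xyz <- matrix(as.numeric(trace_xyz), ncol = 3L)
  n <- nrow(trace_xyz)
  stopifnot(n >= 2L)
  cm <- contacts_from_coords(trace_xyz, cutoff = params$contact_cutoff,
                             min_separation = params$min_separation)
  al <- align_contact_maps(cm, predicted, gap_open = params$gap_open,
                           gap_extend = params$gap_extend,
                           max_iterations = params$align_max_iterations,
                           tolerance = params$align_tolerance)
  sup <- which(al$mapping > 0)
  cuts <- integer(0)
  if (length(sup) > 1L) {
    dA <- diff(sup) - 1L
    dB <- diff(al$mapping[sup]) - 1L
    cuts <- sup[which(pmax(dA, dB) > gap_min)]    # cut after this position
  }
  if (length(sup) > 0L) {
    # unaligned leading/trailing runs longer than gap_min become their
    # own fragments (e.g. a mis-threaded block the alignment rejected)
    if (sup[1] - 1L > gap_min) cuts <- c(sup[1] - 1L, cuts)
    if (n - sup[length(sup)] > gap_min) cuts <- c(cuts, sup[length(sup)])
  }
  bounds <- c(0L, sort(unique(cuts)), n)
  frags <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
    if (hi - lo + 1L >= min_fragment_beads)
      frags[[length(frags) + 1L]] <-
        structure(list(xyz = trace_xyz[lo:hi, , drop = FALSE],
                       id = length(frags) + 1L),
                  class = "ca_fragment")
  }
  frags
}

#' Segment a density map by chain proximity
#'
#' Each voxel above `threshold` is assigned to the chain of its nearest
#' bead if that bead is within `radius`; assignments are disjoint, with
#' equidistant voxels going to the earlier chain id. Per-chain maps keep
#' the original densities at assigned voxels and are zero elsewhere.
#'
#' @param map a [density_map()].
#' @param chains named list of `chain_model` (or any objects with
#'   `coords`).
#' @param radius maximum bead-voxel distance (A).
#' @param threshold voxel inclusion threshold (map units).
#' @return named list of [density_map()] masks, one per chain.
#' @export
segment_map <- function(map, chains, radius = 5, threshold = 0) {
  stopifnot(length(chains) >= 1L)
  ids <- names(chains)
  if (is.null(ids)) ids <- as.character(seq_along(chains))
  vox <- which(map$values > threshold)
  ijk <- arrayInd(vox, dim(map$values))
  xyz <- grid_to_xyz(map, ijk)
  best_d <- rep(Inf, length(vox))
  assign <- rep(NA_integer_, length(vox))
  for (k in seq_along(chains)) {
    beads <- chains[[k]]$coords
    beads <- beads[stats::complete.cases(beads), , drop = FALSE]
    if (nrow(beads) == 0L) next
    nn <- cpp_nearest(xyz, beads)
    upd <- nn$dist < best_d & nn$dist <= radius
    best_d[upd] <- nn$dist[upd]
    assign[upd] <- k
  }
  out <- list()
  for (k in seq_along(chains)) {
    vals <- array(0, dim = dim(map$values))
    sel <- vox[which(assign == k)]
    vals[sel] <- map$values[sel]
    out[[ids[k]]] <- density_map(vals, map$voxel_size, map$origin,
                                 name = paste0(map$name, ":", ids[k]))
  }
  out
}
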