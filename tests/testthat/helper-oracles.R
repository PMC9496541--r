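# Independent oracles used across the suite. These deliberately use
# different algorithms and code paths than the package implementation.

# random contact map: pairs with separation >= min_sep kept with prob p
rand_contact_map <- function(n, p = 0.3, min_sep = 2) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= min_sep, , drop = FALSE]
  keep <- runif(nrow(pairs)) < p
  contact_map(n, pairs[keep, , drop = FALSE])
}

# exhaustive search over all strictly monotone partial mappings
oracle_best_alignment <- function(A, B, gap_open = -1, gap_extend = -0.1) {
  nA <- A$n; nB <- B$n
  best <- 0
  for (k in seq_len(min(nA, nB))) {
    ia <- utils::combn(nA, k)
    ib <- utils::combn(nB, k)
    for (ca in seq_len(ncol(ia))) {
      for (cb in seq_len(ncol(ib))) {
        m <- rep(0L, nA)
        m[ia[, ca]] <- ib[, cb]
        s <- alignment_objective(m, A, B, gap_open, gap_extend)
        if (s > best) best <- s
      }
    }
  }
  best
}

# exhaustive minimum spanning tree weight: try every (n-1)-edge subset
oracle_mst_weight <- function(n, edges, weights) {
  m <- nrow(edges)
  if (m < n - 1) return(NA_real_)
  best <- Inf
  subsets <- utils::combn(m, n - 1)
  for (s in seq_len(ncol(subsets))) {
    sel <- subsets[, s]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    for (e in sel) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (acyclic) best <- min(best, sum(weights[sel]))
  }
  best
}

# random connected sparse graph on n vertices with <= n + extra edges
rand_connected_graph <- function(n, extra = 4) {
  edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1, 1), 1L))
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  avail <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key), , drop = FALSE]
  n_extra <- min(extra, nrow(avail))
  if (n_extra > 0) {
    take <- sample.int(nrow(avail), n_extra)
    edges <- rbind(edges, avail[take, , drop = FALSE])
  }
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  list(n = n, edges = edges, weights = runif(nrow(edges), 0.1, 10))
}

# wrap a plain weighted graph so kruskal_mst accepts it
as_grid_graph <- function(g) {
  structure(list(xyz = matrix(seq_len(g$n), g$n, 3), ijk = NULL,
                 density = rep(1, g$n), edges = g$edges,
                 weights = g$weights, name = "test"),
            class = "grid_graph")
}

# Independent reimplementation of the two fork rules, adjacency-matrix
# style: at the fork whose smallest hanging branch is globally smallest
# (branch sizes saturated at Tp; ties: lowest fork vertex, then lowest
# branch member), delete that branch when it has < Tp beads, otherwise
# delete the fork vertex; repeat. Returns the kept vertex set.
oracle_prune_forks <- function(n, edges, Tp) {
  A <- matrix(FALSE, n, n)
  A[edges] <- TRUE
  A[edges[, c(2, 1), drop = FALSE]] <- TRUE
  alive <- rep(TRUE, n)
  reach <- function(start, banned) {
    seen <- rep(FALSE, n)
    seen[start] <- TRUE
    repeat {
      nxt <- (A %*% seen) > 0 & alive & !banned
      nxt <- as.vector(nxt) | seen
      if (all(nxt == seen)) return(which(seen))
      seen <- nxt
    }
  }
  repeat {
    deg <- vapply(seq_len(n), function(v)
      if (alive[v]) sum(A[v, ] & alive) else 0L, 0)
    forks <- which(deg >= 3)
    if (length(forks) == 0) break
    best <- NULL
    for (v in forks) {
      banned <- rep(FALSE, n); banned[v] <- TRUE
      for (u in which(A[v, ] & alive)) {
        arm <- reach(u, banned)
        sz <- min(length(arm), Tp)
        amin <- if (sz < Tp) min(arm) else Inf
        better <- is.null(best) || sz < best$sz ||
          (sz == best$sz && (v < best$v || (v == best$v && amin < best$amin)))
        if (better) best <- list(v = v, arm = arm, sz = sz, amin = amin)
      }
    }
    if (best$sz < Tp) {
      alive[best$arm] <- FALSE
    } else {
      alive[best$v] <- FALSE
    }
  }
  which(alive)
}

# random tree on n vertices with maximum degree 3 (rejection sampling)
rand_tree_deg3 <- function(n, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    edges <- cbind(2:n, vapply(2:n, function(v)
      sample.int(v - 1, 1), 1L))
    deg <- tabulate(c(edges[, 1], edges[, 2]), n)
    if (max(deg) <= 3) return(cbind(pmin(edges[, 1], edges[, 2]),
                                    pmax(edges[, 1], edges[, 2])))
  }
  NULL
}

# bead graph wrapper around an explicit edge list
as_bead_graph <- function(n, edges) {
  structure(list(xyz = cbind(seq_len(n), 0, 0), edges = edges,
                 anchor = rep(FALSE, n), flagged = logical(nrow(edges)),
                 spacing = 3.8, name = "test"),
            class = "bead_graph")
}

# Y-shaped bead graph: three arms of given bead counts joined at a fork
make_y_graph <- function(arms) {
  n <- 1L + sum(arms)
  xyz <- matrix(0, n, 3)
  edges <- NULL
  nxt <- 2L
  dirs <- rbind(c(1, 0, 0), c(-0.5, 0.87, 0), c(-0.5, -0.87, 0))
  for (a in seq_along(arms)) {
    prev <- 1L
    for (k in seq_len(arms[a])) {
      xyz[nxt, ] <- dirs[a, ] * 3.8 * k
      edges <- rbind(edges, c(prev, nxt))
      prev <- nxt
      nxt <- nxt + 1L
    }
  }
  structure(list(xyz = xyz, edges = edges, anchor = rep(FALSE, n),
                 flagged = logical(nrow(edges)), spacing = 3.8, name = "y"),
            class = "bead_graph")
}

# brute-force windowed overlap by direct per-residue enumeration
oracle_windowed_overlap <- function(model, predicted, window) {
  w <- (window - 1) / 2
  mk <- paste(model$pairs[, 1], model$pairs[, 2])
  vapply(seq_len(predicted$n), function(r) {
    hits <- 0L; tot <- 0L
    if (nrow(predicted$pairs) > 0) {
      for (e in seq_len(nrow(predicted$pairs))) {
        i <- predicted$pairs[e, 1]; j <- predicted$pairs[e, 2]
        if (abs(i - r) <= w || abs(j - r) <= w) {
          tot <- tot + 1L
          if (paste(i, j) %in% mk) hits <- hits + 1L
        }
      }
    }
    if (tot == 0L) NA_real_ else hits / tot
  }, 0)
}

# deterministic small scene shared by several tests (clean contacts)
tiny_fold_blocks <- c("helix:14", "coil:4", "helix:14", "coil:4", "strand:6",
                      "coil:4", "helix:14")
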