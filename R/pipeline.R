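# End-to-end orchestration with a single serializable configuration, so
# every run is reproducible from (inputs, config).

#' Pipeline configuration
#'
#' All thresholds of the tracing and assembly stages with their defaults:
#' density threshold (or the volume heuristic via `n_residues`), fork
#' pruning threshold `Tp`, 3.8 A bead spacing, 11 A join distance, 8 A
#' contact cutoff, probability cutoff 0.5, window 11, affine gap
#' penalties, and iteration caps.
#'
#' @param density_threshold numeric threshold, or `"auto"` to use the
#'   volume heuristic (requires `n_residues`).
#' @param n_residues total residue count, for the auto threshold.
#' @param volume_factor retained volume / expected protein volume.
#' @param min_component_vertices discard smaller skeleton components.
#' @param spacing,spacing_tolerance bead spacing target and tolerance
#'   (A).
#' @param Tp fork pruning threshold (beads).
#' @param min_fragment_beads discard shorter fragments.
#' @param join_distance maximum fragment end gap (A).
#' @param contact_cutoff C-alpha contact distance (A).
#' @param min_separation minimum contact sequence separation.
#' @param p_min predicted-contact probability cutoff.
#' @param gap_open,gap_extend alignment gap penalties.
#' @param align_max_iterations,align_tolerance alignment iteration
#'   controls.
#' @param window diagnostic window size (residues).
#' @param segment_radius map segmentation radius (A).
#' @param max_rounds refinement rounds for [run_refine_trace()].
#' @param seed RNG seed recorded with the run.
#' @return a named list of class `emthread_config`.
#' @export
emthread_config <- function(density_threshold = "auto", n_residues = NULL,
                            volume_factor = 1.5, min_component_vertices = 10,
                            spacing = 3.8, spacing_tolerance = 0.5, Tp = 5,
                            min_fragment_beads = 5, join_distance = 11,
                            contact_cutoff = 8, min_separation = 5,
                            p_min = 0.5, gap_open = -1.0, gap_extend = -0.1,
                            align_max_iterations = 20, align_tolerance = 1e-6,
                            window = 11, segment_radius = 5, max_rounds = 6,
                            seed = 0) {
  structure(as.list(environment()), class = "emthread_config")
}

config_params <- function(config) {
  assembly_params(contact_cutoff = config$contact_cutoff,
                  min_separation = config$min_separation,
                  spacing = config$spacing,
                  join_distance = config$join_distance,
                  gap_open = config$gap_open, gap_extend = config$gap_extend,
                  align_max_iterations = config$align_max_iterations,
                  align_tolerance = config$align_tolerance)
}

#' Trace C-alpha candidate fragments from a density map
#'
#' Stages: threshold the map, build the 26-neighbor density graph, take
#' its minimum spanning forest, prune to degree 3, regularize to 3.8 A
#' beads, resolve forks, and emit unbranched fragments.
#'
#' @param map a [density_map()] (or a path to an MRC file).
#' @param config an [emthread_config()].
#' @return list with `fragments`, `tree` (pruned skeleton), `bead_graphs`,
#'   `threshold`, `config`.
#' @export
run_trace <- function(map, config = emthread_config()) {
  if (is.character(map)) map <- read_mrc(map)
  threshold <- config$density_threshold
  if (identical(threshold, "auto")) {
    if (is.null(config$n_residues))
      stop("density_threshold = 'auto' requires n_residues in the config")
    threshold <- auto_threshold(map, config$n_residues, config$volume_factor)
  }
  graph <- build_grid_graph(map, threshold)
  forest <- kruskal_mst(graph)
  pruned <- prune_to_degree3(forest)
  comps <- tree_components(pruned, config$min_component_vertices)
  if (length(comps) == 0L)
    stop("no skeleton component with >= ", config$min_component_vertices,
         " vertices; lower the density threshold")
  fragments <- list()
  bead_graphs <- list()
  for (comp in comps) {
    bg <- regularize_beads(comp, spacing = config$spacing,
                           spacing_tolerance = config$spacing_tolerance,
                           map = map)
    bg <- prune_forks(bg, Tp = config$Tp)
    bead_graphs[[length(bead_graphs) + 1L]] <- bg
    frs <- tryCatch(extract_fragments(bg, config$min_fragment_beads),
                    error = function(e) list())
    fragments <- c(fragments, frs)
  }
  if (length(fragments) == 0L)
    stop("no fragment with >= ", config$min_fragment_beads, " beads")
  ord <- order(-vapply(fragments, function(f) nrow(f$xyz), 1L))
  fragments <- lapply(seq_along(ord), function(k) {
    f <- fragments[[ord[k]]]; f$id <- k; f
  })
  list(fragments = fragments, tree = pruned, bead_graphs = bead_graphs,
       threshold = threshold, config = config)
}

#' Assemble fragments into registered chains and segment the map
#'
#' @param fragments list of `ca_fragment` (e.g. from [run_trace()]).
#' @param contacts named list of [predicted_contacts()] (filtered at
#'   `config$p_min`) or ready [contact_map()] objects, one per chain.
#' @param sequences named character vector of chain sequences (names
#'   matching `contacts`).
#' @param config an [emthread_config()].
#' @param map optional [density_map()] for segmentation.
#' @return list with `chains` (registered `chain_model`s), `leftover`
#'   fragments, `report` (data.frame: chain, score, n_fragments,
#'   n_registered, coverage), and `masks` (per-chain segmented maps,
#'   when `map` is given).
#' @export
run_assemble <- function(fragments, contacts, sequences = NULL,
                         config = emthread_config(), map = NULL) {
  stopifnot(length(contacts) >= 1L, !is.null(names(contacts)))
  cms <- lapply(contacts, function(x) {
    if (inherits(x, "predicted_contacts")) filter_predicted(x, config$p_min)
    else x
  })
  if (!is.null(sequences)) {
    for (cid in names(cms)) {
      if (!cid %in% names(sequences)) next
      if (nchar(sequences[[cid]]) != cms[[cid]]$n)
        stop("sequence length for chain ", cid, " (",
             nchar(sequences[[cid]]), ") does not match its contact map n (",
             cms[[cid]]$n, ")")
    }
  }
  params <- config_params(config)
  built <- build_all_chains(fragments, cms, params)
  chains <- built$chains
  for (cid in names(chains)) {
    if (chains[[cid]]$unassigned) next
    seq_c <- if (!is.null(sequences) && cid %in% names(sequences))
      sequences[[cid]] else strrep("X", cms[[cid]]$n)
    chains[[cid]] <- register_sequence(chains[[cid]], cms[[cid]], seq_c, params)
  }
  report <- do.call(rbind, lapply(names(chains), function(cid) {
    ch <- chains[[cid]]
    data.frame(chain = cid, score = ch$score,
               n_fragments = length(ch$ids),
               n_registered = if (is.null(ch$register)) 0L
                              else sum(!is.na(ch$register)),
               coverage = if (is.null(ch$register)) 0
                          else sum(!is.na(ch$register)) / cms[[cid]]$n)
  }))
  masks <- NULL
  if (!is.null(map)) {
    live <- chains[!vapply(chains, `[[`, TRUE, "unassigned")]
    if (length(live) > 0)
      masks <- segment_map(map, live, radius = config$segment_radius,
                           threshold = if (is.numeric(config$density_threshold))
                             config$density_threshold else 0)
  }
  list(chains = chains, leftover = built$leftover, report = report,
       masks = masks, config = config)
}

#' Correct an externally supplied trace by iterated fragmentation and
#' concatenation
#'
#' The trace's contact map is aligned to the predicted contacts; the
#' trace is cut at alignment gaps longer than `gap_min` residues and the
#' pieces are re-concatenated by greedy contact-guided growth. The two
#' steps repeat until the alignment score stops improving or
#' `config$max_rounds` rounds.
#'
#' @param trace_xyz ordered n x 3 C-alpha coordinates (or a PDB path;
#'   CA atoms of the first chain are used).
#' @param predicted the chain's [predicted_contacts()] or
#'   [contact_map()].
#' @param config an [emthread_config()].
#' @param gap_min cut at alignment gaps strictly longer than this.
#' @return list with `chain` (final `chain_model`), `score_history`,
#'   `rounds`.
#' @export
run_refine_trace <- function(trace_xyz, predicted, config = emthread_config(),
                             gap_min = 4) {
  if (is.character(trace_xyz)) {
    ca <- read_ca_pdb(trace_xyz)
    ca <- ca[ca$chain == ca$chain[1] & ca$model == ca$model[1], ]
    trace_xyz <- as.matrix(ca[, c("x", "y", "z")])
  }
  trace_xyz <- matrix(as.numeric(trace_xyz), ncol = 3L)
  pcm <- if (inherits(predicted, "predicted_contacts"))
    filter_predicted(predicted, config$p_min) else predicted
  params <- config_params(config)
  score0 <- align_contact_maps(
    contacts_from_coords(trace_xyz, params$contact_cutoff, params$min_separation),
    pcm, params$gap_open, params$gap_extend,
    params$align_max_iterations, params$align_tolerance)$score
  history <- score0
  best <- list(coords = trace_xyz, score = score0, chain = NULL)
  for (round in seq_len(config$max_rounds)) {
    frags <- fragment_by_alignment_gaps(best$coords, pcm, gap_min = gap_min,
                                        params = params,
                                        min_fragment_beads = config$min_fragment_beads)
    if (length(frags) == 0L) break
    chain <- grow_chain(frags, pcm, params)
    if (chain$unassigned || chain$score <= best$score + 1e-9) {
      if (round == 1L)
        warning("refinement did not improve the trace; returning the input")
      break
    }
    real <- which(stats::complete.cases(chain$coords))
    best <- list(coords = chain$coords[real, , drop = FALSE],
                 score = chain$score, chain = chain)
    history <- c(history, chain$score)
  }
  if (is.null(best$chain)) {
    cc <- list(coords = trace_xyz,
               origin = data.frame(pos = seq_len(nrow(trace_xyz)),
                                   frag_id = 1L,
                                   bead = seq_len(nrow(trace_xyz))))
    best$chain <- structure(
      list(ids = 1L, orients = "forward", score = score0,
           coords = cc$coords, origin = cc$origin, register = NULL,
           sequence = NULL, chain_id = NULL, unassigned = FALSE),
      class = "chain_model")
  }
  list(chain = best$chain, score_history = history,
       rounds = length(history) - 1L)
}
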