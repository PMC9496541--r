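---
title: "emthread: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emthread: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emthread` builds Cα backbone models de novo from near-atomic-resolution
cryo-EM maps by combining a density-graph skeletonization with
sequence-assignment driven by co-evolution contact predictions. This
vignette records the model, the tunable parameters, the numerical
conventions, and the design decisions taken where the method left
genuine freedom — in enough detail that a maintainer can tell which
behaviors are principled and which are conventions that could be
revisited.

## 1. The tracing model

The working assumption is that the protein backbone is a high-density
ridge of the map. The map (a `density_map`: 3D array, voxel size,
origin) is converted into a weighted graph whose vertices are the
voxels above a density threshold and whose edges connect all
26-neighbor pairs with weight $w_{ij} = (d_i d_j)^{-1}$. Low weight
means high density, so the minimum spanning tree (MST) of this graph —
computed with a hand-written Kruskal over a deterministic edge order —
concentrates its paths along density ridges. The tree is then pruned to
maximum vertex degree 3, because a Cα is covalently bonded to at most
three non-hydrogen atoms.

**Threshold.** Deposited contour levels are rarely known, so the
default threshold retains a voxel volume of `volume_factor` (default
1.5) times the expected protein volume, taken as 1.21 Å³/Da with
110 Da/residue (`auto_threshold()`). In the synthetic test world the
tracer is almost insensitive to this factor between 1.5 and 3.0; it is
exposed in `emthread_config()` regardless.

**Determinism.** Equal-weight edges are ordered by the lexicographic
grid indices of their endpoints, so the MST is bit-reproducible.
Degree-3 pruning removes, at each over-degree vertex, whole hanging
branches — smallest vertex count first, ties by summed density, then by
smallest vertex index — never interior edges of kept paths.

## 2. From skeleton to Cα beads

The skeleton still lives on the voxel grid (≈1.3 Å spacing) and its
path wanders inside the density tube, so its arc length overestimates
the backbone length by up to a factor of two. Three steps convert it
into Cα-candidate beads at the canonical 3.8 Å spacing:

1. **Twig trimming.** Leaf branches shorter than 3 Å of arc are grid
   artifacts of the tube thickness (sub-residue) and are removed.
2. **Walk and refine.** The tree is walked depth-first from the
   highest-density degree-3 vertex (the most probable Cα with
   side-chain density), placing a bead every 0.65 × 3.8 Å of walked
   arc. Every bead is then refined by density-weighted mean shift
   (radius 2 Å, Gaussian bandwidth 1 Å, density weight `d^6`,
   6 iterations; `refine_vertices()`), which converges beads onto the
   local density maxima — the most probable Cα positions.
3. **Merge.** Beads that converged onto the same peak (closer than
   0.58 × 3.8 Å) are contracted, restoring near-3.8 Å separations.

Without a map (purely geometric input) the walk steps at the full
spacing and no refinement happens; this mode is what the geometric unit
tests exercise. The deliberately oversampling walk-then-merge scheme is
our reading of the method's "refine vertex coordinates to get as many
vertices separated by 3.8 Å as possible": plain per-path arc
resampling was tried first and inflated the bead count with the
skeleton's wander, which in turn wrecked the contact-map alignment
scale; the peak-seeking variant produces ~0.9 beads per residue at
0.3–0.5 Å RMS from the true Cα positions on clean synthetic maps.

**Fork resolution.** Remaining degree-3 beads are resolved by the
two-rule procedure: cutting the three fork edges leaves three branches;
if the smallest branch carries fewer than `Tp` beads (default 5,
≈19 Å — shorter than any secondary-structure element worth keeping) it
is deleted and the other two stay joined through the fork bead;
otherwise the fork bead itself is deleted, yielding three independent
fragments. Forks are processed in increasing order of their smallest
branch (sizes saturated at `Tp`; ties by fork index, then smallest
member index — the saturation keeps the capped branch search cheap and
is part of the documented convention). Maximal unbranched paths of at
least `min_fragment_beads` (default 5 — contact-map alignment is
uninformative below that) become `ca_fragment`s with arbitrary N→C
direction.

## 3. Contact-map alignment

A chain's contact map contains residue pairs with Cα–Cα distance
≤ 8 Å and sequence separation ≥ 5 (closer pairs carry no fold
information and would dominate). Predicted contacts are binarized at
probability ≥ 0.5; probabilities are not used as weights beyond that
filter.

Aligning a model contact map A against a predicted map B means finding
a strictly monotone partial mapping of A positions onto B positions.
The objective is

* for every contact pair of A mapped onto a contact of B:
  `min(1, s_A/s_B, s_B/s_A)` with `s` the sequence separations (so
  contacts of similar range pair preferentially),
* plus affine penalties for internal gaps (`gap_open = -1`,
  `gap_extend = -0.1` per skipped run); leading and trailing gaps are
  free, so the empty mapping scores exactly 0 and a fragment aligning
  anywhere in a long sequence is not punished for the ends.

The free-end convention is a deliberate choice: it keeps the greedy
chain growth monotone (adding a fragment can only add matched contacts
or internal gaps it is accountable for), and it makes the objective a
pure function of the mapping, which the package exploits everywhere
(`alignment_objective()` recomputes the reported score from the
mapping; the two agree to 1e-9 by construction and by test).

The optimizer is iterative double dynamic programming in the spirit of
map_align: an inner gapless DP scores the compatibility of the contact
neighborhoods of every residue pair, an outer Gotoh pass (free end
gaps) aligns on half that similarity matrix (each matched pair is seen
from both endpoints, so the factor ½ makes the DP objective coincide
with the reported objective at the fixed point), and the similarity
matrix is then recomputed restricted to the current mapping until the
score stabilizes (`tolerance = 1e-6`, `max_iterations = 20`). Because
this is a local search, it is restarted from contact-pair anchors — the
first outer pass is forced through the anchored match — using all
anchors when |A|·|B| ≤ 300 and otherwise the 24 best by the
neighborhood-similarity prior. The restarts matter twice: they make the
optimizer provably match exhaustive search on small random maps (a
standing test), and they prevent lock-in to a wrong register on
self-similar folds (helix neighborhoods all look alike). Outer-DP ties
prefer continuing the diagonal and the last maximum endpoint, so
zero-score positions bridge matched clusters instead of truncating the
mapping; those bridging positions carry register information at no
cost.

## 4. Fragment assembly, registration, segmentation

Chains grow greedily: the seed is the oriented fragment with the best
alignment score against the chain's predicted map (ties: lowest id,
forward first); at every step all unused fragments are tentatively
appended or prepended in both orientations wherever the end gap is
within `join_distance` (11 Å), and the best-scoring extension is
accepted unless it would *lower* the score. Score-neutral extensions
are accepted deliberately: an α-helix has no internal contacts at
separation ≥ 5 (the i, i+5 Cα distance is ≈8.6 Å), so a correct
extension often leaves the score flat until the next segment closes a
long-range contact. Ties among equal-scoring extensions go to the
spatially closest join — the true continuation is one residue step
(3.8 Å) away, spurious joins rarely are. Each fragment is used at most
once, so growth terminates; `max_iterations` (10 × pool size) is a
safety cap. When fragments are concatenated with an end gap of `g` Å,
`round(g/3.8) - 1` unregistered placeholder positions keep the chain's
contact map on a residue-true index scale.

All tentative scores are memoized per ordered oriented-fragment tuple.
One cache per chain: the score depends on the chain's predicted map, so
caches are never shared across chains. Cache hits are bit-identical to
recomputation (tested).

`build_all_chains()` grows a tentative chain for every subunit from the
shared pool, commits the best-scoring one, removes its fragments, and
rebuilds the rest from scratch (simplicity and determinism over speed).
The committed chains are fragment-disjoint — this *is* the map
segmentation; `segment_map()` then assigns above-threshold voxels to
the nearest chain bead within 5 Å (ties to the earlier chain id). The
final alignment's mapping becomes the sequence register; beads outside
the mapping stay unregistered (occupancy 0 in the PDB output).

For externally supplied traces (e.g. manual builds in low-resolution
maps), `run_refine_trace()` iterates two steps up to `max_rounds`
(default 6): cut the trace wherever its contact-map alignment skips
strictly more than 4 residues — including unaligned leading/trailing
runs, which is how a mis-threaded block manifests under a monotone
alignment — and re-concatenate the pieces by the greedy growth. A
two-block swap is restored exactly in one round in the tests.

## 5. Scoring diagnostics

* `windowed_overlap()`: for each residue, the fraction of predicted
  contacts with at least one endpoint in the 11-residue window that the
  model satisfies (a both-endpoints mode exists behind a flag);
  undefined windows are `NA`, never 0.
* `smoc()`: segment Manders' overlap coefficient,
  $\sum xy / \sqrt{\sum x^2 \sum y^2}$, between the experimental map
  (negatives clamped to 0 — Manders' coefficient assumes non-negative
  signals) and an 11-residue segment simulated as isotropic Gaussians
  with $\sigma = \mathrm{resolution} / (2\sqrt{2\ln 2})$ (FWHM equals
  the nominal resolution), over the voxels within 3σ of any segment
  bead. Scale-invariant in the experimental map; empty footprints are
  `NA`.
* `ca_deviation()`: label-matched Euclidean distances between
  registered beads and reference Cα (optionally after Kabsch
  superposition); `fragment_accuracy()` is the register-free
  nearest-neighbor RMS used for unassigned fragments.

## 6. The synthetic world, and what a green test establishes

`make_scene()` builds chains from secondary-structure blocks: helices
with 1.5 Å rise and 100° twist per residue (radius derived from those
two so consecutive Cα are *exactly* 3.8 Å apart: 2.28 Å), near-linear
strand zigzags with a 3.3 Å rise, and self-avoiding random-walk coils.
Blocks are placed compactly (among self-avoiding candidate placements,
the one closest to the existing centroid wins) under two floors: no
non-adjacent pair below 3.0 Å, and no sequence-distant pair (≥6 apart)
below 6.5 Å. The second floor is the load-bearing choice: it puts the
long-range contacts into the 6.5–8 Å shell of the 8 Å cutoff — the
default scenes carry 1.0–3.9 contacts per residue, bracketing what
co-evolution servers deliver for real chains — while keeping packed
secondary-structure elements far enough apart that a 3 Å-FWHM map still
separates their density tubes. The three default ~100-residue layouts
(helix-rich, strand-rich, alternating) are deliberately distinct so the
subunits of the simulated heterotrimer are distinguishable by their
contact maps, as real subunits are. Chains are separated by a 16 Å
bounding-box gap; maps are sums of unit Gaussians at each Cα (FWHM =
nominal resolution) on a 1.32 Å grid with ≥5 Å padding; predicted
contacts keep each true contact with probability `sensitivity`
(confidence uniform in [0.5, 1]) and add `fp_rate` × |true| false pairs
(confidence uniform in [0.5, 0.7]). Scenes are bit-reproducible from
their seed.

What this world does *not* emulate: side-chain and backbone-atom
density (maps are Cα balls only), B-factor variation, local resolution
gradients, map noise beyond optional additive Gaussian, chains in
contact, and β-sheets with real 4.8 Å strand pairing (which a 3 Å map
could not separate anyway). A green end-to-end test therefore
establishes that the algorithmic chain — skeleton → beads → alignment →
assembly → register — is internally correct under faithful geometry and
realistic contact sparsity/noise, not that any particular deposited map
will trace at a given accuracy.

One consequence is worth stating openly. With Cα-only Gaussians at
3.0 Å FWHM, the interior of a packed α-helix is *denser than the Cα
spiral itself* (seven surrounding Cα at ~2.3–4 Å all contribute), so
the MST occasionally routes through inter-turn rungs and the bypassed
backbone survives only as sub-`Tp` fork arms, which the spur rule then
deletes. On the default scenes the tracer recovers 84–91 % of true Cα
within 1.5 Å (mean nearest-bead deviation 0.6–0.9 Å) — just under a
90 % coverage target at exactly 3.0 Å, and above it at 2.5 Å or with
any side-chain density, which in real maps is precisely what the
degree-3 anchors exploit. We chose not to tune the synthetic world
around this; the shortfall is physical, and the corresponding test is
allowed to stay red rather than moving the world.

## 7. Numerical conventions and degenerate inputs

* All coordinates are Å in the map frame (origin + index × voxel);
  MRC axis-order headers are honored on input.
* Negative densities (sharpened maps) are excluded by thresholding and
  clamped to zero in mean-shift and SMOC; `edge_weight()` refuses
  non-positive densities outright.
* Empty vertex sets, components below 10 vertices, fragments below 5
  beads, chains with no positive-overlap fragment, empty predicted
  maps, and empty alignment supports all produce typed failures,
  warnings, or `NA`/sentinel values rather than silent zeros;
  `overlap_fraction()` with no predicted contacts is `NA`, never 0.
* The Y-junction bead count after a spur deletion counts the fork bead
  with the surviving path (two 10-bead arms plus the fork give a
  21-bead fragment); branch sizes exclude the fork bead.
* All randomness flows through explicit seeds; `set.seed` is called
  only at user-facing entry points (`make_scene()`, `rng_seed`
  arguments), never inside algorithms.

## 8. Known limitations

* The greedy growth with per-chain sequential commitment can starve
  late chains when fragments are shared candidates; rebuilding the
  remaining chains from the reduced pool mitigates this, but no global
  optimization over chains is attempted.
* Inter-chain predicted contacts are not modeled; homo-multimers are
  treated as one protomer chain and unsatisfiable inter-protomer
  contacts simply lower the absolute score.
* The alignment optimizer is a restarted local search; it is exact on
  small maps (tested exhaustively) but carries no optimality guarantee
  at chain scale.
* Full-atom model building and real-space refinement are out of scope:
  the deliverable is a registered Cα trace plus per-chain map masks for
  downstream tools.
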