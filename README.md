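# emthread

De novo Cα backbone tracing and sequence assignment for near-atomic
resolution (3–5 Å) cryo-EM density maps, guided by residue–residue
contacts predicted from sequence co-evolution.

At 3–5 Å resolution, side-chain density is too poor to read the sequence
directly off the map, and segmenting a multi-subunit map into chains is
itself unsolved when no homologous structures exist. `emthread`
addresses both problems at once:

1. **Tracing.** The map is turned into a weighted graph G(V, E): vertices
   are the voxels above a density threshold, edges connect 26-neighbor
   voxels, and the edge weight is the inverse density product
   w_ij = (d_i · d_j)⁻¹. The minimum spanning tree of G (Kruskal)
   skeletonizes the high-density regions; the tree is pruned to maximum
   vertex degree three (a Cα binds at most three heavy atoms), vertex
   coordinates are refined onto the density peaks, beads are laid down
   at the canonical 3.8 Å Cα–Cα spacing, and remaining forks are
   resolved by deleting sub-threshold spurs (pruning threshold Tp) or
   splitting at the junction. The result is a set of unbranched Cα
   candidate fragments of unknown N→C direction.
2. **Assembly, registration, segmentation.** Each chain's predicted
   contacts (e.g. CASP-RR files from a co-evolution server, binarized at
   probability ≥ 0.5) form a reference contact map. Fragments are
   concatenated greedily — both directions tested, ends joined within
   11 Å — so as to maximize an iterative double-dynamic-programming
   alignment between the growing chain's 8 Å Cα contact map and the
   predicted map (a re-implementation of the map_align idea: maximize
   overlapping contacts, penalize gaps). Chains are built from a shared
   fragment pool and committed best-score-first, which simultaneously
   segments the map into subunits; the final alignment registers the
   sequence onto the beads.
3. **Diagnostics.** Sliding-window (11-residue) predicted-contact
   overlap profiles, the segment Manders' overlap coefficient (SMOC)
   between model-simulated and experimental density, and label-matched
   Cα deviations against a reference.

A synthetic-scene generator (ground-truth traces built from
helix/strand/coil blocks, Gaussian-blurred maps on a 1.32 Å grid, noisy
predicted contacts with tunable sensitivity and false-positive rate)
makes the whole pipeline testable fully offline.

## Worked example

```r
library(emthread)

scene <- make_scene(n_chains = 3, rng_seed = 1,      # 3 x 100 residues
                    resolution = 3.0, sensitivity = 0.8, fp_rate = 0.05)
cfg <- emthread_config(n_residues = 300)

tr  <- run_trace(scene$map, cfg)                     # fragments from the map
res <- run_assemble(tr$fragments, scene$predicted,   # chains + register
                    scene$sequences, cfg, map = scene$map)
res$report
#>   chain     score n_fragments n_registered coverage
#> 1     B 11.502124           1           88     0.88
#> 2     A  9.059262           1           88     0.88
#> 3     C  8.992335           1           86     0.86

ca_deviation(res$chains$B, scene$chains$B)$mean      # label-matched Ca error
#> [1] 1.355733
```

Here the tracer found one fragment per chain (86.7 % of the true Cα
positions are within 1.5 Å of a bead; register-free fragment accuracy
0.35 Å RMS), the contact-driven assembly assigned 100 % of the beads to
the correct subunit without any prior segmentation, and the committed
chains register 86–88 of 100 residues each; `score` is the contact-map
alignment objective (matched predicted contacts minus gap penalties)
and `coverage` the registered fraction of the sequence. The mean
label-matched Cα deviation of ~1.4 Å for chain B is what the sliding
window diagnostics (`windowed_overlap()`, `smoc()`) localize when the
register drifts.

External inputs use standard formats: `read_mrc()` / `write_mrc()`
(MRC/CCP4 mode 2), `read_rr()` (CASP RR contacts), `read_fasta()`,
`read_ca_pdb()` / `write_chains_pdb()`. A thin command-line wrapper
with `trace` / `assemble` / `refine` / `score` / `simulate` subcommands
is installed at `system.file("cli", "emthread", package = "emthread")`.
The `refine` mode (`run_refine_trace()`) corrects an externally traced
backbone by iterated fragmentation at contact-alignment gaps (> 4
residues) and re-concatenation.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a seeded synthetic scene —
tracing the simulated 3 Å map, assembling and registering the three
chains against noisy predicted contacts, segmenting the map — and
prints the tracer coverage, per-chain scores, predicted-contact
overlaps and Cα deviations, writing its JSON summary to `--out`.
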