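---
title: "Prioritizing target genes from TAD disruption and promoter-capture interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing target genes from TAD disruption and promoter-capture interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tadcapture)
```

## The analysis in one paragraph

Chromosomes fold into topologically associated domains (TADs): regions
whose loci contact each other far more often than they contact loci across
a domain boundary. When a boundary moves between two cell states — say a
normal and a cancerous epithelial line — genes can change domains and fall
under the influence of enhancers they were previously insulated from.
`tadcapture` integrates three layers of evidence to nominate genes whose
upregulation plausibly follows from such boundary shifts: Hi-C contact
maps (domain-scale architecture), promoter-capture Hi-C interaction tables
(fine-scale enhancer–promoter loops anchored at captured promoter
fragments, the *baits*), and a differential-expression table. A gene is
reported as a candidate target only when four criteria hold jointly: its
bait shows strong capture-count evidence, at least one of its significant
interactions lands on an enhancer-like element, it lies in a disrupted
TAD, and it is significantly upregulated.

## The pipeline, step by step

**1. Promoter-interacting regions.** Interaction records (ibed or chinput
tables) carry a read count and a significance score in the style of
capture-Hi-C score pipelines. `filter_significant()` keeps records with
score ≥ 5 that are either trans-chromosomal or separated by ≥ 10 kb
between fragment midpoints. Both cutoffs are the field's conventional
ones and are exposed as parameters (`score_min`, `min_distance`). The
score itself is consumed, not computed: re-deriving a convolved
background model is out of scope, and any upstream scorer's output can be
ingested.

**2. Capture accounting.** `per_bait_counts()` and
`per_chromosome_counts()` tally significant interactions; a gene's
*capture count* is the number of significant interactions anchored at its
bait fragment(s). `share_proportions()` converts per-condition totals to
printed-style percentages (round-half-away-from-zero, with the unrounded
shares returned alongside because the rounded ones need not sum to 100).

**3. Differential interactions.** `differential_score()` is a deliberate
stand-in for a full negative-binomial GLM differential pipeline: per
(bait, other-end) pair it runs a two-sided exact binomial test of the
case count against the library-share null, adjusts across pairs with
Benjamini–Hochberg, and reports `diff_score = -log10(adjusted p)` with
significance at > 5, mirroring the score semantics of dedicated
differential capture-Hi-C tools. Pairs are formed over the union of both
tables (a missing pair counts 0; 0/0 pairs carry no evidence and are
dropped). Real differential tables can be ingested in its place. The
test is antisymmetric under swapping conditions, which the test suite
asserts. Differential pairs are restricted to ±500 kb around the bait
(`window_filter()`), matching how differential interactions are usually
windowed for interpretation.

**4. TAD calling and classification.** `call_tad_boundaries()` computes a
multi-window insulation score: for a boundary position before bin *i* and
window *w*, the mean count of the *w*×*w* square of contacts crossing the
position, averaged over window sizes from `min_depth` (60 kb) to
`max_depth` (120 kb) in `step` (20 kb) increments — the common
parameterization for 20-kb-bin matrices. Boundaries are local minima
whose prominence against the flanking maxima exceeds `delta`. This is an
interface-compatible desk-scale caller, not a re-implementation of a full
Hi-C toolchain; externally called boundary BED files can bypass it
entirely. `pair_tads()` matches each condition-A TAD to the condition-B
TAD of maximal base-pair overlap, and `classify_tad_pairs()` labels a
pair *conserved* iff the two TADs contain exactly the same gene set, else
*disrupted*. `affected_genes()` is the union of gene sets over disrupted
pairs, with a biotype tally.

**5. The staged bait cascade.** STAGE 1 keeps baits with a non-zero count
and an absolute case-control capture-count difference ≥ 10; STAGE 2
intersects with baits carrying at least one significant differential
interaction; STAGE 3 intersects with the baits of TAD-affected genes.
The nesting STAGE3 ⊆ STAGE2 ⊆ STAGE1 is enforced structurally and
asserted. STAGE 3 other ends are annotated with SCREEN-style cCRE
classes (PLS, pELS, dELS, DNase-H3K4me3, CTCF); an other end can carry
several classes but counts once per class.

**6. Selection.** `select_target_genes()` reports genes satisfying the
four-criterion conjunction, ranked by descending capture count (ties:
larger log2 fold change, then gene id) and optionally truncated to
`top_k`. A diagnostics table evaluates every gene against each criterion
independently, so an excluded gene's elimination is attributable to the
specific criteria it fails.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `score_min` | 5 | score | conventional significance cutoff for promoter-interacting regions |
| `min_distance` | 10,000 | bp | removes short-range ligation noise between near-adjacent fragments |
| `diff_threshold` | 5 | −log10 p | conventional differential-score cutoff |
| `diff_window` | 500,000 | bp | window around the bait for differential interpretation |
| `min_diff` | 10 | interactions | STAGE 1 capture-count difference |
| `fdr_max` | 0.05 | FDR | DE significance |
| `min_depth`/`max_depth`/`step` | 60/120/20 kb | bp | insulation windows for 20-kb bins |
| `delta` | 0.01 × mean insulation | score | boundary prominence; relative form makes calls invariant under uniform count scaling |

## Design choices where the design was genuinely open

- **Gene-in-TAD membership is TSS-based** (`[start, end)` containment of
  the transcription start site). Body overlap would let one gene sit in
  two adjacent TADs, which is incompatible with classifying domain pairs
  by gene-set equality; a `"body"` mode exists for exploratory use. TSS
  is `start` on `+` and `end − 1` on `−`.
- **Pairing ties** go to the earlier-starting condition-B TAD, making the
  argmax deterministic.
- **STAGE 1 "non-zero count"** is read as non-zero in *at least one*
  condition (`nonzero = "either"`): a bait silenced in one condition is
  precisely the interesting case. The stricter both-nonzero reading is
  available (`nonzero = "both"`).
- **Enhancer-loop evidence** accepts pELS and dELS classes only —
  promoter-like, DNase-H3K4me3 and CTCF elements are not enhancer loops.
- **Distance convention** is midpoint-to-midpoint, symmetric in the two
  fragments. Trans-chromosomal pairs have no distance and pass the
  distance filter by definition (they are retained, flaggable
  downstream).
- **Bait-to-gene tallies** default to once-per-gene (a bait annotated to
  two genes contributes to both); capture counts sum over a gene's baits.
- **`require_de_gene`** (classify only TAD pairs containing a DE gene) is
  off by default in the library; switching it on reproduces the stricter
  replication profile and does not change which planted targets are
  recovered, since planted targets are themselves DE.

## The synthetic world

`simulate_world()` builds a deterministic, seeded world in which every
pipeline claim is checkable against planted truth:

- **Genome**: 2 chromosomes × 10 Mb, 20-kb matrix bins, 10-kb restriction
  fragments, 120 genes (half protein-coding); desk-scale sizes chosen so
  a full world plus pipeline runs in roughly a second.
- **TADs**: 10 per chromosome with spans ≥ 3× the boundary shift. In the
  control condition a run of consecutive boundaries is shifted by
  `shift_bp` (100 kb); one planted *mover* gene inside each shifted
  window guarantees the flanking pairs differ in gene content. A run of
  D−1 consecutive shifts disrupts exactly D pairs, so the planted
  disrupted fraction is exact; background genes avoid shift windows and
  boundary margins so no pair is disrupted accidentally.
- **Interactions**: each bait receives ~30 candidate other ends within
  15–600 kb; counts are negative-binomial with mean
  `mean_reads · (d / 50 kb)^(−decay_exponent)` (defaults 50 and 1) and
  dispersion `nb_dispersion` (0.05). Planted enhancer–promoter loops (15
  per target, at 20–120 kb) multiply the case-condition mean by
  `loop_fold` (4). Scores are the −log10 upper-tail probability of the
  observed count under the *no-loop* expectation — calibrated by
  construction, so at the default fold a closed-form NB tail calculation
  puts per-loop detection at ~0.91–0.98 across that distance band, and a
  15-loop bait clears the STAGE 1 difference of 10 with high margin.
  With `loop_fold = 1` planted loops are exactly null and score ≥ 5 at
  the background false-positive rate (~10⁻⁵).
- **Decoys**, one per violated criterion: `no_loop` (loops without any
  enhancer element at their other ends — the cCRE track explicitly
  excludes them), `conserved_tad`, `not_upregulated` (negative fold
  change at FDR 0.001), `low_capture` (3 loops, below the STAGE 1
  difference). Planted genes never share a bait fragment with each other
  or with background genes, so criterion violations stay localized.
- **Contact matrices**: expected count 10 within each condition's TADs
  over a background of 1, Poisson-sampled and symmetrized.

What the generator does *not* emulate: restriction-fragment length
heterogeneity, GC/mappability bias, trans-chromosomal contacts, the heavy
inter-replicate dispersion of real capture libraries, TAD hierarchies and
nested sub-domains, and realistic cCRE densities. Passing the synthetic
suite therefore demonstrates the *logic* of the cascade — filters,
set algebra, classification, ranking, determinism — not performance on
real libraries, where score calibration and dispersion are controlled by
upstream tools.

## Numerical choices and degenerate inputs

- Rounded percentages use round-half-away-from-zero (printed-style), and
  the exact shares are always returned alongside.
- Adjusted p-values are floored so `diff_score` caps at 300 rather than
  overflowing to infinity.
- `common_gene_fraction()` on two empty sets is an error, not 0 or 1.
- Insulation minima on plateaus take the first position of the plateau; a
  constant matrix yields no boundaries.
- Readers reject inverted or non-integer coordinates with the offending
  line number; nothing is silently corrected. GTF input (1-based closed)
  is converted to the internal 0-based half-open convention on read.
- All randomness flows through R's RNG from a single seed; identical
  config and seed give byte-identical exports (fixed-format writers).

## Problem sizes used by the test suite

Oracle-equivalence suites run ≥ 1,000 random instances per operation
against brute-force enumerations; recovery runs 10 worlds (120 genes,
2,000 fragments, ~9,000 interaction pairs per condition each); the
boundary caller is checked on 20 noised 500-bin matrices; the threshold
monotonicity grid is 3×3×3 over `score_min`, `min_diff` and `fdr_max` on
one world. These sizes were chosen to exercise every code path at desk
scale.

## Known limitations

- The TAD caller is a single-resolution insulation method; hierarchical
  or compartment-aware callers will disagree near nested boundaries.
  External boundary files can be supplied instead.
- Gene-set equality is a brittle notion of conservation on real
  annotations, where a single lncRNA near a boundary flips a pair to
  disrupted; the classification is faithful to that definition rather
  than smoothing it.
- The binomial differential test ignores biological replicates and
  overdispersion; it is plumbing for the cascade, not an inference claim.
- `top_k` has no statistically principled default; ranking is by capture
  count and the cutoff is the analyst's.

## A worked run

```{r, eval = FALSE}
world <- simulate_world(simulation_config(seed = 1))
res <- run_world_pipeline(world)
res$report
attr(res$report, "diagnostics")

# file-based equivalent
dir <- tempfile(); export_world(world, dir)
res2 <- run_pipeline_dir(dir)
identical(res2$report$gene_id, res$report$gene_id)
```
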