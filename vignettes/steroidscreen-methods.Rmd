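---
title: "Methods: marker-anchored co-expression screening and dye-dilution quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-anchored co-expression screening and dye-dilution quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidscreen)
```

## The scientific problem

T helper 2 (Th2) cells are heterogeneous: within an in vitro polarised Th2
population, a subpopulation upregulates the full steroidogenic machinery —
cholesterol synthesis and uptake, mitochondrial cholesterol import through
the transduceosome, and the side-chain cleavage enzyme Cyp11a1 that
converts cholesterol to pregnenolone. These cells behave as suppressors:
their expression profile associates with the suppressor cytokines IL-10 and
TGF-β1 rather than with effector cytokines, and in co-culture they retard
the proliferation of responder T cells.

`steroidscreen` implements the computational arc of that discovery as a
reusable, tested pipeline:

1. **Pathway completeness scoring** of condition-level FPKM profiles — how
   far along the ordered steroidogenesis chain a condition can proceed, and
   which genes block it.
2. **A marker-anchored single-cell correlation screen** — Spearman
   correlation of every gene against an anchor (Cyp11a1 by default) across
   single cells, with gene-module extraction, cell clustering, and
   surface-marker nomination so the subpopulation can be purified by FACS.
3. **Dye-dilution proliferation quantification** — deconvolution of
   fluorescence events into cell generations, the division index, and
   suppression-assay statistics.
4. **Seeded synthetic-data generators** with planted ground truth that
   emulate the study's data structure, so every stage is validated by
   parameter recovery rather than by eyeball.

## Pathway completeness

A pathway is an ordered list of steps, each yielding a metabolite and
requiring a gene set; `any_of = TRUE` marks redundant alternatives (e.g.
the three voltage-dependent anion channels, or synthesis vs uptake as
cholesterol sources). A gene counts as *detected* in a condition when its
FPKM exceeds the white point of the display ramp (3 FPKM by default, the
same value that renders as white in the usual heatmap colouring; 15 FPKM
saturates). The condition's *reach* is the metabolite of the last step in
an unbroken satisfied prefix, and `blocked_at` names the undetected genes
of the first unsatisfied step.

Two judgement calls are deliberately configuration rather than constants:

- **Interpolation** between the ramp endpoints is linear — the minimal
  assumption when only the endpoints are specified.
- **The detection cutoff for completeness equals the white point** (FPKM
  > 3). Whether genes in the 3–15 FPKM band should count as "expressed"
  for completeness purposes is a genuinely open question; both endpoints
  are arguments of `pathway_reach()`.

On the shipped archetypes, the Th2 profile reaches pregnenolone (with the
downstream branch enzymes Cyp17a1/Hsd3b1 undetected), the Th1 profile
stalls immediately before pregnenolone blocked at Cyp11a1, and the naive
profile reaches nothing:

```{r pathway}
reach <- pathway_reach(generate_pathway_table(noise_sd = 0),
                       default_steroidogenesis_pathway())
reach
```

## The anchor screen

`spearman_rho()` computes Spearman's ρ as the Pearson correlation of
mid-rank (average-tie) ranks — the standard convention, stated explicitly
because zero-inflated single-cell data is tie-heavy. The default p value
is the asymptotic t approximation `t = ρ√((n−2)/(1−ρ²))` on `n − 2`
degrees of freedom; a seeded permutation null is available where the
asymptotic form is distrusted at small n.

`anchor_screen()` correlates every gene against the anchor across **all**
cells, including cells where the anchor is undetected: zeros carry rank
information, and conditioning on anchor detection would bias ρ upward.
Genes constant across cells or detected in fewer than `min_detected_cells`
(default 3) are excluded and listed with reasons rather than silently
dropped. Two gene sets fall out of the records:

- `screened_genes`: ρ strictly greater than 0.3 (strict `>`, matching the
  screen's published form);
- `cell_cluster_genes`: ρ > 0.35 or ρ ≤ −0.35. The positive-or-negative
  band is the declared interpretation of an ambiguously printed threshold;
  both cutoffs are `screen_config()` fields.

Benjamini–Hochberg q values are computed across all tested genes in the
screen; discoveries in the recovery analyses are genes passing both the ρ
threshold and q ≤ 0.05. Records sort by ρ descending with ties broken by
gene symbol, making output order a pure function of the statistics.
`nominate_surface_markers()` is the same ranking restricted to annotated
surface receptors — the route by which a sortable marker (Ly6C in the
motivating study) is nominated.

## Clustering

**Genes.** `cluster_genes()` runs agglomerative clustering on the distance
`1 − ρ` with average linkage (robust for correlation distances; complete
and single linkage are available). The module partition cuts the
dendrogram at height `1 − threshold`. The anchor's own module is then
refined: walking the dendrogram upward from the anchor leaf, below the cut
height, the largest node whose mean off-diagonal ρ still exceeds the
threshold is kept. The "largest node that still passes" rule is used
because the smallest passing node is almost always the anchor's first
pair merge, which would truncate a genuine module; the height cap stops
weakly-linked unions of unrelated blocks from being absorbed when their
pooled mean correlation happens to stay above threshold.

**Cells.** `cluster_cells()` rank-standardises each gene across cells
(mid-ranks scaled to zero mean and unit variance — consistent with the
rank-based screen and insensitive to monotone distortions), clusters cells
with Ward linkage on Euclidean distance, and chooses k ∈ {2..6} by mean
silhouette width unless k is given. The anchor cell cluster is the cluster
with the highest mean anchor expression; the fraction of anchor-detected
cells captured inside it quantifies how cleanly the anchor-positive
subpopulation separates.

## Dye-dilution proliferation

A covalent tracing dye halves in intensity at every division, so on a log2
fluorescence scale generation peaks sit exactly 1.0 apart. This physical
constraint is imposed on the model: `assign_generations()` fits a 1-D
Gaussian mixture whose component means are fixed at `g0 − i` for
generations `i = 0..max_generations`, with one shared free σ (staining
coefficient of variation dominates peak width and a shared σ keeps the
fit identifiable at small event counts) and free weights, by EM. Counts
are soft posterior masses by default; hard nearest-mean assignment is
available, with midpoint ties resolved to the lower (brighter) generation.

Locating the undivided peak is the one genuinely delicate step: in a
fast-proliferating culture, generation 0 can be ~2% of events, so naive
peak-finding misses it. The `g0_center = "auto"` rule anchors the
generation grid at the dominant kernel-density mode, slides it brighter
one division at a time, and keeps the offset with the best mixture
likelihood (ties resolve so the brightest events are generation 0).
Events below `g0 − max_generations − 0.5` log2 units are dye-negative
debris outside the model; they are assigned to the last generation with a
warning. EM non-convergence raises a typed error with diagnostics rather
than returning a silently bad fit.

The **division index** — the average number of divisions per cell of the
starting population — down-weights each generation-i cohort to its
`n_i / 2^i` founding precursors:
`DI = Σ i·(n_i/2^i) / Σ (n_i/2^i)`. It is scale-invariant, zero exactly
when nothing divided, and strictly increasing whenever a cell moves up a
generation. `suppression_assay()` chains deconvolution and DI per
replicate, reports percent suppression `100·(1 − DI_cond/DI_ref)` against
the responder-alone reference, and compares conditions with the classic
equal-variance unpaired two-tailed t test (the test named by the assay's
standard write-up; Welch's form via `var_equal = FALSE`). Replicate
counts are arguments, not constants, because published "mean DI" values
rarely pin them down.

## The synthetic generators

The generators are first-class, tested code: they define the conditions
under which the pipeline's guarantees are demonstrated.

**Single-cell matrices.** Anchor and module genes share an equicorrelated
latent Gaussian block whose Pearson correlation is set by the exact latent
conversion `r = 2·sin(π·ρ_S/6)`, so the *rank* correlation — the quantity
the screen measures — is controlled analytically; at n = 2000 with no
dropout the realised pairwise Spearman ρ lands within ±0.05 of the
target. On top of the copula, cells in the planted subpopulation (30% by
default) get a mean shift on the anchor/module genes. The marginal is a
truncated log-normal on the log2 scale; excess zeros are then added with
a per-gene probability logistic in the gene's expressed-state mean, 30%
at the average. The off-state baseline (−2 log2 units, mostly truncated
to zero) together with a +7 shift makes anchor and module genes
essentially on/off — the regime of the steroidogenic subpopulation this
emulates, where Cyp11a1 is undetected outside the subpopulation. These
marginal parameters were fixed once at design time; the copula
calibration check is run without shift and dropout because the shift and
the zero ties deliberately add association beyond the copula's target.
Default scale is 91 cells split 52/39 across the G4P/G2N gates — fixture
flavour mirroring the motivating data set, not a tuned quantity.

What the generator does **not** emulate: library-size and batch effects,
read-level noise, gene-length bias, doublets, or cell-cycle structure.
Passing recovery tests therefore demonstrates the statistical machinery
under the declared model, not robustness to every artefact of real
single-cell data.

**Dye dilution.** Events are `2^(g0 − gen + N(0, σ))` with generations
drawn from stated proportions; truth records each event's generation.
DI-targeted experiments use a one-parameter geometric tilt
(`p_i ∝ q^i`), solved numerically for the target DI — a smooth family
that reaches any DI in `[0, G)`. Written sample sheets carry only
file/condition/replicate; planted truth never enters analysis-facing
files.

## Numerical and reproducibility choices

- All randomness flows through explicit seeds; generators save and
  restore the global RNG state, so they are pure functions of
  (config, seed). Pipeline stages derive named substreams from the root
  seed and record them in their manifests.
- Reports are written at 10 significant digits with deterministic field
  order; a rerun with the same (config, seed) is byte-identical, and
  reloading reproduces values exactly at that precision.
- EM tolerance is a relative log-likelihood change of 1e-8 (500-iteration
  cap); σ is floored at 1e-4 to avoid component collapse.
- Missing cells in input tables are hard errors, never imputed: silent
  zeros would corrupt rank statistics. Undetected qPCR reactions are an
  explicit NA sentinel and normalise to 0 via `e = max(0, LOD − Ct)`
  (default LOD 28 cycles, configurable because the underlying protocol's
  exact limit varies between platforms).
- Gene symbols match case-insensitively against annotations but are
  case-preserved in output.

## Problem sizes used in validation

The shipped test-suite and acceptance script validate at: 1000 random
vector pairs for the Spearman oracle; an exhaustive division-index sweep
over generations 0–2 up to 64 cells and generations 0–5 up to 16 cells
plus thousands of random vectors across the full range; 20 replicates of
the 200-cell planted-module screen; 10 replicates of the 100-cell
subpopulation recovery; 10 deconvolution runs at 5000 events and
σ = 0.15; and 3-replicate suppression experiments at 5000 events. These
sizes were chosen to give tight Monte-Carlo error on each check while
keeping the whole validation suite runnable on a laptop in minutes.

## Known limitations

- The screen is correlational; it does not model confounders such as cell
  size or total expression, and offers no causal reading.
- The anchor-module refinement rule assumes the anchor belongs to exactly
  one coherent module; interleaved, overlapping modules will be cut at
  the dendrogram's mercy.
- The mixture model assumes log-normal peaks at exact halving intervals
  and a shared width; dye efflux, uneven staining, or autofluorescence
  bleed-through violate it and should be gated out upstream.
- With fewer than ~50 events, or when generation 0 is entirely absent
  and the brightest observed peak is itself divided, the automatic
  undivided-peak location can be off by a whole generation; supply
  `g0_center` from an unstimulated control in that case.
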