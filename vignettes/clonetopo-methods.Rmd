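---
title: "Clonal topography, virtual biopsies, and the barcode counting pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal topography, virtual biopsies, and the barcode counting pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(clonetopo)
```

## The problem

Lineage barcoding labels each tumor-initiating cell with a short heritable
DNA tag, so that every cell of the grown tumor can be assigned to a founder
clone by amplicon sequencing. This makes two clinical questions quantifiable
in preclinical models: how are clones arranged in space within a primary
tumor, and how much of that clonal composition does a biopsy — a dissected
piece, a core needle, or circulating tumor DNA in plasma — actually capture?

`clonetopo` implements the complete computational side of such a study:

1. a stochastic agent-based simulator of 3D clonal growth on a lattice
   (`sim_params()`, `initialize_tumor()`, `grow_to()`),
2. virtual sampling of the simulated tumor: dissection, directional core
   needles at two depths, and a plasma shedding model (`dissect()`,
   `needle_biopsy()`, `sample_cfdna()`),
3. demultiplexing and counting of barcode amplicon reads against a known
   library (`demultiplex_and_count()`),
4. the count-matrix QC filter chain (`qc_filter()` and its four steps),
5. diversity and representativeness statistics (`shannon_index()`,
   `pct_barcodes_detected()`, `biomass_captured()`, `dominant_clones()`,
   `group_comparison()`), and
6. seed-deterministic synthetic-data generators so every stage is testable
   without any sequencing download (`synth_library()`,
   `synth_tumor_profiles()`, `simulate_counts()`, `write_fastq()`).

## The growth model

Cells live on a 3D cubic lattice (26-connected by default; 6-connected
selectable) and carry three per-cell rates, in arbitrary time units:

* birth rate $b$ — division into a uniformly chosen empty neighbor site,
  the daughter inheriting the parent's barcode; a cell with no empty
  neighbor cannot divide (contact inhibition, which makes growth
  surface-limited),
* death rate $d$ — the cell is removed and its site becomes reusable,
* mobility $M$ — a short-range hop to a uniformly chosen empty neighbor.

Because every cell carries the same total rate $b + d + M$, the kinetic
Monte Carlo step reduces to choosing a cell uniformly at random and then an
event type with probabilities $b : d : M$. The simulation starts from 200
barcoded founder cells packed in a ball at the lattice center and runs
until a target population size (extinction is reported as an explicit
result). Identical parameters and seed give bit-identical trajectories.

Defaults are $b = 0.69$, $d = 0.1$, $M = 0.05$; only their ratios shape
the clonal pattern, and these values are deliberately labelled
non-authoritative configuration defaults — they produce modest cell
turnover and weak mixing, the regime in which clonal patches form. The
desk-scale default target size is $2 \times 10^5$ cells (a ball of radius
$\approx 36$ sites); the multi-million-cell regime is available by raising
`target_size`, with memory growing as the cube of the lattice extent. The
analyses in the test suite and the acceptance script use $10^5$ cells and
20 replicate simulations, sizes at which every run completes in well under
a second.

The central observable is a purely geometric one: surface-limited growth
traps the founder mixture in the tumor interior while a few outward-facing
sectors expand, so the tumor **center retains far more distinct clones than
any peripheral piece**. With the defaults above the center piece holds
around 4x the distinct-clone count of a peripheral piece — the package's
in-silico replication of the center-enrichment observation.

```{r center, eval = FALSE}
st <- simulate_tumor(200, sim_params(target_size = 1e5, rng_seed = 7))
vapply(dissect(st, five_piece_plan()), clone_richness, 1)
#>   A   B   C   D   E
#>  31  28  23  29 142
```

## Virtual sampling geometry

**Dissection.** The five-piece plan cuts the outer 25% off both faces of
the x and y axes (pieces A–D), leaving the central box as piece E; the
seven-piece plan also cuts both z faces. Cuts are applied in order against
the original occupied bounding box and each cell joins the first piece that
claims it, so the pieces are a partition by construction. The cut fraction
is configurable because only the order of cuts, not their exact
proportions, is a fixed feature of the protocol being modelled.

**Needles.** A needle is a cylinder of radius 2 lattice units (default)
entering the tumor surface along a direction through the centroid. Depth
is expressed as a fraction of the tumor's chord along that direction:
`depth_fraction = 0.5` reaches the center (deep, "needle-a"), `0.25`
covers a quarter of the diameter (shallow, "needle-b"). A shallow core is
therefore always a geometric subset of the deep core along the same track,
which yields the tested ordering deep ≥ shallow in clone richness. Whether
a real aspiration needle samples a clean cylinder is unknown; the cylinder
is the simplest defensible geometry.

**Plasma.** `sample_cfdna()` draws $F$ barcode fragments multinomially
with probability proportional to clone size × shed weight, splits them
uniformly into 5 pseudo-replicates (plasma barcode PCRs are run in
quintuplicate precisely to rescue sparse detections), and calls a clone
detected only if it appears in ≥ 2 of them — the same replicate-detection
rule the QC chain applies to sequencing replicates. $F$ defaults to
$10^{-4}$ × population size, which makes detection probability grow with
tumor burden, the qualitative hallmark of cfDNA monitoring. With equal
shed weights the draw is an unbiased multinomial sample of the census; an
optional necrotic-core boost models tumors whose dying center sheds
disproportionately. At the desk-scale default ($10^5$ cells, $F = 10$
fragments) roughly half of simulated draws recover any barcode at all —
sparse, burden-limited detection rather than a faithful miniature of
plasma biology.

## The counting and QC pipeline

Reads are laid out `[index][anchor][barcode][filler]`; the index and
barcode regions are extracted positionally and matched against the sample
sheet and barcode library by Hamming distance under user-set mismatch
budgets. Ties at equal distance are never assigned — a conservative policy
that keeps counts honest — and every read is accounted for: assigned +
unassigned = total, a property tested under injected sequencing errors.
Base qualities are ignored, matching amplicon pipelines whose specificity
comes from the known library rather than quality trimming.

The QC chain applies four steps in a fixed order, each with a strict,
boundary-tested inequality:

1. counts ≤ 10 are zeroed within each sample (10 → 0, 11 → 11),
2. samples with < 10,000 total reads are dropped (9,999 out, 10,000 in),
3. within each non-exempt replicate group, replicates whose mean pairwise
   Pearson r with their peers is < 0.6 are removed (r = 0.59 out,
   r = 0.60 in); cfDNA groups are exempt and only flagged, because
   low-input plasma replicates are expected to disagree,
4. a barcode must be present in ≥ 2 replicates of a group to be kept
   there (1 of 2 discarded, 2 of 5 kept).

Replicates are then pooled by addition and normalized to frequencies;
piece profiles are cumulatively added and renormalized to reconstruct the
whole tumor; and sample profiles can be restricted to the tumor's barcode
set. Numerical choices worth stating: the concordance correlation is
computed on raw counts (log1p selectable) over the barcodes nonzero in at
least one member of each pair; for a discordant *pair* both members are
removed, since concordance cannot attribute blame within a pair; the
"present in ≥ 2 replicates" requirement is capped at the group size so a
single-replicate group is not emptied wholesale; and a replicate with an
undefined (zero-variance) correlation is treated as discordant rather than
silently kept.

## Statistics

All representativeness metrics treat "detected" as nonzero frequency
after the full QC chain. `shannon_index()` uses natural logs (the base is
switchable; reported diversity values should state the base).
`dominant_clones()` is strictly greater-than 1% — a clone at exactly the
threshold is not dominant. `biomass_captured()` sums tumor frequencies
over the union of barcodes detected across the supplied samples, so it is
monotone under adding biopsies, which is what makes needle + cfDNA
combinations meaningful. `group_comparison()` delegates to the classical
machinery (unpaired equal-variance t test for two groups, one-way ANOVA
with Tukey's HSD for more) and reports comparisons involving groups of
n < 3 as not determined. Correlations between a sample and the tumor are
computed over the union of barcode sets with absent barcodes at 0;
intersection-only correlation is available but inflates r.

## What the synthetic generators emulate — and what they do not

`synth_tumor_profiles()` draws clone abundances from a log-normal law
(σ = 1.5 by default, giving a handful of > 1% dominant clones over a long
minor tail, the shape real barcoded tumors show) and splits each clone's
mass across pieces with an independent symmetric Dirichlet draw
(concentration 0.3 by default: most of a minor clone's mass lands in one
or two pieces, emulating spatial patchiness without geometry).
`simulate_counts()` layers multinomial or Dirichlet-multinomial
(overdispersed) sequencing replicates on top, and `write_fastq()`
realizes a count matrix read-for-read, so
`demultiplex_and_count()` can be validated as its exact inverse.

Two deliberate limitations. First, Dirichlet patchiness does not conserve
piece volumes: summed piece masses are unequal, unlike an equal-volume
dissection. Consequently, sequencing pieces at *equal depth* and
re-adding them cannot recover the generating tumor frequencies even in
expectation — piece depth no longer encodes piece mass. The end-to-end
recovery analysis therefore sequences the whole-tumor specimen in PCR
duplicate; geometry-true piece profiles come from `sim_engine` +
`dissect()` when piece-level truth matters. Second, exact recovery of the
dominant-clone *set* is only well-posed when no clone sits essentially at
the 1% threshold: at sequencing depth $10^5$ the frequency of a 1% clone
has standard error $\approx 2\times10^{-4}$, so a clone within a percent
(relative) of the threshold flips sides with probability approaching 1/2.
The recovery check of the dominant set accordingly uses an abundance
spectrum whose clones are bounded away from 1% (0.5% below, 3% and 8%
above); the log-normal spectrum is still used for the frequency-recovery
correlation (r ≥ 0.99). These are identifiability boundaries of the
check, not pipeline defects, and passing them says nothing about barcodes
whose true frequency hugs the threshold.

The generators do not model PCR chimeras or jackpotting beyond symmetric
overdispersion, sequencer error profiles beyond uniform substitution,
fragment-length or vascular physiology of cfDNA, or driver-mutation
fitness differences between clones (all clones are neutral). Passing
tests on this synthetic structure validates the pipeline's arithmetic and
its filter semantics — not the biological fidelity of any particular
tumor model.

## Degenerate inputs and tie-breaking

Founder seeding is deterministic: lattice sites sorted by squared
distance to the lattice midpoint, ties broken lexicographically, barcode
IDs assigned in placement order. A birth or move attempt with no empty
neighbor is suppressed (it consumes the event draw), which is what makes
interior cells inert and growth surface-limited. `grow_to()` with zero
birth and death rates but a larger target is a progress error; with
positive death it runs to an explicit extinction result. Empty biopsy
profiles are valid values, not errors, and propagate as zero detection
through every statistic; empty tumor references, by contrast, raise
errors, since every representativeness metric is undefined without a
tumor denominator.
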