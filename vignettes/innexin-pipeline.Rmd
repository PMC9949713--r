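---
title: "Reconstructing the ctenophore innexin radiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the ctenophore innexin radiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inxtools)
```

Innexins are the invertebrate gap-junction proteins; undocked hemichannels
built from them (innexons) connect a cell's cytoplasm directly to the
extracellular space. This package implements, as reusable and tested code,
the four computational analyses behind a comparative study of the innexin
repertoires of four ctenophores — *Beroe ovata* (Bo), *Mnemiopsis leidyi*
(Ml), *Pleurobrachia bachei* (Pb) and *Hormiphora californensis* (Hc):

1. gene-family **event reconstruction** (gains, losses, duplications) on the
   species tree ((Bo,Ml),(Pb,Hc));
2. **tandem-cluster and microsynteny** detection in genome gene-order tables;
3. **single-cell UMI coexpression** statistics and bulk expression ratios;
4. **single-channel electrophysiology**: unitary amplitude, idealization,
   I–V fitting, open probability and Nernst predictions.

A fifth module simulates inputs for all four with machine-readable ground
truth, and a thin command-line layer (`inx_main()`, `inst/cli/inx`) wires the
stages together.

## Event reconstruction

The family delimitation is an *input* (a gene → family TSV): families were
circumscribed by eye on a supported phylogeny in the original analysis, and
no algorithmic cut rule reproduces that judgement, so the package validates
the input (`validate_family_monophyly()`) rather than guessing a rule.

Given a rooted gene tree and the assignment, `build_presence_matrix()`
tallies copies per family and species. For each family:

* **Dollo gains and losses** (`dollo_events()`): under Dollo parsimony a
  family is gained exactly once, on the branch subtending the MRCA of the
  species that retain it; each maximal branch whose whole descendant clade
  lacks the family carries one loss. This placement provably minimizes the
  loss count under the single-gain constraint, and the test suite checks it
  against exhaustive search over all single-gain loss placements on all
  presence subsets of the 4-species tree and a thousand random 6-species
  cases.
* **Duplications** (`infer_duplications()`): standard LCA-mapping
  reconciliation. Each gene-tree node maps to the species-tree MRCA of its
  tips' species; a node that maps to the same species-tree node as one of
  its children is a duplication, placed on the branch leading to that node.

`summarize_events()` assembles totals and predicts terminal gene counts as
(families present in the species) + (duplications on ancestral-or-equal
branches in families the species retains) — i.e. a duplication propagates
one extra copy to every descendant that keeps the family, with no per-copy
loss modelling. On the packaged fixture this reproduces the published
reconstruction: 17 families, 14 stem gains, 13 losses (Ml 4, Bo 2, Pb 7,
Hc 0), 4 duplications, and terminal counts Pb 9, Hc 19, Ml 12.

```{r}
fx <- innexin_fixture()
pm <- build_presence_matrix(fx$gene_tree, fx$family_map, fx$species_tree)
summarize_events(pm, fx$gene_tree, fx$family_map, fx$species_tree)
```

Two deliberate choices are worth flagging. First, the stated per-lineage
events imply 13 terminal genes for *B. ovata* while the source reports 12;
the fixture follows the event statements, and Bo's terminal count is treated
as a documented inconsistency rather than silently reconciled. Second, the
reported ancestral Pb+Hc duplication does not name a family; the fixture
places it in INXE, an arbitrary choice that affects no totals.

**Isoform removal** (`dedup_isoforms()`) mirrors the transcriptome
pre-processing step: same-species sister tips whose terminal branches are
both effectively zero-length are collapsed to one representative, repeated
to a fixed point (hence idempotent). "Zero" means ≤ 1e−9 to absorb parser
rounding, and the lexicographically smallest tip id is kept — the original
analysis does not state which isoform was retained, so the tie-break is
fixed and documented rather than meaningful.

## Tandem clusters and microsynteny

`find_family_clusters()` chains target-family loci along a scaffold whenever
the boundary-to-boundary distance (end of one gene to start of the next) is
at most `max_gap` (default 40 kb, the working threshold for the innexin
cluster). The threshold's "within 40 kb" phrasing does not say whether it is
boundary-to-boundary or span-based; boundary-to-boundary is used because it
matches the phrasing for compact clusters, and the choice is exposed via
`max_gap`. Intervening counts are non-target genes lying strictly between
consecutive members. Singleton chains are reported too, so the clusters
partition the target loci — a property the tests enforce.

`microsynteny_blocks()` finds maximal runs of ortholog pairs occupying
consecutive gene ranks in both genomes, ignoring gene order within the run
and strand (strand is not used anywhere: the source analysis does not use
it). Genes without an ortholog interrupt runs, which is what keeps blocks
small in genomes with sparse ortholog coverage. Coordinates are normalized
internally to 0-based half-open; GFF3 input (1-based inclusive, `gene`
features only) is converted on read, BED passes through.

## Single-cell coexpression

"Expressing" is UMI ≥ 1 by default: the original analysis parsed raw UMI
counts and never states a threshold, so the minimal one is assumed, applied
without normalization, and exposed (`min_umi`). On the binarized mask:

* `innexin_count_histogram()` buckets cells by the number of expressed
  target genes (0/1/2/≥3 by default; because the published figure's ">3"
  label is ambiguous about cells expressing exactly three, a strict variant
  with separate "3" and ">3" buckets is available — both sum to 1).
* `metacell_markers()` implements the "at least 50% of the cells comprising
  a metacell" rule with an inclusive boundary (exactly 50% is a marker).
* `pairwise_coexpression()` reports, per gene pair, 100 × (cells expressing
  both) / min(cells expressing each) — the minimum-denominator percentage.
  When a gene is expressed nowhere the percentage is undefined and reported
  as missing, never 0. Percentages are rounded to one decimal.
* `expression_ratio()` summarizes per-sample TPM ratios (samples with a zero
  denominator skipped) by the median and the raw (unscaled) median absolute
  deviation, a deliberately assumption-free spread for three-replicate
  tissue panels.

## Electrophysiology

Cells pass QC when input resistance ≥ 300 MΩ and cell-attached seal
≥ 1 GΩ, both inclusive (`qc_filter()`). The analysis chain for a sweep set
(`analyze_sweeps()`) is:

1. **Unitary amplitude** (`estimate_unitary_amplitude()`): the all-points
   amplitude histogram is fit with an equal-variance Gaussian mixture of
   1–4 components chosen by BIC (the cap encodes the observation of
   short-lived subconductance states without unbounded model growth).
   Components with mixing weight < 2% are not counted as levels — they are
   almost always low-pass-filter transition samples — and adjacent means
   closer than three noise SDs are merged, since such levels are not
   resolvable. One surviving component means "no activity". The unitary
   amplitude is the median spacing of adjacent level means, signed relative
   to the baseline (the mode of the histogram, identified as the
   heaviest-weight component). Segments shorter than 50 ms are refused.
2. **Idealization** (`idealize()`): half-amplitude assignment of each sample
   to an occupancy level, with dwells shorter than twice the filter rise
   time (0.3321/f_c) merged into their longer neighbour — the standard dead
   time for a low-pass-filtered record. N is the maximum level observed.
3. **I–V fit** (`fit_iv()`): ordinary least squares through the per-voltage
   unitary amplitudes; slope in pA/mV is a conductance in nS, reported in
   pS; the reversal potential is −intercept/slope. Exact collinear input is
   reproduced to machine precision.
4. **Open probability** (`open_probability()`): P_o = I/(N·i), clamped to
   [0, 1] with the raw value retained.

`nernst_potential()` evaluates V = 1000·RT/(zF)·ln(c_out/c_in) mV with
R = 8.314 J mol⁻¹ K⁻¹ and F = 96485 C mol⁻¹. Temperature defaults to
295.15 K: recordings were made at an unstated "room temperature", and the
default is overridable everywhere it is used. The recording recipes are
shipped as a per-ion table (`solution_recipes()`): extracellular chloride is
the sum over chloride salts (486 NaCl + 5 KCl + 2×13.6 CaCl₂ + 2×9.8 MgCl₂
= 537.8 mM). Under these solutions the predicted ideal-channel reversals are
K⁺ ≈ −95 mV, Cl⁻ ≈ −24 mV, and pooled monovalent cation ≈ +22 mV, so an
observed reversal near 0 mV indicates a nonselective pore.

## What the simulators emulate — and what they do not

All generators are pure functions of their parameters and seed, and each
returns ground truth sufficient to score the corresponding analysis module.
A single global seed can be fanned out to per-generator streams with
`fanout_seed()` (streams: 1 families, 2 genomes, 3 UMI, 4 traces).

**Families** (`simulate_family_evolution()`): every family is gained at the
root; on each branch a surviving family is lost with probability `p_loss`
(all copies, no regain — Dollo-compatible) or duplicated with probability
`p_dup` (one extra copy for all descendants that retain it). Defaults 0.15
and 0.10 produce per-family event counts comparable to the observed innexin
histories (0–2 losses and 0–1 duplications for most families). Extinct
families are regenerated and counted. Not every history is recoverable by
*any* Dollo method: a gain whose surviving species all sit in one root
subtree is indistinguishable from a later gain, and sibling losses merge
into one maximal absent clade. The simulator therefore flags each family as
Dollo-identifiable or not, using set arithmetic on its own event log, and
recovery is asserted to be exact on the identifiable ones (typically
~60–70% at the default rates).

**Genomes** (`simulate_genome_order()`): background genes are spaced
60–120 kb apart (above the 40 kb threshold), planted cluster members 5 kb
apart with optional intervening genes inside the gaps, so planted clusters
are exactly recoverable by construction. The default plants the
INXB–INXC–INXD cluster with one conserved non-innexin flanking gene, making
a four-gene conserved run — the shape of the observed conserved block.
Genome B keeps conserved runs contiguous, shuffles everything else, and only
70% of background genes receive orthologs; real genomes' sparse ortholog
maps are what keeps observed microsynteny blocks short.

**UMI counts** (`simulate_umi()`): negative binomial counts (default mean 2,
size 1) for "on" genes — overdispersed relative to Poisson, with dropout
arising naturally since an "on" gene can still draw zero. Planted pairs
share a latent on/off program in a fraction of cells, which yields a
closed-form expected coexpression percentage of 100·q_Aq_B/min(q_A,q_B)
where q = 1 − (size/(size+mean))^size is the probability an "on" gene is
observed. The generator does not emulate ambient RNA, doublets, batch
effects, or depth variation between cells, so passing tests demonstrate
correctness of the statistics, not robustness to those artefacts.

**Patch traces** (`simulate_patch_traces()`): N identical channels, each an
independent two-state Markov chain simulated with exact exponential dwells
and started from its stationary distribution; zero calcium forces the
opening rate to zero (calcium is modelled as a binary gate, since the high
condition's free calcium is only bounded below in the source). Defaults:
g = 340 pS, V_rev = 0 mV, opening 10 s⁻¹ and closing 40 s⁻¹ (stationary
open probability 0.2, chosen so the closed level dominates the all-points
histogram as in the observed recordings), Gaussian noise 2 pA, 20 kHz
sampling, 5 kHz low-pass (second-order Butterworth, applied forward and
backward), and the published step protocol (200 ms steps in 10 mV
increments; analysis window −120…−40 mV, below the activation range of the
voltage-gated currents that are out of scope here). Capacitance transients
and bursting/modal gating are not simulated.

## Numerical choices and degenerate inputs

* Terminal branch lengths ≤ 1e−9 count as zero for isoform removal; missing
  lengths are an error naming the offending tip.
* A family with zero copies everywhere is rejected; a single-tip family
  subtree yields no duplications (empty result, not an error).
* Negative `max_gap`, non-integer UMI counts, empty target sets, zero
  unitary amplitudes, all-identical voltages and non-positive Nernst
  concentrations are all explicit errors.
* Undefined coexpression percentages are `NA`, never 0; open probabilities
  outside [0, 1] are clamped with the raw value retained.
* Mixture fits subsample long segments to 5,000 evenly spaced points; at a
  20 kHz sampling rate this keeps per-voltage fits around a second without
  affecting the level means.

## Problem sizes used by the test suite

The reconstruction oracle runs 200 simulated families; the Dollo
exhaustive-search comparison covers all 15 presence subsets of the
4-species tree plus 1,000 random subsets on random 6-species trees; synteny
oracles run on 100 random genomes; coexpression brute force on a 50-gene ×
1,000-cell mask with planted-pair convergence at 5,000 cells (averaged over
10 replicates, since a single draw of the min-denominator percentage has
~2-point sampling noise); the electrophysiology recovery uses 9 voltages ×
5 sweeps and 100 independent zero-calcium runs. These sizes were chosen to
hold Monte-Carlo error well below each assertion's tolerance.

## Known limitations

* The event model assumes the species tree is known and fixed; alternative
  topologies can be supplied but are not averaged over.
* Duplications propagate to all retaining descendants; per-copy loss after
  duplication is not modelled, which is sufficient for the observed
  terminal counts but not a general gene-tree birth–death model.
* Microsynteny blocks are order-free common intervals; inversions inside a
  block are invisible by design, and no significance statistic is attached.
* The idealizer assumes a stable baseline within a segment; slow drift
  should be removed upstream.
* Sequence-level analysis (similarity search, alignment, tree inference) is
  out of scope: the pipeline consumes finished trees and tables produced by
  the field's standard external tools.
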