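---
title: "Methods: k-mer screening for VNTR frameshift insertions"
author: "vntrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer screening for VNTR frameshift insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the detection
model and its assumptions, what the synthetic-data generator does and
does not emulate, the numerical and design choices that were genuinely
open, and the known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The locus model

The target is a coding VNTR made of 60-bp, GC-rich repeat units — the
*MUC1* exon-2 architecture, with copy numbers ranging from roughly 20 to
125 per allele and disease transmitted dominantly by a heterozygous
single-cytosine insertion that frameshifts the open reading frame. The
package models the locus as:

- a **motif catalog**: the unit alphabet, a TSV of (motif_id, 60-nt
  sequence). The real unit inventory of *MUC1* is not public; the
  package ships a clearly-labelled *synthetic* catalog of five GC-rich
  units (`synthetic_catalog()`) that emulates unit length and base
  composition, and accepts any user catalog in the same format.
- an **allele**: an ordered vector of motif_ids, optional insertion
  (0-based `repeat_index`, 0-based `offset`, inserted sequence — the
  insertion goes *before* the base at `offset`; stated once here, used
  everywhere), and 5'/3' flank anchors.
- a **diploid genotype**: two alleles; a carrier has the insertion on
  exactly one.

## Detection: diagnostic k-mers instead of alignment

Mapping short GC-rich tandem-repeat reads is unreliable, so the caller
never aligns. For k-mer length $k$ and catalog $U$:

**Reference space.** All k-mers of every ordered pair concatenation
$u \cdot v$, $u, v \in U$. Self-pairs capture the rotational k-mer
content of tandem copies; cross pairs capture every possible unit–unit
junction, because unit order within a real allele is unknown. When the
flank anchors are supplied (they are part of the assay design), the
flank–unit junction k-mers are included too, so the insertion-free
sequence space of the whole capture region is covered. With $k \le 60$
every read window touches at most two units, so pairwise contexts are
sufficient — this is why `k > 60` is rejected.

**Candidate insertions.** The caller is candidate-driven: it tests a
configured insertion alphabet (default the pathogenic `"C"`; `"GGCT"`
can be added to track the known artifact motif) at every offset of every
unit, rather than assembling novel variants de novo — the upstream
methodology it follows is equally catalog-limited. For each candidate,
the diagnostic set is every k-mer window overlapping an inserted base in
a mutated context, *minus* the reference space.

Three design points here were genuinely open:

1. **Neighbour contexts.** A window overlapping the insertion can extend
   up to $k-1$ bases into the neighbouring unit, and the true neighbour
   is unknown. Enumerating only the homogeneous tandem context (the
   mutated unit flanked by copies of itself) silently discards most
   diagnostic windows whenever the real neighbour differs — for
   insertions near unit edges this loses nearly all support and makes
   sensitivity depend on where in the unit the insertion falls, at any
   coverage. `candidate_insertions()` therefore unions the enumeration
   over *all* ordered neighbour contexts (every catalog unit, plus the
   flank anchors for the first/last unit). The exported
   `enumerate_variant_kmers()` keeps the simple single-context contract
   (its set size is bounded by $k + |s| - 1$) and accepts explicit
   contexts.
2. **Equivalent candidates.** Inserting a C anywhere inside a C
   homopolymer run, or at a unit boundary (writable as the end of one
   unit or the start of the next), yields the *same* mutated sequence.
   Candidates whose diagnostic sets intersect are therefore merged into
   one group (connected components), reported under the leftmost
   context — the same normalisation as VCF indel left-alignment. K-mers
   shared between candidates with *different* inserted sequences
   identify neither and are dropped. After merging, groups are pairwise
   disjoint, so a diagnostic hit identifies its variant unambiguously;
   the test suite asserts this for the shipped catalog.
3. **Depth aggregation.** A real insertion creates exactly
   $k + |s| - 1$ diagnostic windows (fewer under homopolymer
   degeneracy); the rest of a merged group corresponds to neighbour
   hypotheses that did not materialise. `alt_depth` is therefore the
   mean of the top $k + |s| - 1$ counts in the group. A plain mean over
   the group would dilute true support by the number of contexts; a
   median would zero it. The aggregation lives in one place
   (`count_kmer_depths()`) and is deliberately isolated.

**Screening.** Reads sharing at least 3 k-mers (either strand) with the
combined index are recruited; everything else — the bulk of a panel — is
discarded before counting. The index stores only the coding orientation;
reads are matched in both orientations.

**Scoring and classification.** The upstream pipeline publishes its
High-confidence rule but not its depth-score formula. The package uses
the simplest quantity for which the published floor is sensible:

$$\mathrm{depth\ score} = \frac{\mathrm{alt\_depth}}
 {\mathrm{alt\_depth} + \mathrm{total\_depth}},$$

defined as 0 when both depths are zero, with `total_depth` the mean
reference k-mer count. A call is High confidence iff depth score
$\ge 0.00515$ (inclusive — "at least") and alternate depth $> 20$
(strict — "greater than"); boundary semantics are pinned by tests. This
formula is an explicit stand-in kept behind `depth_score()` so it can be
swapped without touching anything else. Low-confidence calls with
insertions longer than 1 bp are flagged as probable artifacts
(`artifact_flag`), retained but marked — the empirical signature of
pipeline false positives (`GGCT` with markedly low depth scores); a
High-confidence multi-base call is *not* flagged, the rule is a strict
conjunction.

## The synthetic-data generator

`simulate_short_reads()` draws fragments uniformly from both alleles in
equal expectation (paired-end by default, fragment length Normal(350, 50)
truncated at the read length, reads 150 bp, constant Q30 qualities —
the detector never uses qualities), applies substitution errors at
`per_base_error_rate` (default 0.001), and thins fragments with
probability $\min(1, e^{-\beta(\mathrm{GC} - 0.5)})$, one scalar
$\beta$ (`gc_bias_strength`, default 0) standing in for GC dropout.
The fragment count is calibrated so interior depth matches
`mean_coverage`; two presets encode the panel regimes of interest,
`broad_panel` (344x) and `adtkd_panel` (2424x), the reported median
VNTR coverages of a broad kidney-gene panel and an ADTKD-specific
panel. Repeat counts are drawn uniformly from 20–125 per allele —
the documented copy-number range, left untouched by every test.

`simulate_long_reads()` emits flank-to-flank amplicon reads (allele
picked fairly, strand random, substitution errors at 0.002 by default).

What the generator does **not** emulate: indel sequencing errors (so
read lengths are exact — the long-read oracle exploits this), PCR
chimeras, duplication, instrument-specific error profiles, alignment
artifacts, and any non-uniform fragment-start bias beyond the one GC
scalar. Passing tests therefore demonstrate algorithmic correctness
under a clean error model, not performance on real instrument data: in
particular, real long reads have indel-dominated errors that would
break the exact-length clustering and require indel-aware consensus.

## The long-read oracle

`reconstruct_alleles()` mirrors manual long-read practice: locate both
flank anchors (approximate match, up to 10% mismatches per flank, both
orientations), extract the enclosed VNTR, cluster segment lengths with
1-D 2-means (centroids closer than 30 nt — half a unit — are merged, so
homozygous-length genotypes form one cluster), then, within a cluster,
partition reads by exact length: under the substitution-only error
model a 1-bp insertion allele is a distinct length class even when
clustering cannot separate it. Each class gets a per-column majority
consensus (ties broken alphabetically). A consensus whose length is not
a multiple of 60 carries an insertion of length `len mod 60`; its
position is the removal point that minimises total mismatches of the
remaining sequence tiled into 60-nt catalog units anchored at the 5'
flank, leftmost on ties, then left-normalised. The reconstruction
reports repeat count (`len %/% 60`), read count, allele frequency, and
the 60-bases-per-line layout in which the insertion line runs long.

## Cohort statistics and renal survival

`summarize_cohort()` computes the descriptive statistics of a
diagnosed-case table: median/IQR of age at diagnosis using linear
interpolation of order statistics (R quantile type 7 — the only common
quantile convention consistent with the published IQR for this table
shape), counts of sex, family history, biopsy and MCKD findings,
hypertension and hyperuricemia (rows marked ND are excluded from
numerators, not imputed), patients already on renal replacement therapy
(RRT), and proteinuria among non-RRT patients. Proteinuria needed a
threshold the source material does not state: numeric urinary protein
$\ge 0.15$ g/gCr counts, `negative`/`ND`/`auria` do not, and RRT
patients are excluded from both numerator and denominator.

`to_survival()` builds ESKD survival records: event at RRT age (which
takes precedence over a later diagnosis age), censoring at age at
diagnosis otherwise. `kaplan_meier()` wraps the product-limit estimator
(`survival::survfit`), with events preceding censorings at tied times
and the median defined as the smallest age at which survival drops to
0.5 or below. The confidence interval uses the Greenwood standard error
on the log-survival scale (`conf.type = "log"`, the `survfit` default):
among the standard interval constructions it is the one that matches
published cohort estimates for this locus, and the choice is exposed as
an argument. A median CI bound is reported as `NA` when the
corresponding CI curve never crosses 0.5 — the expected outcome when
few events occur late in follow-up. An independent brute-force
product-limit implementation lives in the test suite and is checked
against the estimator on fuzzed small cohorts.

## Validation harness

`run_scenario()` reproduces the two study designs in silico: carrier
cohorts scored for sensitivity, non-carrier cohorts for specificity,
with truth taken from the simulator sidecar and optionally
cross-checked against the long-read oracle. By default a Low-confidence
call counts as a *negative* (every Low-confidence positive in the
motivating clinical material proved false on long-read validation); the
`count_low_conf_as_positive` flag flips to the screening-first reading.
Per-case seeds derive from the scenario seed by counter, so any case is
individually replayable. `coverage_sensitivity_curve()` sweeps mean
coverage (default grid 10, 50, 344, 2424) and attaches exact binomial
confidence intervals; sensitivity is monotone in coverage in
expectation because alternate depth scales linearly with it.

Problem sizes used by the shipped tests: 50 error-free non-carrier
cohorts and 20 carrier cohorts at full clinical repeat-count range for
the scenario checks, 20 cases per coverage grid point, 100 fuzzed
genotypes for exact long-read recovery, 100 fuzzed catalogs for
diagnostic-k-mer soundness, and cohorts of up to 12 for the
product-limit cross-check.

## Numerical and degenerate-input choices

- `k = 25` by default: well under the 60-nt unit (k-mers stay
  informative within one repeat) and under typical 100–150-bp read
  lengths; configurable, bounded by (1, 60].
- Insertions at equivalent positions are left-normalised; comparisons
  of called against simulated coordinates go through
  `normalize_insertion_point()` on both sides.
- Degenerate insertions that recreate reference context yield smaller
  (possibly empty) diagnostic sets; empty candidates are dropped rather
  than reported with zero support.
- `depth_score(0, 0) = 0` by definition; negative depths are rejected.
- Screening of an empty index is an error (configuration mistake), an
  empty read set returns an empty screen.
- Consensus ties in the oracle break alphabetically; insertion-point
  ties break leftmost.
- All simulator outputs are pure functions of `(seed, inputs)`; each
  operation derives an independent sub-seed so genotype, short reads
  and long reads can be regenerated separately.

## Limitations

- Candidate-driven: only insertions from the configured alphabet are
  detectable; novel motifs or other variant classes (deletions,
  substitutions, copy-number changes) are out of scope by design.
- The depth-score formula and the alternate-depth aggregation are
  documented stand-ins for unpublished upstream definitions; both are
  isolated behind single functions.
- The shipped catalog is synthetic; results on it validate the
  algorithm, not the real *MUC1* unit inventory.
- The clean error model (substitutions only, uniform within read)
  flatters both the detector and the oracle relative to real data;
  coverage thresholds tuned here should not be read as instrument
  guidance.
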