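# vntrscreen

Mapping-free detection of frameshift insertions in GC-rich 60-bp coding
tandem repeats from short-read panel sequencing — the variant class behind
ADTKD-*MUC1* (autosomal-dominant tubulointerstitial kidney disease caused
by *MUC1*) — together with everything needed to validate such a caller
without patient data: a diploid VNTR read simulator, a long-read
reconstruction oracle, a concordance harness, and clinical cohort
statistics with Kaplan–Meier renal survival.

## The problem

The *MUC1* coding VNTR consists of 20–125 copies of a 60-bp, extremely
GC-rich repeat unit. The canonical pathogenic lesion is a single cytosine
insertion inside the repeat array, which frameshifts the protein
(MUC1-fs). The region resists both Sanger sequencing and conventional
mapping-based short-read analysis, so insertions there are classically
detected by long-read amplicon sequencing of the whole array.

`vntrscreen` implements the alternative screening strategy: skip mapping
entirely and look for **diagnostic k-mers** — length-k subsequences
created by the insertion that provably occur nowhere in the insertion-free
repeat space. For a repeat-unit catalog *U* and k-mer length *k* (default
25), the reference k-mer space is every k-mer of every ordered
unit-pair concatenation *u·v* (*u, v ∈ U*), plus the flank–unit junctions
of the locus anchors. A candidate insertion of sequence *s* at offset *o*
of a unit is scored by the depth of its diagnostic k-mers in the reads:

- `alt_depth` — mean of the top *k + |s| − 1* diagnostic k-mer counts
  (the number of windows a real insertion creates),
- `total_depth` — mean reference k-mer count,
- `depth_score = alt_depth / (alt_depth + total_depth)`.

A call is **High confidence** iff `depth_score >= 0.00515` **and**
`alt_depth > 20` (inclusive / strict, respectively); everything else is
Low confidence. Low-confidence calls with multi-base insertions (e.g.
`GGCT`) are flagged as probable artifacts — in practice that combination
is always a false positive.

## Worked example

```r
library(vntrscreen)

catalog <- synthetic_catalog()

# a heterozygous carrier of the pathogenic single-C insertion,
# sequenced at the ADTKD-specific panel depth (2424x)
cfg <- coverage_preset("adtkd_panel", seed = 42)
geno <- simulate_genotype(cfg, catalog, carrier = TRUE)
reads <- simulate_short_reads(geno, catalog, cfg)
detect(reads$reads, catalog)
#> VNTR insertion screen: 49094/49150 reads recruited, k=25, 175 candidate insertions
#> 175 call(s): 1 High confidence, 174 Low (0 flagged as artifacts)
#>   inserted_sequence context alt_depth total_depth  depth_score supporting_kmers
#> 1                 C    u1:0    603.16    6290.429 0.0874957932               51
#> 2                 C   u3:14      2.08    6290.429 0.0003305518               13
#> ...
```

The true variant stands out: depth score 0.087 (threshold 0.00515) with
alternate depth 603 (threshold 20) — High confidence. The remaining rows
are sequencing-error noise, two to three orders of magnitude weaker and
all Low confidence; with default settings they would be screened out as
negatives.

The long-read oracle reconstructs the same genotype directly and reads
the insertion off the repeat array:

```r
lr <- simulate_long_reads(geno, catalog, cfg)
reconstruct_alleles(lr, catalog)
#> Long-read VNTR reconstruction: 60/60 spanning reads, 2 allele(s)
#>   consensus_length repeat_count read_count allele_frequency insertion
#> 1             1201           20         35        0.5833333    C@11:0
#> 2             4980           83         25        0.4166667
```

The clinical cohort module reproduces descriptive statistics and renal
survival for a diagnosed-case table (packaged example: 19 patients):

```r
tbl <- read_cohort_table(example_cohort_path())
summarize_cohort(tbl)
#> Cohort of 19 patients
#>   age at diagnosis: median 41 (IQR 35-48)
#>   sex: 11 M / 8 F; family history: 17
#>   biopsies: 12 (MCKD findings: 8)
#>   hypertension: 10; hyperuricemia: 6
#>   on RRT at diagnosis: 7; proteinuria among 12 non-RRT: 5
kaplan_meier(to_survival(tbl))
#> Kaplan-Meier renal survival: median 48 years (95% CI 46-NA)
```

A command-line front end over the same functions ships at
`inst/cli/vntrscreen.R` (subcommands `simulate`, `detect`, `oracle`,
`validate`, `cohort`).

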