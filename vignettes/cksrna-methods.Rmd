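---
title: "Methods: models, parameters and design choices in cksrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cksrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cksrna` analyses dual small-RNA sequencing of a plant root colonized by
a fungal endophyte. This vignette is the package's own account of the
models it implements, the parameters that matter, and the design
decisions taken where the analysis design was genuinely open.

## The measurement model

The experiment has three sample classes: a mock-treated plant root
(`Bd_C`), a colonized root (`Bd_Si`, containing RNA of both organisms),
and an axenic fungal culture (`Si_ax`). The core question is which
sRNAs are *induced by colonization* and have *silencing-competent
complementarity* to transcripts of the interacting organism — candidate
cross-kingdom (ck-) sRNAs. Two parallel filter cascades share the
upstream steps: endogenous sRNAs are analysed against their own genome
(profiles, loci, miRNAs), ck-sRNA candidates are scanned against the
partner transcriptome.

### Read preparation

Reads carry a 3′ sequencing adapter. `trim_adapter()` cuts at the
leftmost full adapter occurrence, or failing that at the longest
terminal overlap between a read suffix and an adapter prefix of at
least `min_overlap` (default 8 nt — long enough that a random match is
rare at the ~0.002 % level per read, short enough to rescue reads
truncated inside the adapter). Reads without adapter evidence are
rejected: in this library design every genuine insert is shorter than
the read, so a read without any adapter trace was not generated from a
small RNA. Empty inserts (adapter dimers) are rejected too. The
published protocol size-selects 15–35 nt inserts, so `filter_reads()`
keeps that range, boundary inclusive, and drops ambiguous bases. No
quality filtering is applied beyond that: the upstream quality step in
this kind of protocol is an inspection step, and the synthetic data
carry constant qualities by design.

### Exact dual-genome classification

Collapsed unique sequences are matched *exactly* (both strands,
substitutions only, no indels) against both genomes. Zero mismatches is
the deliberate default for genome-of-origin assignment: with two
diverged genomes, allowing mismatches blurs precisely the distinction
the pipeline is built to make, and an exact-match rule makes the
classifier's behaviour fully decidable against a naive substring scan
(which is how the test suite checks it). A one-mismatch mode exists and
is used only for matching locus products against a mature-miRNA
reference, where single-nucleotide family variation is expected.

Classification order: structural (tRNA/rRNA sequence-set match, either
strand) first, then `ambiguous` if a sequence occurs in both genomes,
then `plant` / `fungus` / `unmapped`. Ambiguous reads are excluded from
both pipelines because their origin is genuinely undecidable; the two
pipelines may otherwise overlap (an sRNA can have both an endogenous
locus and a cross-kingdom target). The structural filter matches
against a reference *sequence set*, not genome coordinates, mirroring
how such sets (e.g. from RNAcentral) are actually used.

### Normalization and induction

`rpm_normalize()` scales counts by 10⁶ over the *per-organism mapped
total of that sample*: plant reads in the mixed sample are normalized
by the plant-mapped total of that sample, fungal reads by its
fungus-mapped total. This removes the (large, uninteresting) difference
in fungal biomass between samples. Ambiguous and unmapped reads do not
enter any denominator. Per organism and sample the RPM values sum to
10⁶ exactly, which the tests assert at relative tolerance 10⁻⁶.

log2(colonized/control) is computed without pseudocounts;
colonized-exclusive sRNAs carry `NA` rather than an arbitrary large
value, and that `NA` is propagated into the reported duplex tables as
the mark of exclusivity. "Induced" means exclusive or log2FC > 0 — any
positive change, not a threshold — with log2FC > 1 flagged separately
as highly upregulated. The candidate filter keeps 21-nt sequences by
default, the canonical ck-sRNA length.

### Target prediction

`predict_targets()` is a seed-weighted complementarity expectation
scorer in the psRNAtarget/Allen tradition: the sRNA is aligned
antiparallel and *gapless* against every window of every transcript
(sense strand only — the sRNA binds the mRNA). Penalties per position:
match 0, G:U wobble 0.5, mismatch 1.0; doubled at sRNA positions 2–13
(the seed region); expectation = penalty total, 0 iff perfectly
complementary. A mismatch or wobble at positions 9–11 — the
slicing-competent centre — calls the duplex translational inhibition
instead of cleavage. Sites with expectation ≤ 5 (the conventional
stringent cutoff; exposed as a parameter since predictions are
threshold-sensitive) are retained, best site per transcript, ties to
the leftmost window. Gapless scoring was chosen deliberately: it keeps
the scorer exactly checkable against an independently coded
all-windows oracle, and bulged duplexes are a declared non-goal.

### Confirmation against differential expression

Predicted targets are joined to the partner organism's gene-level DE
table (transcript IDs resolve to gene IDs by stripping a trailing
isoform suffix; an explicit mapping can be supplied). A pair is
confirmed when the target has adjusted p < 0.05 **and** log2FC < 0 —
strictly negative, with no effect-size floor, matching the joint
criterion such studies apply. Coverage percentages
(`summarize_coverage()`) are reported with conventional half-up
rounding to one decimal; note that published reports sometimes truncate
instead (49/317 = 15.46 % can appear as "15.4 %"), so a 0.1-point
discrepancy against printed values is expected and documented rather
than imitated.

### Loci, DicerCall, miRNAs

`call_loci()` merges alignments within `merge_gap = 75` nt into loci by
single linkage and discards loci with fewer than 5 reads — values
mirroring common ShortStack defaults, exposed as parameters because no
single setting suits every library depth. A locus receives a DicerCall
when ≥ 80 % (boundary inclusive) of its count-weighted reads fall in
the 20–24 nt Dicer-typical window; the call is the modal in-window
length, ties to the smaller. Predominant sequences are matched against
a mature-miRNA reference at ≤ 1 substitution over equal length; ties
break by fewest mismatches then reference order. No hairpin
secondary-structure validation is performed — matching against a
provided mature reference stands in for a miRBase comparison, and RNA
folding is a non-goal.

### Phenotype statistics

Growth/yield traits are compared per biological replicate with a
two-sample test chosen by assumption checks: Shapiro–Wilk on both
groups and an F variance-ratio test, all at α = 0.05. Both normal and
homoscedastic → pooled t; normal but heteroscedastic → Welch t;
otherwise the two-sided Mann–Whitney–Wilcoxon (exact for group sizes
≤ 8 where ties permit; fully degenerate zero-variance data returns
p = 1). "Pairwise" comparison is read as *unpaired* two-sample testing,
since treated and control plants are distinct individuals.
Benjamini–Hochberg correction is applied across the traits tested
within one replicate — the correction family is the panel of
comparisons a reader sees together; whether to correct across
replicates too is genuinely open, so the family is configurable.
Adjusted p values are then averaged over replicates and stars assigned
to the average (* ≤ 0.05, ** ≤ 0.001, *** ≤ 0.0001 — an unusually
strict two-/three-star convention, kept as published). The effect size
is 100·(mean_treated − mean_control)/mean_control.

## The synthetic-data generator

The generator exists so that every pipeline claim can be tested against
a known truth. It emulates the *statistical structure* of the real
experiment:

* plant endogenous sRNAs with length modes at 21 nt (miRNA-like loci: a
  dominant mature sequence, 90 % of locus reads, plus two
  low-abundance shifted variants so DicerCall dominance thresholds are
  exercised; mature 5′ base biased to U with probability 0.8) and 24 nt
  (siRNA clusters with a 5′-A read bias of 0.7);
* fungal sRNAs with modes at 26 nt and 29–30 nt;
* 21-nt ck-sRNAs per direction, half colonized-exclusive and half
  induced four-fold, each with a perfectly complementary planted site
  in a partner transcript;
* DE tables in which exactly the planted target genes are
  significantly downregulated (log2FC = −1.5, padj < 0.05) and all
  other genes draw symmetric-around-zero fold changes and uniform
  adjusted p values;
* structural-RNA reads, unmappable noise reads, and optional "decoy"
  segments present verbatim in both genomes to exercise the ambiguous
  class.

Three constructions make recovery *exactly* measurable rather than
approximately:

1. **Cross-genome uniqueness at k = 15.** No 15-mer (nor its reverse
   complement) is shared between the two genomes outside decoys; 15 nt
   is the minimum accepted read length, so every read's origin call has
   a provable ground truth. Uniqueness is enforced by rejection
   sampling with bounded repair (single-base mutations of colliding
   windows); genomes too small for the requested layout raise an error
   rather than silently degrading.
2. **Identical endogenous counts across samples.** Endogenous locus
   reads get the *same* raw counts in colonized and control samples.
   Because the colonized sample additionally contains ck-sRNA reads,
   its per-organism mapped total is strictly larger, so every
   endogenous sRNA has slightly negative log2FC after RPM
   normalization — and the induced 21-nt set equals the planted ck set
   *exactly*, making precision and recall well-defined at 1.0 rather
   than approximately high.
3. **Transcriptomes independent of genomes.** Target sites live in
   transcript sequences that are not genome substrings; planting a site
   can therefore never disturb genome uniqueness or read
   classification.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: realistic base composition or
k-mer spectra, sequencing errors and quality variation, hairpin
thermodynamics of miRNA precursors, isoform structure, partial
genome/transcriptome incompleteness, or biological replicate
variability in the sRNA counts (replication is modelled only in the
phenotype module). Real libraries will always yield softer
precision/recall than the planted-truth 1.0.

### Generator defaults

| parameter | default | meaning |
|---|---|---|
| `plant_genome_len` / `fungal_genome_len` | 50 kb / 25 kb | desk-scale genomes, two contigs each |
| `n_plant_mirna_loci` / `n_plant_sirna24_loci` | 8 / 8 | 21-nt and 24-nt plant locus counts |
| `n_fungal_loci_26` / `n_fungal_loci_29_30` | 6 / 6 | fungal locus counts |
| `n_ck_srnas_per_direction` | 20 | planted ck-sRNAs each way |
| `ck_len` | 21 nt | ck-sRNA length |
| `induction_factor` | 4 | colonized/control raw-count ratio of induced ck-sRNAs |
| `depth_per_sample` | 20 000 reads | per sample class |
| `noise_read_fraction` | 0.02 | unmappable random reads |
| `fiveprime_a_bias_24` | 0.7 | P(first base A) of 24-nt reads |
| `adapter_seq` | TruSeq small-RNA 3′ adapter | appended to every read |
| `de_effect_log2fc` | −1.5 | planted target fold change |
| `read_len` | 50 nt | insert+adapter truncation length |

The defaults *are* the study conditions; they were fixed once when the
generator was designed and are not tuned against test outcomes.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally; GFF3 export and the
  human-readable locus report convert to 1-based inclusive.
* Sequences are held uppercase in the DNA alphabet internally (U→T on
  input); report writers render sRNAs in the RNA alphabet.
* Collapsed-read tables sort lexicographically with radix (C-locale)
  ordering, so output is deterministic across locales.
* Ties: predominant locus sequence — lexicographically smallest among
  equal counts; DicerCall — smaller length; target sites — leftmost
  window; miRNA reference — fewest mismatches, then reference order.
* Percentages are half-up rounded (machine output: one decimal).
* The test suite runs the full pipeline at two scales: a "tiny"
  simulation (16 kb + 10 kb genomes, 3 000 reads/sample) for module
  tests, and the study-condition run (50 kb + 25 kb, 10⁴ reads/sample,
  zero noise, 20 ck-sRNAs per direction) for the end-to-end and
  conservation checks. These sizes keep the whole suite under a minute
  while leaving every distributional check comfortably powered (e.g.
  the binomial standard error of the 5′-A fraction at depth 10⁴ is
  ≈ 0.007 against a ±0.05 assertion band).

## Known limitations

* Exact-match classification discards genuinely multi-kingdom reads
  (the ambiguous class) rather than resolving them probabilistically.
* The expectation scorer has no bulges, no thermodynamics and no
  degradome evidence; confirmed duplexes are *candidates*, exactly as
  in the source analysis — validation requires degradome/AGO data.
* Locus calling has no hairpin test, so "miRNA locus" here means
  "locus whose predominant product matches a supplied mature
  reference".
* The DE tables are consumed, not fitted: the package deliberately does
  not re-implement count-model differential expression.
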