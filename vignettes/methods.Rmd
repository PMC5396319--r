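---
title: "Methods: integrating somatic lesions in CRLF2-rearranged ALL cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating somatic lesions in CRLF2-rearranged ALL cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crlf2landscape)
```

## The analysis model

A *CRLF2*-rearranged ALL cohort is observed through three partially
overlapping windows: whole-exome mutation calls on a sequenced subset,
paired-end structural variants (SVs) on the same subset, and copy-number
alterations measured cohort-wide by SNP arrays and targeted MLPA. The
package reduces all three to a single per-patient object — the **defective
gene set** — and builds every downstream statistic from it.

### Coordinates

Internally every interval is 0-based half-open, the BED convention. The
1-based formats are converted at their readers and nowhere else: VCF
positions lose 1 on read, SEG segments (1-based, inclusive ends) become
`[start - 1, end)`. One convention with conversion confined to the I/O
boundary removes the usual off-by-one drift between modalities. Overlap is
strand-agnostic — a somatic lesion damages a gene regardless of which
strand the gene is annotated on — so strand is stored but never consulted.

### The defective-gene rule

A gene is defective in a patient when it (1) carries at least one nonsilent
mutation, (2) sits at a breakpoint junction of a validated SV, or (3) lies
inside a focal copy-number region of at most 1 Mb. Decisions behind the
details:

* **Nonsilent** means protein-altering: missense, nonsense, frameshift,
  in-frame indel, splice. The consequence vocabulary is closed and the
  synonym map from VEP/SnpEff-style strings is explicit
  (`normalize_consequence()`); an unknown term is an error rather than
  silently "noncoding", because the whole rule hinges on this
  classification.
* **Validated SV** means ≥ 5 supporting read pairs and a breakpoint pair
  that spans coding sequence; candidates with both ends in the same intron
  or entirely outside genes are excluded. The exclusion is precomputed into
  an `annotation_context` column by the annotator so the filter itself
  (`filter_sv_candidates()`) stays a pure predicate on two fields.
* **1 Mb** is decimal (1,000,000 bp) and the cap is inclusive: a segment of
  exactly 1,000,000 bp qualifies. Binary mebibytes are not used in genome
  annotation. Both losses and gains qualify by default — recurrent focal
  amplifications are biologically "defective" too — with a `states =
  "loss"` switch for a deletions-only analysis.
* **MLPA** "deleted" calls are targeted single-gene copy-number assays and
  enter through criterion (3) directly; MLPA and array segments are pooled,
  deduplicated at the gene level. A gene hit by a copy-number-type SV
  breakpoint *and* a focal segment keeps both evidence tags on one entry.

Every tagged gene traces back to its supporting records
(`defective_evidence()`), so the sets are auditable.

### Hypergeometric enrichment

A group's pooled defective list (the union over its patients; each gene
once) of size $n$ is modelled as a draw without replacement from the $N$
protein-coding genes of the annotation; for a pathway of size $K$ with
observed overlap $x$ the p-value is $P(X \ge x)$ under
$X \sim \mathrm{Hypergeom}(N, K, n)$. The universe is a *parameter*
($N = 20{,}805$ for GRCh37.p13), not derived from the GMT, because pathway
collections cover only a fraction of the genome. Pooling the union is the
primary definition; a per-sample variant (test each patient, average) is
available behind `method = "per_sample"`.

Numerics: binomial coefficients via `lgamma`, each term exponentiated from
log space, and whichever tail has fewer terms is summed directly with the
other obtained by complement — so a p-value of $10^{-100}$ retains relative
accuracy instead of collapsing to `1 - 1`. The implementation is checked in
the tests against exhaustive subset enumeration (every parameter
combination with $N \le 25$, to $10^{-12}$) and against `stats::phyper` as
an independent route. Results are ordered by (p, pathway id) so output is
deterministic under ties; significance is unadjusted $p < .05$ (the
published analysis design), with Benjamini–Hochberg available as an
optional extra column.

The patient-by-pathway matrix counts each sample's defective genes per
pathway; per-sample totals count a gene once even when it belongs to
several displayed pathways. Top-$k$ display selection is by per-pathway
total with a lexicographic tie-break.

### Exact subgroup comparisons

Lesion frequencies between subgroups form 2×2 tables tested with the
two-sided Fisher exact test under **point-probability ordering**: all
tables with the observed margins whose point hypergeometric probability is
at most that of the observed table (relative tie tolerance $10^{-7}$)
contribute to $p$. Several two-sided conventions exist; this one is the
convention of mainstream statistical packages and reproduces the published
cohort p-values (IKZF1 $p < .001$, BTG1 $p = .004$, ADD3 $p = .008$).
Samples with unknown group status leave the denominators. No
multiple-comparisons adjustment is applied, matching the exploratory design
at the 5% level. Display follows the journal style — integer percentages,
3-decimal p-values with "< .001" below 0.0005 — while unrounded values are
retained in the tidy output.

The FISH cutoff is the control-slide false-positive mean plus three sample
standard deviations ($n-1$ denominator); only the upper bound is used,
since positivity calls act on false-positive excess, and a sample exactly
at the cutoff is negative. At least 100 scored nuclei are required.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage — file parsing included —
can be exercised and validated end-to-end. Its defaults *are* the published
cohort conditions:

| parameter | default | rationale |
|---|---|---|
| cohort size | 172 | published cohort |
| subtype mix | 47 IGH : 125 P2RY8 | published cohort |
| DS probability | 0.20 IGH / 0.35 P2RY8, ~6% unknown | published DS split |
| IKZF1 deletion | 0.71 IGH / 0.33 P2RY8 | published frequencies |
| BTG1, ADD3 | 0.31/0.09, 0.46/0.13 | published frequencies |
| CDKN2A/B, PAX5 | 0.38, 0.30 (both subtypes) | published cohort-wide rates |
| point mutations | Poisson(17) per patient | published mean |
| in/dels | Poisson(2.8) | 31 events / 11 patients |
| validated SVs | Poisson(12.7) | published mean |
| extra SV candidates | Poisson(30.3) | ~43 candidates/patient total |
| VAF | Beta(8, 10) | median ≈ 0.44, ~80% mass > 0.30 |
| low-VAF outlier | one patient, Beta(2, 10) | one published outlier patient |

The generator draws the *validated* SV burden directly and adds
non-qualifying candidates (low support, same-intron, non-coding) separately;
this pins the quantity the analysis consumes to its published mean while the
candidate total matches the discovery-stage burden. The nonsilent fraction
of point mutations is 0.75, a typical exome proportion of protein-altering
calls.

The toy genome is 3 chromosomes × 24 genes (50 kb genes every 400 kb), with
driver genes on fixed slots and CDKN2A/CDKN2B adjacent; tiling with gaps
makes interval edge cases (breakpoint exactly at a gene start, segments
straddling gene boundaries, >1 Mb segments that must *not* count) occur by
design. The toy pathway collection has ten sets with deliberate overlaps to
exercise the counted-once rule. For simulated data the background universe
is the number of genes that exist (72), not 20,805: the universe parameter
describes the annotation the data were drawn from, and using the real-genome
constant on a 72-gene toy would misstate every tail probability. Real
analyses pass `background_n = 20805`.

Reproducibility: one master integer seed; each sample's substream seed is a
deterministic function of (master seed, sample index), so enlarging a cohort
extends it without reshuffling existing samples, and two runs with the same
seed emit byte-identical files. Each simulated lesion's implied defective
genes are recorded at generation time, giving a per-sample truth set that
the pipeline must reproduce exactly from the emitted files — the
round-trip check that validates coordinate conversions in both directions.

### What the simulation does and does not establish

Passing tests on synthetic cohorts shows that the statistics are computed
correctly and that frequencies and planted signals are recovered under the
generative model: independent per-gene lesions, uniform placement within
genes, no clonal structure, no germline contamination, no caller error
model, no read-level noise. Real cohorts violate several of these
(co-occurring deletions, mutation hotspots, subclonal VAF structure), so
simulation results say nothing about caller accuracy or about which
pathways are truly enriched in patients — only that, given calls of this
shape, the integration and inference are faithful.

## Validation experiment sizes

The test suite runs three designed simulation experiments: frequency
recovery on 2,000-patient cohorts (≈1,000 per subtype arm, where the
binomial standard error of ±1.4 points makes a ±5-point band a 3.5σ
criterion) over 20 seeds; planted 5× enrichment on compact 10-patient,
mutation-only cohorts (small enough that the pooled union does not saturate
the 72-gene toy universe) over 100 seeds, requiring the planted pathway to
rank first; and null calibration on 12-patient cohorts with uniform lesion
probabilities over 200 seeds, where gene exchangeability makes the
hypergeometric null exact and the attained fraction of $p < .05$ tests must
stay at or below 10%. Exact-test correctness is established by full
enumeration: all hypergeometric parameters to $N = 25$ and every 2×2 table
with total ≤ 40.

## Known limitations

* Criterion (2) treats both breakpoints of copy-number-type SVs as junction
  genes even when the same event appears as a segment under criterion (3);
  the union deduplicates at the gene level, which matches pooled reporting
  but cannot distinguish the two mechanisms afterwards.
* The per-sample enrichment variant averages x, n and p across patients; it
  is a descriptive alternative, not an exact test.
* Gene models are plain intervals: no transcript structure, so "same
  intron" must be annotated upstream (the simulator assigns it
  geometrically).
* Survival/outcome analysis is out of scope by design.
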