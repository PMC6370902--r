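---
title: "Measuring variant-calling accuracy across a sequencing-depth titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring variant-calling accuracy across a sequencing-depth titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthconcord)
```

## The question the package answers

Choosing a whole-genome sequencing depth is a trade-off: depth buys genotype
accuracy, and accuracy saturates. The standard way to locate the saturation
point is a depth titration — subsample one deeply sequenced genome to a
ladder of target depths, call variants at each level, and score every call
set against a trusted reference (a SNP microarray of the same individual, the
full-depth call set itself, and wet-lab HLA types). `depthconcord` implements
that evaluation end to end as reusable, seeded, tested code. Because the raw
sequence data behind such studies is controlled-access, the package pairs the
scoring machinery with a synthetic-data generator that reproduces the
statistical structure the evaluation depends on, so every stage is testable
and the whole sweep runs on a desktop.

## The measurement model

**Depth stages.** Depth is total bases divided by the effective (non-N)
reference length. Six stages track a dataset through the pipeline: raw reads
(RRD), after adapter trimming (RRDaT), after mapping (MRD), after duplicate
removal (URD, the x-axis of every accuracy curve), mean DP over variant
records (VD), and mean DP over filter-passing records (VDaF). The first four
can only lose depth; VD and VDaF can *exceed* URD at very low depth because
only covered sites yield records — the mean of a zero-truncated Poisson is
above its unconditional mean. `reduction_percent()` and `fold_change()`
express stage-to-stage changes; presentation rounding is one decimal,
half-up.

**Genotype concordance.** For every truth-panel site the call set contributes
a diploid genotype; sites absent from the VCF are assessed as hom-ref.
Crossing truth by call genotype over \{Ref/Ref, Ref/Alt, Alt/Alt\} gives a
3×3 matrix, with one extra tally: a non-reference call whose alternate
allele differs from the truth allele is *alt-discordant* and counts as a
false positive. Four indices summarize the matrix:

* **CR** — diagonal / all truth sites;
* **FPR** — (truth Ref/Ref called non-ref + alt-discordant) / all truth sites;
* **FNR** — truth non-ref called Ref/Ref / all truth sites;
* **NTPR** — concordant non-ref calls / truth sites carrying any non-ref
  call (alt-discordant included).

The matrix graphic in the source analysis does not transcribe the NTPR cell
formula; the definition above ("confined to sites where the sequencing data
made a call") is the one adopted here, and it is isolated in
`compute_metrics()` so a different reading changes one function. A
site-by-site brute-force recount in the test suite guarantees the matrix
path and the definition agree exactly.

**Stratifications.** Heterozygote-only CR (the truth-Ref/Alt row of the
matrix) isolates the genotype class most sensitive to allele dropout.
Alternate-allele-frequency strata use five bins — <0.01, 0.01–0.05,
0.05–0.1, 0.1–0.5, ≥0.5 — half-open on the low side, with 0.5 in the top
bin, matching the printed labels.

**All-reads comparison.** Genome-wide (off-array) accuracy uses the
maximum-depth call set as the truth parameter. SNVs reuse the matrix
convention (absent ⇒ hom-ref; the alternate allele must match). Indels are
concordant only when position *and* both allele strings are identical —
`100:AT>A` against `100:ATT>A` is discordant. Genotype is deliberately not
part of the indel rule.

**Hard filter.** The per-annotation exclusion rules are strict inequalities
exactly as specified — SNVs: QD < 2.0, FS > 60.0, MQ < 40.0,
MQRankSum < −12.5, ReadPosRankSum < −8.0, HaplotypeScore > 13.0, SOR > 3.0;
indels: QD < 2.0, FS > 200.0, ReadPosRankSum < −20.0, SOR > 10.0 — so
boundary values pass. An absent annotation never triggers its rule (the
GATK VariantFiltration convention; rank sums are undefined at hom-alt sites,
and the simulator emits them as missing there to keep that path honest).
Every failed item is recorded, and `exclusion_rates()` counts a record once
per failed item. Model-based recalibration (VQSR) is not implemented; the
pipeline's filtration strategy is pluggable and ships a pass-through
strategy in that role.

**HLA concordance.** Four-digit genotypes are unordered allele pairs per
classical gene. Scoring is per-allele credit — the maximum multiset matching
between truth and call pairs over two, giving 0, 0.5 or 1 — because
replicate-averaged per-gene accuracies ending in odd decimals require
sub-genotype granularity; a hom truth \{X,X\} against \{X,Y\} scores 0.5.
Per-gene accuracy is the replicate-mean score ×100 (one decimal, half-up);
per-tool averages are unweighted means over *available* genes only — six for
PHLAT and HLA-VBseq, which cannot type DPA1/DPB1, eight otherwise. The
report generator treats additional depth columns (e.g. a three-digit-depth
column) as further applications of the same arithmetic.

## What the generator emulates — and what it does not

The generator replaces everything upstream of the VCF: read simulation,
alignment, duplicate marking, the callers, and the external HLA tools. Its
defaults are the study conditions; they are set once, from the design of the
emulated experiment and from field-standard magnitudes, and the tests run
against them.

* **Truth catalog.** Distinct positions on one contig; AAFs from a
  beta(0.25, 0.8) spectrum (rare-variant-heavy, all five bins populated);
  genotypes from Hardy–Weinberg at each site's AAF; SNV alleles mixed to a
  Ts/Tv target of 2.1; indels 1–3 bp. Hom-ref genotypes persist only on the
  array subset (an array probes a site regardless of the carrier state; a
  non-array truth site is by definition a variant the individual carries, so
  hom-ref draws there are resampled conditional on a non-reference
  genotype). Array membership is SNV-only (`array_fraction`, default 0.13,
  roughly a 564k-SNP panel against a 4.3M-variant genome); array QC
  metadata are drawn so that a realistic few percent of panel sites fail
  the call-rate/HWE/MAF/multi-allelic exclusions.
* **Coverage and genotype error.** Per-site read counts are
  Poisson(depth) — depth is simulated per site, not per read position,
  because the evaluation consumes genotype calls, and per-site sampling
  reproduces the depth–missingness law exactly
  (P(uncovered) = e^{−d}). Sites below the callable floor (default 1 read)
  are absent. Heterozygous reads split Binomial(k, ½): all-reference draws
  lose the site (dropout to an implicit hom-ref), all-alternate draws
  miscall hom-alt. This mechanistic channel dominates the depth response;
  small flat per-site rates (het 2×10⁻³, hom-alt 5×10⁻⁴, spurious het at
  covered array hom-ref sites 10⁻³, wrong-alternate 10⁻³) model residual
  caller error, and false-positive records appear at non-truth positions at
  a coverage-scaled rate (10⁻² per truth site).
* **Annotations.** No annotation distributions are published for the
  emulated pipeline, so each of the seven filtration annotations mixes a
  "clean" component drawn inside the passing range with an "artifact"
  component that violates the record's own threshold, at a small per-item
  weight (0.2–0.3%). The HaplotypeScore artifact weight additionally grows
  as 0.25·log₁₀(depth/100) above 100×, emulating haplotype-count inflation
  in very deep data — at 410× that yields ≈15% HaplotypeScore exclusions.
* **Read accounting.** Stage depths derive from retention factors: fixed
  trimming (0.97) and mapping (0.98) retention, and duplicate loss
  saturating as 0.33·d/(d+25) — deeper libraries lose proportionally more,
  reproducing a ≈34% raw-to-variant loss for a ≈500× library against ≈13%
  near 10×.
* **HLA calls.** Per-allele miscall probability
  1 − (1 − floor)·(1 − e^{−d/3}): random at vanishing depth, saturating at a
  per-tool floor (PHLAT 0.15, HLA-VBseq 0.12, HLA-HD 0.01, HISAT-genotype
  0.03, SNP2HLA 0.05 — the accuracy tiers the emulated tools exhibit at
  high depth). A miscall is drawn from a per-gene pool of common alleles
  excluding the true genotype, so a wrong call never earns accidental
  partial credit. The default truth genotypes are the evaluated
  individual's wet-lab types.

What passing tests on this generator show about real data is therefore
limited and explicit: the *scoring* definitions, the replicate policy, the
filter rules and the arithmetic are exercised exactly; the *accuracy values*
at a given depth reflect the configured error model, not any particular
sequencing platform. Features deliberately not emulated: read-level
artifacts (mapping ambiguity, strand bias structure, indel realignment),
linkage between neighbouring sites, structural variants, population allele
sharing, and the internals of VQSR or the HLA callers.

## Titration design, seeds and replicates

The default schedule is a union of log- and linear-spaced levels trimmed to
54 values spanning 0.05×–410× (the exact published levels are not
enumerated; the schedule is configurable). Depths strictly below 45× get 10
independently seeded replicate datasets whose metric values are averaged;
45× and above get one. Every dataset seed is
`base_seed + 1000·depth_index + replicate_id`, so a sweep is reproducible
file-for-file; sweep outputs are written with fixed numeric formatting so
reruns are byte-identical. Subsampling uses Bernoulli thinning (the
semantics of samtools `view -s`) rather than exact counts, consistent with
the per-site Poisson model.

## Numerical and degenerate-input choices

* Half-up rounding (not banker's) for all presented one-decimal values,
  with a √ε guard against binary representation error in decimal sums.
* Ts/Tv with zero transversions, NTPR with an empty non-reference-call
  denominator, and variant depth on an empty record set are undefined:
  reported missing (first two) or rejected (last), never coerced to 0.
* The replicate threshold is read strictly (`< 45`): exactly 45× runs one
  replicate.
* Matching key for site comparison is (chrom, pos, ref); multi-allelic
  query records are excluded from panel comparison and counted, mirroring
  the array-side multi-allelic exclusion.
* An empty AAF bin yields no row rather than NaN metrics.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  genome_length = 1e8, n_variants = 20000, array_fraction = 0.7,
  depth_schedule = c(0.5, 5, 13.7, 30), base_seed = 1
)
run_sweep(cfg, "sweep_out")
rep <- make_report("sweep_out", threshold_cr = 0.99)
subset(rep$summary, stratum == "all" & metric == "cr")
rep$cr_threshold_depth
```

The test suite and the acceptance script run the same machinery at fixed
problem sizes chosen to make the statistical checks sharp at desk scale:
50,000 array sites for error-rate recovery (3 binomial standard errors),
20,000 truth sites for the Poisson-missingness and spectrum-recovery laws,
and an 8-depth sweep (0.1×–50×, 10 replicates below 45×, 10,000 sites) for
the monotonicity and reproducibility checks. The sweep's depth levels are
concentrated below 10× because that is where accuracy changes fastest —
above saturation, adjacent levels differ by less than replicate noise and a
monotonicity check would be uninformative.

## Known limitations

* The error model is per-site and conditionally independent across sites;
  it cannot reproduce locally correlated error (segmental duplications, the
  MHC's mapping difficulty) — which is precisely why the HLA arm is modeled
  separately with its own error floors.
* The pass-through strategy stands in for VQSR's *role* in the pipeline,
  not its behaviour; filtration comparisons in this package are therefore
  hard-filter-vs-none, nothing more.
* Indel representation is not normalized (no left-alignment); the
  identical-string concordance rule assumes both call sets emit indels in
  the same representation, which holds for the simulator but not for
  arbitrary caller pairs.
* One contig, one individual, single-sample calling; joint calling and
  imputation-based designs are out of scope.
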