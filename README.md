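# depthconcord

How much sequencing depth does accurate germline variant calling need?
`depthconcord` answers that question the way depth-titration studies do:
build a ladder of whole-genome call sets at target mean depths, score each
one against trusted references, and read the depth at which accuracy
saturates off the resulting curves. It is written for statistical
geneticists and sequencing-core analysts who want the titration machinery —
concordance definitions, filtering rules, replicate policy, reporting — as
tested, seeded, reusable code rather than one-off scripts.

The package couples the scoring machinery to a synthetic-data generator
that emulates the upstream pipeline (coverage, caller errors, annotation
distributions, HLA typing), so the full sweep runs on a desktop with no
controlled-access data.

## The measurements

For a truth panel *T* and a call set *Q* (sites absent from *Q* are
assessed as hom-ref), the 3×3 genotype matrix over {Ref/Ref, Ref/Alt,
Alt/Alt} plus an alt-discordant tally *D* (non-reference calls whose
alternate allele differs from truth) yields:

- CR = Σ diag / |T|
- FPR = (#{truth RR, call ≠ RR} + D) / |T|
- FNR = #{truth ≠ RR, call RR} / |T|
- NTPR = #{concordant non-ref calls} / #{sites with any non-ref call, D included}

plus heterozygote-only CR, metrics stratified into five alternate-allele
frequency bins (<0.01 … ≥0.5), Ts/Tv ratios, GATK-style hard-filter
exclusion rates (QD, FS, MQ, rank sums, SOR, HaplotypeScore; strict
thresholds, missing annotations pass), six pipeline depth stages
(RRD → VDaF), concordance against the maximum-depth "all reads" call set
(indels require identical ref/alt strings, not just position), and
four-digit HLA genotype accuracy per gene and tool (per-allele credit
0/0.5/1, unweighted per-tool averages over available genes). Depths
strictly below 45× are simulated as 10 seeded replicates and averaged.

## Worked example

```r
library(depthconcord)

cfg <- sim_config(genome_length = 1e8, n_variants = 20000,
                  array_fraction = 0.7,
                  depth_schedule = c(0.5, 5, 13.7, 30), base_seed = 1)
run_sweep(cfg, "sweep_out")
rep <- make_report("sweep_out", threshold_cr = 0.99)
subset(rep$summary, stratum == "all" & metric == "cr")
```

```
 target_depth stratum metric      mean           sd n_replicates
          0.5     all     cr 0.6347731 0.0020961556           10
          5.0     all     cr 0.9494632 0.0019680365           10
         13.7     all     cr 0.9899463 0.0013698086           10
         30.0     all     cr 0.9910322 0.0008593845           10
```

Each row is the replicate-mean concordance rate against the QC-filtered
array-like truth panel at one target depth: about 63% of panel genotypes
are recovered at 0.5× (most sites are uncovered and default to hom-ref),
95% at 5×, and the curve saturates near 99% past ~14×.
`rep$cr_threshold_depth` reports the first scheduled depth whose mean CR
exceeds the threshold (here 30, since 13.7× lands at 0.98995 — just under
0.99). Stage arithmetic works the same way on published depths:

```r
reduction_percent(523, 359)   # 31.4  (% depth lost raw reads -> filtered variants)
reduction_percent(10.5, 9.1)  # 13.3
fold_change(0.052, 2.36)      # 45.38462  (low-depth URD -> VDaF inversion)
```

`rep$hla` tabulates per-gene/per-tool HLA accuracy with an `Average` row;
tools that cannot type DPA1/DPB1 show `NA` there and average over six
genes.

A thin command-line wrapper ships at `inst/cli/depth-sweep.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/depth-sweep.R", package="depthconcord"))')" \
  --outdir sweep_out --depths 0.5,5,13.7,30 --seed 1
```

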