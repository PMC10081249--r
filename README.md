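# splicefidelity

Quantify splicing accuracy from RNA-seq split-read junction tables.

Splice-site selection is imperfect: a fraction of splicing events use a
cryptic donor or acceptor near an annotated one, and these events surface in
RNA-seq as split reads sharing exactly one boundary with an annotated
intron. `splicefidelity` classifies exon–exon junctions against a transcript
annotation, assigns each novel junction uniquely to an annotated intron, and
summarises splicing fidelity per intron with the **mis-splicing ratios**

```
MSR_D = Σ j_i / (Σ j_i + Σ s_i)        MSR_A = Σ a_i / (Σ a_i + Σ s_i)
```

where `j_i`, `a_i`, `s_i` are the novel-donor, novel-acceptor and annotated
read counts of sample *i* for one intron, pooled over the sample set.
`MSR = 0` is fully accurate splicing at that site; `MSR = 1` complete
mis-splicing. Around this core the package provides:

* **Readers and QC** for regtools BED12 and STAR `SJ.out.tab` junction
  dialects, GTF annotations (Ensembl/GENCODE, MANE tags, biotypes),
  blacklist BEDs and bedGraph score tracks; filters for implied intron
  length (25–1,000,000 bp), unplaced contigs, blacklist overlap, RIN ≥ 6
  and minor-spliceosome introns.
* **Splice-site strength**: 5'ss 9-mer / 3'ss 23-mer scoring with a loader
  for the published maximum-entropy parameter tables and a bundled toy PWM
  model with the same interface; `delta = score(annotated) − score(novel)`
  per novel junction.
* **Novel-site geometry**: transcript-oriented signed distances (negative =
  intronic side, so the AG-exclusion zone appears as a gap at small
  negative acceptor distances), ±30 bp profiles stratified by coding use,
  and the reading-frame (mod-3) frameshift analysis restricted to MANE,
  exclusively protein-coding introns within 100 bp.
* **Covariate models**: per-intron OLS of MSR_D / MSR_A on ten gene- and
  intron-level covariates (gene length, median TPM, transcript count,
  protein-coding fraction, site strengths, conservation and constraint
  window means over −5/+35 and −35/+5 bp), with BH/Bonferroni q-values.
* **Matched comparisons**: greedy caliper matching (log10 coverage 0.005;
  RIN 0.05), paired/unpaired Wilcoxon tests with continuity correction,
  rank effect sizes r = |Z|/√N and superiority probabilities, and age
  stratification into the closed bins 20–39 / 40–59 / 60–79.
* A **seeded synthetic-data generator** (annotation + genome + junction
  tables + metadata with serialized ground truth) so the whole pipeline is
  testable end to end offline.

Everything is tibble-in / tibble-out and pipes cleanly; fitted models have
`tidy()` / `glance()` methods, and result types have `plot_*()` helpers.

## Worked example

Simulate a small study with known truth, run the core analyses:

```r
library(splicefidelity)
library(dplyr)

cfg <- sim_config(n_genes = 10, n_samples = 6, depth = 300, seed = 42)
sim <- simulate_dataset(cfg)

cls <- classify_and_assign(sim$junctions, sim$annotation)
count(cls, category)
#>   category           n
#> 1 annotated         36
#> 2 novel_acceptor   646
#> 3 novel_donor      648

msr <- compute_msr(cls, sim$junctions)
arrange(msr, desc(msr_a)) |> head(3)
#>   intron_id sum_annotated_reads sum_novel_donor_reads sum_novel_acceptor_reads msr_d msr_a
#> 1        23                1222                   163                      379 0.118 0.237
#> 2        10                1201                   173                      372 0.126 0.236
#> 3        30                1257                   205                      366 0.140 0.226

d <- junction_distances(cls, sim$annotation)
modulo3_analysis(d)
#>     n frac_mod0 frac_mod1 frac_mod2 frameshift_fraction
#> 1 648     0.355     0.312     0.333               0.645

deltas <- delta_mes(cls, sim$annotation, sim$genome, toy_splice_model())
summarise(deltas, .by = kind, median_delta = median(delta))
#>   kind     median_delta
#> 1 acceptor         25.2
#> 2 donor            16.8
```

The 36 annotated junctions are the generator's introns; the ~1,300 novel
junctions are planted mis-splicing events. The mis-splicing ratios track the
generator's per-intron truth (`cor ≈ 0.99` at this depth), about 64% of
novel sites shift the reading frame (the generator's in-frame fraction is
0.4), and median delta scores are positive at both sites — novel sites are
weaker than their annotated partners, as expected when cryptic sites sit in
unconstrained sequence.

The full workflow — QC, classification, MSR, deltas, geometry, covariate
models, age comparison, with one TSV per stage and a checksum manifest — is

```r
run_pipeline(pipeline_config(sim = cfg), out_dir = "results/")
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --simulate --out results/`
(file-based inputs: see `?pipeline_config`).

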