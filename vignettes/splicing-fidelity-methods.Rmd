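---
title: "Quantifying splicing fidelity from split-read junctions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing fidelity from split-read junctions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefidelity)
library(dplyr)
```

## The problem

Spliceosomal intron excision is accurate but not perfect. In bulk RNA-seq,
imperfect splice-site selection leaves a trace: split reads whose gapped
interval shares exactly one boundary with an annotated intron. Reads sharing
the acceptor but not the donor boundary evidence a *novel donor* event
(mis-selection at the 5' splice site); reads sharing only the donor boundary
evidence a *novel acceptor* event. `splicefidelity` turns per-sample
exon–exon junction tables into per-intron estimates of mis-splicing
frequency and a set of downstream analyses: splice-site strength deltas,
novel-site geometry, covariate models of splicing fidelity, and matched
two-group comparisons.

## Junction classification and unique assignment

A junction is compared with the intron catalog extracted from a GTF
annotation (gaps between consecutive exons of each transcript, deduplicated
by coordinates and strand). The *novel* end names the category:

* exact interval match — `annotated`;
* acceptor boundary matches some intron's acceptor, donor does not —
  `novel_donor`;
* donor matches, acceptor does not — `novel_acceptor`;
* both ends match boundaries but the pairing is unannotated —
  `novel_combination` (putative exon skipping);
* neither — `unclassified`.

`novel_combination` and `unclassified` junctions are reported but excluded
from all downstream statistics: the three-class scheme underlying the
mis-splicing ratios has no interpretation for them. Strand-unknown
junctions adopt the strand of a unique match and are otherwise discarded as
ambiguous.

When the shared boundary belongs to several introns (annotation-level
alternative donors/acceptors), the junction must be assigned to exactly one
intron. The rule is: highest total annotated read count across the sample
set, then shortest intron, then smallest start coordinate. The read-support
argmax reflects that the mis-spliced product most plausibly derives from
the intron that is actually being spliced in the tissue; the remaining
tie-breaks only make the choice deterministic. This rule is this package's
construction — any deterministic rule would do for the statistics — and is
validated against an exhaustive all-pairs matcher in the test suite.

## Quality control

Defaults follow the values used throughout the analyses this package
supports: junctions with an implied intron shorter than 25 bp or longer
than 1,000,000 bp are removed, as are junctions on non-listed contigs or
overlapping a blacklist region by at least 1 bp (the junction table does
not carry exonic anchors, so only the intron interval is tested). Samples
need RIN ≥ 6. Introns spliced by the minor spliceosome (supplied as an
exact-coordinate list) are removed together with the junctions assigned to
them, since their splice-site consensus differs from the major-spliceosome
sequences every other stage assumes. The "shorter than 25 bp" rule is
interpreted as the implied intron length, consistent with a 25 bp
minimum-intron setting at junction extraction.

## Mis-splicing ratios

For one intron and a sample set, reads are pooled across samples before the
ratio is formed:

$$\mathrm{MSR}_D = \frac{\sum_i j_i}{\sum_i j_i + \sum_i s_i}, \qquad
  \mathrm{MSR}_A = \frac{\sum_i a_i}{\sum_i a_i + \sum_i s_i},$$

where $j_i$, $a_i$ and $s_i$ are the novel-donor, novel-acceptor and
annotated read counts of sample $i$ for that intron. Pooling (not averaging
per-sample ratios) is load-bearing: with unbalanced depths the two differ,
and the test suite pins the pooled form. A zero denominator yields `NA` —
the ratio has no smoothing or pseudocounts — and such introns are excluded
from downstream tests. 0 means fully accurate splicing at that site, 1
complete mis-splicing.

Category composition is summarised two ways: `p_unique` counts
junction–sample occurrences (a junction seen in k samples contributes k,
following the summation form of the percentage definitions), and
`p_unique_distinct` deduplicates across samples; both are emitted, the
former is primary. `p_reads` uses cumulative read counts.

## Splice-site scoring

Sites are scored on the standard windows: 9 bp at the 5'ss (3 exonic + 6
intronic bases) and 23 bp at the 3'ss (20 intronic + 3 exonic), always in
transcript orientation. Two models share one interface:

* `read_mes_model()` loads the published maximum-entropy parameter tables
  (donor: consensus GT dinucleotide odds times a 4^7 table over the
  remaining 7-mer; acceptor: consensus AG odds times nine composed
  sub-sequence models with segment lengths 7,7,7,7,7,3,4,3,4). Supply the
  table directory at run time.
* `toy_splice_model()` is a bundled position-weight log-odds model over the
  same windows, built in code from consensus-like base frequencies. It
  keeps the whole pipeline runnable and testable with no external files;
  its scores are comparable within a model, not across models.

Sequences containing non-ACGT bases are skipped (not imputed) and tallied.
The delta score of a novel junction is the annotated site's score minus the
novel site's score, so positive deltas mean the novel site is weaker. On
generated data, where annotated sites carry consensus-like context and
novel sites sit in random sequence, median deltas are strongly positive at
both site kinds.

## Novel-site geometry

Distances between a novel site and its intron's annotated site are signed
so that **negative is always the intronic side**, at both site kinds and on
both strands: donors use `annotated − novel` on the plus strand (mirrored
on the minus strand), acceptors use the mirrored formula. The two published
conventions — a strand-flipped coordinate difference and the requirement
that acceptor-side suppression sit on the intronic side — disagree for
acceptors on the plus strand; the kind-aware mirror resolves this with one
uniform semantics, and places the AG-exclusion-zone (AGEZ) gap at small
negative acceptor distances.

Distance profiles are binned within ±30 bp and stratified by whether the
intron is used exclusively by protein-coding transcripts. The reading-frame
analysis keeps novel junctions strictly closer than 100 bp to their
annotated site and, by default, restricts jointly to introns of MANE Select
transcripts that are exclusively protein-coding (both restriction flags are
exposed and can be applied separately). `mod3` is the mathematical modulus
of the signed distance (in {0,1,2}; mod3 of −4 equals mod3 of +2), and the
frameshift fraction is the mass off class 0.

## Covariate models of mis-splicing

Per intron, ten covariates feed an OLS model for each response
($\mathrm{MSR}_D$, $\mathrm{MSR}_A$): gene length (exon-span by default;
a merged-exon-length definition is used for TPM denominators), median gene
TPM across samples, the gene's transcript count, the intron's
protein-coding-transcript fraction, the maximum-entropy scores of its two
sites, and mean conservation (phastCons-like) and constraint (CDTS-like)
track scores over the proximal windows −5/+35 bp around the 5'ss and
−35/+5 bp around the 3'ss, transcript-oriented. Intron length is carried as
an additional predictor. Track bases without data are excluded from the
window mean rather than zero-filled, and windows under 50% coverage are
undefined (the row is dropped and tallied). Covariates are used
untransformed by default because the effect sizes of interest are reported
on the raw scale; a z-scoring switch exists but defaults off.

p-values are two-sided per coefficient; q-values come from BH by default,
computed across whatever family is submitted together
(`adjust_across_fits()` pools the donor- and acceptor-side fits). The
response is a [0,1]-bounded, zero-inflated ratio fit by ordinary least
squares — deliberately the plainest model whose coefficients read directly
on the MSR scale; a beta-regression alternative is a known improvement left
out of scope. The
same `fit_linear()` machinery serves the expression-versus-age analyses,
with `encode_categorical()` mapping categorical sample covariates to
integers — statistically crude, and documented as such.

## Matched comparisons

`match_by_value()` implements deterministic greedy nearest-neighbour
matching without replacement (descending value order, caliper on the raw or
log10 scale). Off-the-shelf matching tools do not expose a reproducible
pairing order; the greedy rule is auditable, and its optimality gap is
bounded against an exhaustive assignment oracle in tests.
Default calipers: 0.005 on log10 mean coverage for intron matching between
tissues, 0.05 on RIN for sample matching across age bins (closed bins
20–39, 40–59, 60–79; a body site needs 25 samples per bin and 75 overall;
the two older bins are down-sampled against the youngest).

Group comparisons use the Wilcoxon signed-rank test (paired, zeros dropped
per the signed-rank convention — mis-splicing tables contain many exact
zeros, so this materially affects n) or the rank-sum test, with exact
null distributions for small n and the continuity-corrected normal
approximation otherwise. Effect sizes are $r = |Z|/\sqrt{N}$ (N = pairs
for paired, total observations otherwise) with Z recomputed from the rank
statistic with tie correction, plus the superiority probability
$P(\text{case} > \text{control})$ with ties counted half. Bonferroni is the
default family adjustment for knockdown-style batches, BH elsewhere.

## The synthetic-data generator

The generator exists so that every stage is testable end to end without
downloads, with ground truth serialized alongside the data.

* **Annotation/genome**: genes on both strands across two chromosomes;
  every intron carries consensus-like donor (`CAG|GTAAGT`) and acceptor
  (pyrimidine tract + `CAG|G`) context with the invariant GT/AG fixed and
  the remaining consensus bases 15% degenerate, so annotated site
  strengths vary; one MANE Select protein-coding transcript per gene,
  extra transcripts lncRNA with configurable probability. Exon lengths are
  log-normal with median ≈ 120 bp (the typical human exon); intron lengths
  log-normal with a 150 bp floor so the offset and AGEZ geometry always
  fits.
* **Reads**: per intron and sample, a Poisson total (default mean 300) is
  split multinomially into novel donor / novel acceptor / annotated reads
  with probabilities $(\pi_D, \pi_A, 1-\pi_D-\pi_A)$. Marginally the novel
  counts are Binomial$(n, \pi)$; conditional on the donor-side total the
  novel donor count is Binomial with success probability
  $\pi_D/(1-\pi_A)$, which is exactly what $\mathrm{MSR}_D$ estimates, so
  the truth table stores both the raw $\pi$'s and these MSR-scale truths.
  Per-intron $\pi_D$ comes from a mixture with a point mass at 0 (30% of
  introns by default, matching the idea that many introns show no
  detectable mis-splicing) and $\pi_A = 2\pi_D$ by default, reflecting the
  higher acceptor-side noise seen in real tissues.
* **Offsets**: each novel read is placed at a signed offset with
  geometrically decaying weight in |offset| (so mass concentrates near the
  annotated site), an in-frame (mod3 = 0) fraction f = 0.4 by default, and
  an 18 bp acceptor dead zone on the intronic side emulating the AGEZ.
  Offsets that would collide with an annotated boundary are excluded from
  the support so the generator and classifier agree by construction.
* **Metadata**: RIN ~ Normal(7.5, 1.2) truncated to [0, 10]; ages uniform
  over 20–79; an optional multiplier on the mis-splicing probabilities of
  samples aged 60–79 plants an age effect for end-to-end power checks.

One seed drives everything; annotation, metadata and reads use derived
substreams so each stage is independently reproducible.

What the generator does **not** emulate: alignment and sequencing error,
anchor-length effects, intron retention, NMD-driven depletion of
frameshifted products, expression structure beyond a flat Poisson depth,
and correlated mis-splicing across introns of one gene. Tests passing on
this generator therefore validate the statistical machinery and the
bookkeeping, not the biology of any particular real dataset.

## Numerical choices and degenerate inputs

* MSR with zero denominator, window means with <50% coverage, and
  comparisons with empty intron intersections are `NA`/errors, never
  silently imputed.
* Contamination rate `100·j/y` with `y = 0` is flagged undefined rather
  than raising a division error; values over 100% are possible by
  construction (j and y are disjoint counts) and flagged, not clamped.
* The assignment and matching tie-breaks are total orders, making
  classification, assignment and matching invariant to input order; tests
  assert order invariance explicitly.
* Analysis sizes in the test and acceptance runs (≈200–250 introns, 30
  samples, 300 reads per intron; 500 introns for the two-group checks;
  5,000 rows and 100 replicates for the regression recovery) were chosen as
  the smallest sizes at which the binomial and OLS sampling theory used by
  the checks is comfortably in its asymptotic regime.

## Known limitations

OLS on a bounded zero-inflated response; integer encoding of categorical
covariates in the reused linear-model path; greedy (not optimal) matching;
junction-level (not base-level) coverage as the matching variable where
"mean coverage" is ambiguous — each is the simplest faithful choice, noted
where it matters. The bundled toy splice-site model is a PWM, not a
maximum-entropy model; real parameter tables plug in through
`read_mes_model()` without code changes.
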