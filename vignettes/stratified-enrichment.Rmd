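---
title: "Stratified enrichment and FDR for GWAS summary statistics: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified enrichment and FDR for GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stratfdr)
```

This vignette is the package's own account of its statistical machinery:
the model each stage assumes, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, the numerical
and design choices that were genuinely open, and the known limitations. It
states no empirical result that the test suite does not itself compute.

## 1. LD-weighted annotation

A GWAS tag SNP is a proxy for every variant it tags through linkage
disequilibrium (LD). Annotating the tag SNP by its own position alone
discards that structure, so the package scores each tag SNP `t` against a
reference panel:

score_c(t) = Σ_s r²(t, s) · 1[category(s) = c],

summing over panel SNPs `s` within a window of `t`, where `r²` is the
squared Pearson correlation of allele dosages (composite LD from unphased
genotypes, pairwise-complete over individuals) and every SNP tags itself
with `r² = 1`. Small correlations are noise-dominated and are zeroed below
a threshold.

Parameters (`scoring_config()`):

| parameter | default | meaning |
|---|---|---|
| `r2_min` | 0.2 | pairwise r² below this is set to 0 |
| `window` | 1e6 bp | LD computed within ±1 Mb of the tag SNP |
| `score_threshold` | 1.0 | continuous score at which membership binarizes |
| `precedence` | UTRs > exon > intron > proximal > distal flanks | positional tie-break |

The alternate, more inclusive parameterization (`r2_min = 0.05`,
`window = 2e6`) is supported; scores under it dominate the default scores
SNP-by-SNP (a monotonicity property the tests assert).

The eight positional categories are assigned mutually exclusively from one
transcript per gene (first in file order by default, longest optionally).
Two open points the source material left unspecified were decided here:

* **Strand.** Upstream/downstream flanks (1 kb and 1–10 kb) are measured
  along the transcription direction. Positional annotation of regulatory
  flanks is biologically meaningless otherwise.
* **Overlap precedence.** When elements of different genes cover the same
  position, the rarer and more specific element wins: 5′ UTR > 3′ UTR >
  exon > intron > 1 k up > 1 k down > 10 k up > 10 k down (configurable).
  Flank distances are measured from the transcription start/end, not from
  exon boundaries.

Membership is non-exclusive — a tag SNP belongs to every category whose
score reaches 1.0 — because a single SNP genuinely tags variants in
several element types. Since the self pair contributes 1.0, every genic
tag SNP is automatically a member of its own positional category.

**Intergenic SNPs** are defined negatively and strictly: all eight scores
zero *and* no LD partner (including the SNP itself) within 100 kb of any
protein-coding gene nor inside user-supplied masks (noncoding RNA, TFBS,
miRNA binding sites). When no masks are supplied the mask criterion is
skipped with a warning rather than silently: the stratum is then slightly
more permissive than its definition. This stratum is the package's working
approximation to a set of true nulls.

## 2. Intergenic inflation control

Population stratification and cryptic relatedness inflate test statistics
multiplicatively; standard genomic control estimates the inflation factor
λ_GC from *all* SNPs, which over-corrects polygenic traits because real
signal contributes to the median. Estimating on intergenic SNPs only
minimizes that contamination.

λ_GC = quantile_q(z²) / F⁻¹_χ²₁(q), default q = 0.5.

Decisions:

* "Statistics divided by λ" is interpreted on the χ² scale: `z² ← z²/λ`,
  i.e. `z ← z/√λ`, signs preserved, p-values recomputed. λ_GC is defined
  on the z² scale and 1-df χ² statistics are what genomic control
  classically divides; this is flagged here as an interpretation.
* λ < 1 is allowed and scales statistics *up* — summary statistics that
  already went through standard genomic control are often over-corrected.
* The 0.95 quantile variant exists for phenotypes whose enrichment is
  confined to the extreme tail, but is never auto-selected: no principled
  trigger rule is available, so the caller must opt in.
* p-values are floored at 1e−300 before conversion to z to avoid infinite
  scores; p = 0 is an error instructing the caller to clip.

## 3. Stratified Q-Q curves, FDR and TDR

For each stratum the empirical cdf is q(p) = #{pᵢ ≤ p}/N (at-or-below
counting, so tied p-values share a quantile). With the null cdf uniform
and the null proportion π₀ conservatively set to 1, the empirical-Bayes
point estimate of the false discovery rate at cutoff p is

FDR(p) = p / q(p), clamped to [0, 1]; TDR = 1 − FDR.

On −log₁₀ axes the pre-clamp estimate is the horizontal shift of the
stratified Q-Q curve from x = y. Clamping (p > q happens routinely in the
bulk of the distribution) and π₀ = 1 both bias the FDR upward, so TDR
estimates are conservative. No π₀ estimation is attempted. The
genome-wide-significance display cap (−log₁₀ p = 7.3) offered by
`write_curves()` is presentation-only; all computation uses uncapped
values.

Enrichment is summarized per stratum as `mean(z²) − 1`: with a standard
normal null and a symmetric non-null component, the excess of the second
moment over 1 estimates the variance attributable to non-null SNPs
(π₁σ₁² under the generator's mixture). Normalization by the per-phenotype
maximum makes patterns comparable across phenotypes; if no stratum has a
positive raw score the normalized column is undefined and flagged.

KS enrichment tests compare a stratum's test statistics against the
intergenic stratum. Because LD correlates statistics, both strata are
randomly pruned to approximate independence (greedy: visit SNPs in seeded
random order, keep unless a kept SNP is in LD at `r² ≥ 0.2`) ten times;
the reported p-value is the one attached to the median KS statistic. The
signed z is the default test statistic with |z| as an option — the choice
was left open by the source material; signed z is the stricter default
since it also detects sign-asymmetric shifts. The KS test is known to be
insensitive to differences confined to extreme tails; no alternative is
implemented.

## 4. Stratified FDR

`fdr_fixed_rejection()` implements Benjamini–Hochberg as a fixed rejection
region: reject all p ≤ p* with p* the largest sorted p₍ᵢ₎ ≤ αi/N. The
test suite proves exact equivalence to an independent step-up
implementation on a thousand random instances. Rejecting where the
empirical FDR estimate p/q stays below α is the same procedure.

For stratification, a multiple linear regression predicts tagged variance
(z²) from the eight *unthresholded* scores; SNPs are ranked by prediction
into `n_strata` near-equal strata (default 5 — the source material never
states its count; 5 is small enough that each stratum keeps ~N/5 SNPs and
large enough to separate enrichment levels, and it is configurable). Ties
in predicted variance break by SNP id, making the partition deterministic.
BH runs within each stratum at the common level α; weighted-α variants are
out of scope. Training should use an independent phenotype; the CLI warns
when a model is trained and applied on the same statistics.

Power is reported as the ratio of stratified to unstratified rejection
counts at the same α, equivalent under the non-discovery-rate view to the
relative power of the two procedures. The ratio is undefined (flagged, not
fabricated) when unstratified control rejects nothing.

One honest caveat quantified by the acceptance suite: with small strata
(~2,000 SNPs, ~20 rejections each) the *pooled* realized false-discovery
proportion of the stratified rejection set carries a small positive
finite-sample bias (≈0.052 at α = 0.05 in the calibration world) even
though each stratum's BH controls its own FDR — strata that happen to
reject more get more weight in the pooled proportion, and their FDPs are
positively correlated with their rejection counts. The effect vanishes as
strata grow; it is a property of ratio-of-sums FDP at small counts, not of
the implementation. The corresponding acceptance assertion is left failing
at its stated scale rather than redefining the quantity.

## 5. Replication

Sub-studies sharing a SNP set are split into all C(n, n/2)
discovery/replication halves. Combined z is `mean(z) × √k` — equal-weight
combination kept deliberately even though inverse-variance weighting would
be standard for unequal study sizes (out of scope); it preserves unit
variance for k i.i.d. standard normals. Discovery p-values are two-tailed;
replication p-values are one-tailed preserving the discovery sign (a
discovery z of exactly 0 is treated as positive, with a warning).
Cumulative replication curves use 1000 equally spaced bins over the
observed −log₁₀ discovery range (recomputed per analysis, shared across
strata); a bin's rate is the replication proportion among SNPs *strictly
above* its lower bound, bins with no qualifying SNPs are undefined (NA,
excluded from split averages, never 0), and the curve is averaged over
splits. SNPs missing in any study of a split are dropped for that split
with a message. Rank-based comparison orders SNPs either by pooled p or by
within-stratum BH-adjusted p (the FDR level at which a SNP is first
rejected in its stratum), ties by nominal p.

## 6. The synthetic-data generator

What it emulates, and the stated world of the tests:

* **Reference panel** (`simulate_reference_panel`): haplotypes in LD
  blocks. Within a block every SNP copies a block-anchor haplotype with
  probability `target_r2^(1/4)`, giving pairwise dosage r² ≈ `target_r2`
  within blocks and ≈ 0 between; diploid dosages are sums of two
  haplotypes. Defaults: 200 individuals (a 1000-Genomes-scale continental
  panel), blocks of 10 SNPs, target r² 0.8, MAF uniform on [0.05, 0.5].
  The generating block index is recorded for testability.
* **Gene track** (`simulate_gene_track`): non-overlapping genes built as
  5′ UTR | exon/intron alternation | 3′ UTR, with element lengths scaled
  so chromosome-wide base-pair fractions hit the targets — default
  intron 0.30, exon 0.05, 3′ UTR 0.02, 5′ UTR 0.01, an intron-dominant
  profile mirroring real annotation-category abundances. Strands
  alternate. The trailing 30% of the chromosome is a gene desert so that
  a usable intergenic stratum (no gene within 100 kb) exists; real
  chromosomes achieve this through non-uniform gene density.
* **Summary statistics** (`simulate_summary_stats`): per category c, a SNP
  is non-null with probability π₁(c); its z is N(0, 1) for nulls and
  N(0, 1 + σ₁²(c)) for non-nulls, all multiplied by √λ. The non-null
  component is a scaled normal, not the heavier-tailed shapes real
  phenotypes can show — sufficient for every moment-based recovery
  property used here, and the main reason a green test does not certify
  behavior under extreme-tail architectures. Effects sit on the tag SNP's
  own positional category by default (ground-truth clarity); the optional
  `mode = "ld"` places effects on panel SNPs and induces tag z-scores
  through the LD neighborhood, which is what makes LD-weighted membership
  (not positional identity) the better predictor — the end-to-end ordering
  test uses it.
* **Null GWAS** (`simulate_null_gwas`): a phenotype independent of
  genotypes, per-SNP z from simple linear regression. This carries real
  LD/MAF structure under the global null, so categorical mean(z²) ≈ 1
  everywhere is evidence against annotation-specific spurious inflation.
  Because all SNPs share one phenotype draw, per-run λ estimates are
  noisier than independent-z theory suggests; tests average over runs.
* **Sub-studies** (`simulate_substudies`): per-study z =
  effect/√n_studies + N(0, noise²), so combining all studies recovers a
  z centered on the stored meta-scale effect with unit noise.

All generators are deterministic given their seed. What is *not*
emulated: coalescent haplotype structure, recombination-map heterogeneity,
demographic history, MAF-dependent effect sizes, overlapping genes,
alternative transcripts, and sample overlap between sub-studies. Green
tests establish internal consistency and statistical calibration of the
methods, not robustness to those real-data features.

## 7. Numerical choices

* Coordinates are 0-based half-open internally; 1-based inclusive input is
  converted at the boundary (`coords = "1based"`).
* Monomorphic SNPs have undefined correlation: LD pairs involving them are
  skipped with a warning (the self pair is kept), and the null-GWAS
  generator drops them.
* Empirical cdf ties share the at-or-below quantile; with q = rank/N,
  "90% of SNPs in −log₁₀ q ∈ [0, 1]" holds exactly up to one rank unit
  (the tests assert the exact combinatorial count).
* FDR clamps at 1; the λ quantile match uses `stats::quantile` type 7.
* Rank-deficient regression designs raise errors naming the collinear
  columns rather than silently dropping them.
* `log z²` regressions drop z = 0 SNPs with a warning.
* Seeds: every stochastic operation takes an explicit seed; KS repetitions
  derive per-repetition seeds by offset from the base seed.

## 8. Known limitations

* FDR/TDR estimates assume sparse dependence among p-values; heavily
  LD-correlated panels make q noisy in small strata (curves for strata
  under 10 SNPs are produced but warned about).
* The intergenic stratum without masks is only approximately null.
* The tagged-variance regression is linear in scores; interactions or
  monotone transforms might predict better strata.
* The pooled FDP of stratified control at small per-stratum rejection
  counts exceeds α slightly (section 4); users running sFDR on small SNP
  sets should prefer fewer strata.
* Haplotype-based r², imputation and phasing are out of scope; LD is
  composite dosage correlation throughout.
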