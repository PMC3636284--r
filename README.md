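# stratfdr

Stratified enrichment and false discovery rate analysis for GWAS summary
statistics.

## The problem

In a genome-wide association study (GWAS) every tag SNP is conventionally
treated as exchangeable: one test, one p-value, one genome-wide threshold.
But SNPs tagging regulatory and coding elements of protein-coding genes
(5′ UTRs, exons) carry a visibly higher proportion of true associations
than intronic SNPs, and far more than intergenic SNPs. `stratfdr` is for
statistical geneticists who have only summary statistics (no genotypes for
the study samples) and want to (i) quantify that stratification, (ii) use
the depleted intergenic stratum for cleaner genomic-control correction, and
(iii) convert enrichment into extra discoveries at a fixed false discovery
rate.

## The method

1. **LD-weighted annotation.** Against a reference panel, each tag SNP `t`
   gets a continuous score per genic category `c`:

   `score_c(t) = Σ r²(t, s)` over panel SNPs `s` in category `c`, with
   `r² < 0.2` set to 0, a 1 Mb window, and `r²(t, t) = 1`. A SNP is a
   member of every category with `score ≥ 1.0`. The eight categories are
   10 k/1 k upstream, 5′ UTR, exon, intron, 3′ UTR, 1 k/10 k downstream
   (strand-aware flanks). SNPs with all eight scores zero and no LD partner
   within 100 kb of a gene (nor in noncoding-RNA/TFBS/miRNA masks) are
   *intergenic* — approximately null by construction.

2. **Intergenic inflation control.** `λ_GC = median(z²) / F⁻¹_χ²₁(0.5)`
   estimated on intergenic SNPs only, and all statistics rescaled by
   `z ← z/√λ_GC`; estimating λ on a stratum depleted of signal avoids the
   over-correction that polygenic signal causes in standard genomic
   control.

3. **Stratified Q-Q / TDR.** Per stratum, the empirical quantile
   `q(p) = #{pᵢ ≤ p}/N` gives the conservative estimates
   `FDR(p) = min(1, p/q)` and `TDR = 1 − FDR`; on the −log₁₀ scale the FDR
   is the horizontal shift of the stratified Q-Q curve from `x = y`.
   Enrichment is summarized per stratum as `mean(z²) − 1`, normalized by
   the per-phenotype maximum, and tested by two-sample KS tests under
   repeated random LD pruning.

4. **Stratified FDR (sFDR).** A linear regression predicts tagged variance
   (`z²`) from the eight unthresholded scores; SNPs are ranked into strata
   by prediction, and Benjamini–Hochberg control at level α is applied
   within each stratum. Enriched strata reject deeper into their p-value
   tails, so total rejections grow at the same nominal FDR.

5. **Replication.** Sub-studies are split into all `C(n, n/2)`
   discovery/replication halves (70 for 8 studies), z-scores combined as
   `mean × √k`, discovery p two-tailed, replication p one-tailed preserving
   the discovery direction, and cumulative replication-rate curves traced
   over 1000 bins of −log₁₀ discovery p.

A synthetic-data module (LD-block reference panels, gene tracks with
intron-dominant category proportions and a gene desert, two-component
mixture z-scores with per-category non-null proportions `π₁(c)` and effect
variances `σ₁²(c)`, multiplicative inflation λ, null GWAS runs, and
sub-studies with shared true effects) makes the whole pipeline testable
offline with known ground truth.

## Worked example

```r
library(stratfdr)

panel <- simulate_reference_panel(n_ind = 200, n_snp = 2000,
                                  chr_length = 2e6, seed = 1)
track <- simulate_gene_track(chr_length = 2e6, seed = 2)
cfg   <- scoring_config()   # r2 >= 0.2, 1 Mb, membership at 1.0

nb   <- compute_pairwise_ld(panel, panel$snps$id, cfg)
pcat <- assign_positional_category(panel$snps, track, cfg)
names(pcat) <- panel$snps$id
prof <- ld_weighted_scores(nb, pcat, cfg)
prof <- flag_intergenic(prof, nb, track, masks = list())

spec <- mixture_spec(pi1 = c(utr5 = 0.3, exon = 0.15, intron = 0.03),
                     sigma1sq = c(utr5 = 16, exon = 9, intron = 4),
                     lambda = 1.2)
sim <- simulate_summary_stats(prof, spec, seed = 3)

est <- estimate_lambda_gc(sim$stats, subset = prof$intergenic,
                          subset_label = "intergenic")
est
#> lambda_GC = 1.3723 (quantile 0.50, 486 intergenic SNPs)
corrected <- apply_inflation_control(sim$stats, est)
```

The true λ is 1.2; at ~500 intergenic SNPs the median-based estimate is
noisy (±0.08 or so), and this draw over-corrects slightly — visible below
as mildly negative enrichment in the non-enriched strata.

```r
strata <- annotation_strata(prof, include = c("utr5", "exon", "intron",
                                              "intergenic", "all"))
enrichment_scores(corrected, strata)
#>      stratum    n         raw  normalized
#> 1       utr5   93  0.38928934  1.00000000
#> 2       exon  479  0.12084980  0.31043696
#> 3     intron 1284 -0.02706711 -0.06952953
#> 4 intergenic  486 -0.06368080 -0.16358219
#> 5        all 2000 -0.04617980 -0.11862590
```

`raw` is `mean(z²) − 1`, the variance attributable to non-null SNPs. The
generator placed signal `π₁σ₁²` of 4.8, 1.35 and 0.12 on SNPs positionally
in 5′ UTRs, exons and introns; each LD-weighted stratum dilutes that with
member SNPs whose own positional category differs, but the enrichment
ordering is preserved. The same gradient appears in the conservative TDR
at a fixed p-value cutoff:

```r
curves <- estimate_fdr_tdr(stratified_qq(corrected, strata))
aggregate(tdr ~ stratum, subset(curves, p < 0.01), mean)
#>      stratum   tdr
#> 1        all 0.348
#> 2       exon 0.734
#> 3 intergenic 0.000
#> 4     intron 0.563
#> 5       utr5 0.879
```

A SNP at p < 0.01 in the 5′ UTR stratum is estimated ~88% likely to be a
true association; the same p-value among intergenic SNPs carries no
evidence. Feeding predicted tagged variance into stratified FDR control
turns this into extra discoveries:

```r
model <- fit_tagged_variance_model(corrected, prof, label = "synthetic")
res <- stratified_fdr(corrected, predict_strata(model, prof, 5),
                      alpha = 0.05)
res
#> sFDR at alpha = 0.05: 3 stratified vs 1 unstratified rejections
#>   power ratio 3.00 (+200% rejections)
```

## Command line

```sh
Rscript -e 'stratfdr::stratfdr_cli()' annotate \
  --panel panel.tsv --genes genes.gtf --sumstats stats.tsv --out prof.tsv
Rscript -e 'stratfdr::stratfdr_cli()' correct \
  --sumstats stats.tsv --annotations prof.tsv --subset intergenic --out corrected.tsv
Rscript -e 'stratfdr::stratfdr_cli()' sfdr \
  --sumstats corrected.tsv --annotations prof.tsv --n-strata 5 --alpha 0.05 --out sfdr.tsv
```

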