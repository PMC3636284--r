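#' Simulate an LD-block-structured reference panel
#'
#' Generates haplotypes block-wise: SNPs are partitioned into LD blocks;
#' within a block each SNP copies a block "anchor" haplotype allele with
#' probability `target_r2^(1/4)` and otherwise draws independently at the
#' block allele frequency.  Two SNPs in the same block then have haplotype
#' correlation `sqrt(target_r2)`, so the squared dosage correlation is
#' approximately `target_r2`; SNPs in different blocks are independent.
#' Diploid dosages are formed by summing two haplotypes per individual.
#'
#' @param n_ind Number of diploid individuals.
#' @param n_snp Number of SNPs.
#' @param chr_length Chromosome length in bp (positions are a sorted sample
#'   without replacement).
#' @param block_size Mean LD-block size in SNPs (geometric lengths);
#'   `block_size = 1` gives independent SNPs.
#' @param target_r2 Within-block target r-squared in [0, 1).
#' @param maf_range Allele-frequency range for block frequencies (uniform).
#' @param chrom Chromosome name (default "1").
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [reference_panel()] whose `snps` table carries the generating
#'   LD-block index in a `block` column.
#' @export
simulate_reference_panel <- function(n_ind = 200L, n_snp = 1000L,
                                     chr_length = 1e7,
                                     block_size = 10L, target_r2 = 0.8,
                                     maf_range = c(0.05, 0.5),
                                     chrom = "1", seed = 1L) {
  stopifnot(n_ind > 0, n_snp > 0, chr_length >= n_snp, block_size >= 1)
  if (target_r2 < 0 || target_r2 >= 1) {
    stop("target_r2 must be in [0, 1): perfect LD would make blocks ",
         "monomorphic copies, which defeats per-SNP allele frequencies")
  }
  set.seed(seed)
  pos <- sort(sample.int(chr_length, n_snp))
  # geometric block lengths with the requested mean
  lens <- integer(0)
  while (sum(lens) < n_snp) {
    lens <- c(lens, 1L + stats::rgeom(n_snp, prob = min(1, 1 / block_size)))
  }
  lens <- lens[cumsum(lens) - lens < n_snp]
  lens[length(lens)] <- n_snp - sum(lens[-length(lens)])
  block <- rep(seq_along(lens), times = lens)
  n_hap <- 2L * n_ind
  s <- target_r2^(1 / 4)  # per-SNP anchor-copy probability
  hap <- matrix(0L, nrow = n_snp, ncol = n_hap)
  for (b in seq_along(lens)) {
    rows <- which(block == b)
    f <- stats::runif(1, maf_range[1], maf_range[2])
    anchor <- stats::rbinom(n_hap, 1L, f)
    for (r in rows) {
      copy <- stats::runif(n_hap) < s
      hap[r, ] <- ifelse(copy, anchor, stats::rbinom(n_hap, 1L, f))
    }
  }
  geno <- hap[, seq_len(n_ind) * 2L - 1L, drop = FALSE] +
    hap[, seq_len(n_ind) * 2L, drop = FALSE]
  snps <- data.frame(id = sprintf("snp%0*d", nchar(n_snp), seq_len(n_snp)),
                     chrom = chrom, pos = pos, block = block,
                     stringsAsFactors = FALSE)
  reference_panel(snps, geno)
}

#' Simulate a gene track with target category proportions
#'
#' Lays non-overlapping genes along a chromosome.  Each gene is built as
#' 5' UTR, alternating exons and introns, then 3' UTR, with element lengths
#' scaled so that the base-pair (and hence dense-SNP) fraction of each
#' category matches the requested targets; the remainder of the chromosome
#' is inter-gene space.  Strands alternate deterministically with random
#' jitter on element lengths.
#'
#' A trailing fraction of the chromosome (`desert_fraction`) is kept free
#' of genes: a gene desert whose interior SNPs can satisfy the intergenic
#' definition (no gene within 100 kb).  Category targets are fractions of
#' the whole chromosome, desert included.
#'
#' @param chr_length Chromosome length in bp.
#' @param targets Named fractions of the chromosome to be covered by
#'   `utr5`, `exon`, `intron`, `utr3` (sum < 1; default intron-dominant).
#' @param n_introns Introns per gene (default 5).
#' @param mean_intron_len Mean intron length in bp (default 1500).
#' @param desert_fraction Trailing gene-free fraction of the chromosome
#'   (default 0.3).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A [gene_track()].
#' @export
simulate_gene_track <- function(chr_length = 1e6,
                                targets = c(utr5 = 0.01, exon = 0.05,
                                            intron = 0.30, utr3 = 0.02),
                                n_introns = 5L, mean_intron_len = 1500,
                                desert_fraction = 0.3,
                                chrom = "1", seed = 1L) {
  stopifnot(all(element_categories() %in% names(targets)),
            all(targets >= 0), n_introns >= 1L,
            desert_fraction >= 0, desert_fraction < 1)
  if (sum(targets) >= 1 - desert_fraction) {
    stop("category targets must sum to below the non-desert fraction")
  }
  set.seed(seed)
  # per-gene expected bp per category, derived from the targets so all
  # realized fractions track their targets simultaneously
  intron_bp <- n_introns * mean_intron_len
  per_gene <- c(utr5 = unname(intron_bp * targets["utr5"] / targets["intron"]),
                exon = unname(intron_bp * targets["exon"] / targets["intron"]),
                intron = intron_bp,
                utr3 = unname(intron_bp * targets["utr3"] / targets["intron"]))
  span <- sum(per_gene)
  genic_region <- chr_length * (1 - desert_fraction)
  n_genes <- floor(chr_length * targets[["intron"]] / intron_bp)
  if (n_genes < 1L) {
    stop("infeasible packing: chromosome too short for one gene at the ",
         "requested intron target")
  }
  gap <- (genic_region - n_genes * span) / (n_genes + 1)
  if (gap < 0) stop("infeasible packing: genes exceed the genic region")
  jitter <- function(mu, n) {
    pmax(1L, as.integer(round(mu * stats::runif(n, 0.8, 1.2))))
  }
  t_rows <- vector("list", n_genes)
  e_rows <- vector("list", n_genes)
  cursor <- gap
  for (g in seq_len(n_genes)) {
    n_exons <- n_introns + 1L
    l_u5 <- jitter(per_gene[["utr5"]], 1L)
    l_u3 <- jitter(per_gene[["utr3"]], 1L)
    l_ex <- jitter(per_gene[["exon"]] / n_exons, n_exons)
    l_in <- jitter(mean_intron_len, n_introns)
    strand <- if (g %% 2L == 0L) "-" else "+"
    # coordinate order; 5' UTR sits at the low end on '+', high end on '-'
    cats <- c("utr5", as.vector(rbind(rep("exon", n_introns), rep("intron", n_introns))),
              "exon", "utr3")
    lens <- c(l_u5, as.vector(rbind(l_ex[-n_exons], l_in)), l_ex[n_exons],
              l_u3)
    if (strand == "-") {
      cats <- rev(cats)
      lens <- rev(lens)
    }
    starts <- cursor + c(0, cumsum(lens[-length(lens)]))
    ends <- starts + lens
    tx_id <- sprintf("tx%d", g)
    t_rows[[g]] <- data.frame(gene = sprintf("gene%d", g),
                              transcript = tx_id, chrom = chrom,
                              strand = strand,
                              tx_start = starts[1L],
                              tx_end = ends[length(ends)],
                              stringsAsFactors = FALSE)
    e_rows[[g]] <- data.frame(transcript = tx_id, category = cats,
                              start = starts, end = ends,
                              stringsAsFactors = FALSE)
    cursor <- ends[length(ends)] + gap
    if (cursor > genic_region) break
  }
  gene_track(do.call(rbind, t_rows), do.call(rbind, e_rows))
}

#' Mixture specification for synthetic summary statistics
#'
#' Two-component scaled-normal mixture per category: a SNP in category `c`
#' is non-null with probability `pi1[c]`, in which case its true (meta
#' scale) effect is drawn N(0, `sigma1sq[c]`); its z-score is the effect
#' plus unit normal sampling noise, so non-null z-scores are
#' N(0, 1 + sigma1sq) marginally.  All z-scores are finally multiplied by
#' `sqrt(lambda)` to emulate multiplicative genomic inflation.
#'
#' Categories absent from `pi1` (including `"intergenic"` and `"none"`)
#' default to pure null.
#'
#' @param pi1 Named vector of non-null proportions in [0, 1].
#' @param sigma1sq Named vector of non-null effect variances (>= 0); names
#'   must match `pi1`.
#' @param lambda Multiplicative inflation factor (> 0, default 1).
#' @return A `mixture_spec`.
#' @export
mixture_spec <- function(pi1 = c(utr5 = 0), sigma1sq = c(utr5 = 0),
                         lambda = 1) {
  stopifnot(all(pi1 >= 0), all(pi1 <= 1), all(sigma1sq >= 0), lambda > 0,
            setequal(names(pi1), names(sigma1sq)))
  structure(list(pi1 = pi1, sigma1sq = sigma1sq[names(pi1)],
                 lambda = lambda),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("mixture_spec (lambda = %.3g):\n", x$lambda))
  print(data.frame(category = names(x$pi1), pi1 = unname(x$pi1),
                   sigma1sq = unname(x$sigma1sq)), row.names = FALSE)
  invisible(x)
}

#' Simulate mixture-model summary statistics with known truth
#'
#' Draws z-scores from the per-category two-component mixture of a
#' [mixture_spec()].  The category of each SNP is its own positional
#' category (`"intergenic"` for flagged SNPs, `"none"` when unannotated)
#' when `profiles` is given, or taken directly from `categories`.
#'
#' With `mode = "ld"`, effects are instead placed on reference-panel SNPs
#' (by their positional category) and each tag SNP's z-score mean is the
#' r-squared-weighted sum of tagged effects over its LD neighborhood,
#' exercising the rationale for LD-weighted annotation.
#'
#' @param profiles An `annotation_profiles` (or `NULL` when `categories`
#'   is given).
#' @param spec A [mixture_spec()].
#' @param categories Optional character vector of per-SNP categories (with
#'   optional names as SNP ids), used when `profiles` is `NULL`.
#' @param mode `"tag"` (default) or `"ld"`.
#' @param neighborhoods Required for `mode = "ld"`: `ld_neighborhoods`.
#' @param panel_categories Required for `mode = "ld"`: named category
#'   vector over panel SNP ids.
#' @param seed Integer seed.
#' @return List with `stats` (a [sumstats()]) and `truth` (a
#'   `synthetic_truth` data.frame: id, category, nonnull, effect, plus the
#'   spec as attribute).
#' @export
simulate_summary_stats <- function(profiles = NULL, spec = mixture_spec(),
                                   categories = NULL, mode = c("tag", "ld"),
                                   neighborhoods = NULL,
                                   panel_categories = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "mixture_spec"))
  if (is.null(categories)) {
    stopifnot(inherits(profiles, "annotation_profiles"))
    categories <- ifelse(profiles$intergenic, "intergenic",
                         ifelse(is.na(profiles$positional), "none",
                                profiles$positional))
    ids <- profiles$id
    chrom <- profiles$chrom
    pos <- profiles$pos
  } else {
    ids <- if (!is.null(names(categories))) names(categories) else
      sprintf("snp%0*d", nchar(length(categories)),
              seq_along(categories))
    chrom <- NA_character_
    pos <- NA_integer_
  }
  n <- length(ids)
  pi1 <- function(cat) ifelse(cat %in% names(spec$pi1),
                              spec$pi1[cat], 0)
  s1 <- function(cat) ifelse(cat %in% names(spec$sigma1sq),
                             spec$sigma1sq[cat], 0)
  set.seed(seed)
  if (mode == "tag") {
    nonnull <- stats::runif(n) < pi1(categories)
    effect <- ifelse(nonnull,
                     stats::rnorm(n, 0, sqrt(s1(categories))), 0)
  } else {
    if (is.null(neighborhoods) || is.null(panel_categories)) {
      stop("mode = 'ld' needs `neighborhoods` and `panel_categories`")
    }
    pid <- unique(neighborhoods$id)
    pcat <- ifelse(is.na(panel_categories[pid]), "none",
                   panel_categories[pid])
    p_nonnull <- stats::runif(length(pid)) < pi1(pcat)
    p_eff <- ifelse(p_nonnull, stats::rnorm(length(pid), 0,
                                            sqrt(s1(pcat))), 0)
    names(p_eff) <- pid
    w <- rowsum(neighborhoods$r2 * p_eff[neighborhoods$id],
                factor(neighborhoods$tag, levels = ids))
    effect <- as.numeric(w) / sqrt(pmax(1, as.numeric(
      rowsum(neighborhoods$r2, factor(neighborhoods$tag, levels = ids)))))
    nonnull <- effect != 0
  }
  z <- (effect + stats::rnorm(n)) * sqrt(spec$lambda)
  stats <- sumstats(data.frame(id = ids, chrom = chrom, pos = pos, z = z,
                               stringsAsFactors = FALSE))
  truth <- structure(
    data.frame(id = ids, category = unname(categories),
               nonnull = unname(nonnull), effect = unname(effect),
               stringsAsFactors = FALSE),
    spec = spec, class = c("synthetic_truth", "data.frame"))
  list(stats = stats, truth = truth)
}

#' Simulate a null GWAS on a reference panel
#'
#' Draws a phenotype independent of all genotypes and computes per-SNP
#' association z-scores from simple linear regression of phenotype on
#' dosage.  Because the genotypes carry real LD and MAF structure, this
#' exercises the annotation and enrichment machinery under the global null:
#' any categorical "enrichment" it shows would be a spurious artifact of
#' LD or MAF stratification.
#'
#' @param panel A [reference_panel()] with at least 50 individuals.
#' @param seed Integer seed.
#' @return A [sumstats()] table (monomorphic SNPs are skipped with a
#'   warning).
#' @export
simulate_null_gwas <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (panel$n_ind < 50L) stop("need at least 50 individuals")
  set.seed(seed)
  y <- stats::rnorm(panel$n_ind)
  g <- panel$geno
  sdg <- apply(g, 1L, stats::sd, na.rm = TRUE)
  mono <- is.na(sdg) | sdg == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) skipped in null GWAS")
  }
  keep <- which(!mono)
  r <- suppressWarnings(as.vector(
    stats::cor(t(g[keep, , drop = FALSE]), y,
               use = "pairwise.complete.obs")))
  n_obs <- rowSums(!is.na(g[keep, , drop = FALSE]))
  tval <- r * sqrt((n_obs - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n_obs - 2)
  z <- sign(tval) * stats::qnorm(pmax(p, 1e-300) / 2, lower.tail = FALSE)
  sumstats(data.frame(id = panel$snps$id[keep],
                      chrom = panel$snps$chrom[keep],
                      pos = panel$snps$pos[keep],
                      z = z, stringsAsFactors = FALSE))
}

#' Simulate sub-studies sharing true effects
#'
#' Each sub-study's z-score for a SNP is the SNP's true meta-scale effect
#' scaled by `1/sqrt(n_studies)` plus independent N(0, noise_scale^2)
#' noise, so that [combine_z()] over all studies recovers a z-score
#' centered on the true effect with unit noise variance.
#'
#' @param truth A `synthetic_truth` from [simulate_summary_stats()].
#' @param n_studies Number of sub-studies (>= 2; default 8).
#' @param noise_scale Per-study noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return A `substudy_set`.
#' @export
simulate_substudies <- function(truth, n_studies = 8L, noise_scale = 1,
                                seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_studies >= 2L)
  set.seed(seed)
  n <- nrow(truth)
  labels <- paste0("study", seq_len(n_studies))
  zmat <- matrix(truth$effect / sqrt(n_studies), nrow = n,
                 ncol = n_studies) +
    matrix(stats::rnorm(n * n_studies, 0, noise_scale), nrow = n)
  dimnames(zmat) <- list(truth$id, labels)
  structure(list(z = zmat, ids = truth$id, labels = labels,
                 lambdas = rep(NA_real_, n_studies)),
            class = "substudy_set")
}
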