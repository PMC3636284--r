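#' Reference panel of genotypes
#'
#' Holds bi-allelic SNP dosages over a set of individuals, as used for
#' pairwise LD computation and positional annotation.  Per-SNP minor allele
#' frequency, missingness and a Hardy-Weinberg equilibrium p-value are
#' computed on construction (and recomputed whenever individuals are
#' dropped).
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based SNP
#'   position), one row per SNP; positions must be strictly increasing
#'   within each chromosome.
#' @param geno Numeric matrix of allele dosages (0/1/2, `NA` for missing),
#'   rows = SNPs (in `snps` order), columns = individuals.
#' @return An object of class `reference_panel` with fields `snps`, `geno`,
#'   `maf`, `missingness`, `hwe_p`, `n_ind`.
#' @export
reference_panel <- function(snps, geno) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)),
            is.matrix(geno), nrow(geno) == nrow(snps))
  if (nrow(snps) == 0L) stop("empty panel")
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids in panel")
  snps$id <- as.character(snps$id)
  snps$chrom <- as.character(snps$chrom)
  ok <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(ok)) stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(geno) <- snps$id
  obj <- list(snps = snps, geno = geno, n_ind = ncol(geno))
  obj <- recompute_panel_stats(obj)
  class(obj) <- "reference_panel"
  obj
}

recompute_panel_stats <- function(panel) {
  g <- panel$geno
  n_called <- rowSums(!is.na(g))
  f <- rowSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  panel$maf <- pmin(f, 1 - f)
  panel$missingness <- 1 - n_called / ncol(g)
  n0 <- rowSums(g == 0, na.rm = TRUE)
  n1 <- rowSums(g == 1, na.rm = TRUE)
  n2 <- rowSums(g == 2, na.rm = TRUE)
  panel$hwe_p <- hwe_pvalue(n0, n1, n2)
  panel
}

#' Hardy-Weinberg equilibrium test p-value
#'
#' Pearson chi-square test (1 df) of the observed genotype counts against
#' Hardy-Weinberg proportions at the sample allele frequency.  Monomorphic
#' sites return 1.
#'
#' @param n0,n1,n2 Counts of reference-homozygous, heterozygous and
#'   alternate-homozygous genotypes (vectorized).
#' @return Vector of p-values.
#' @export
hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * pmax(n, 1L))
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chi <- ifelse(p == 0 | p == 1 | n == 0, 0,
                (n0 - e0)^2 / pmax(e0, .Machine$double.eps) +
                  (n1 - e1)^2 / pmax(e1, .Machine$double.eps) +
                  (n2 - e2)^2 / pmax(e2, .Machine$double.eps))
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d SNPs x %d individuals (%d chromosomes)\n",
              nrow(x$snps), x$n_ind, length(unique(x$snps$chrom))))
  cat(sprintf("  MAF range: %.3f-%.3f, max missingness %.3f\n",
              min(x$maf), max(x$maf), max(x$missingness)))
  invisible(x)
}

#' Quality-control a reference panel
#'
#' Removes individuals missing more than `indiv_missing_max` of their
#' genotypes, then (with per-SNP statistics recomputed on the remaining
#' individuals) removes SNPs with minor allele frequency below `maf_min`,
#' missingness above `snp_missing_max`, or Hardy-Weinberg equilibrium
#' p-value below `hwe_p_min`.
#'
#' @param panel A [reference_panel()].
#' @param maf_min Minimum MAF (default 0.01, i.e. MAF < 1\% removed).
#' @param snp_missing_max Maximum per-SNP missingness (default 0.05).
#' @param hwe_p_min Minimum HWE p-value (default 1e-6).
#' @param indiv_missing_max Maximum per-individual missingness (default 0.10).
#' @return The filtered `reference_panel`.
#' @export
qc_reference_panel <- function(panel, maf_min = 0.01,
                               snp_missing_max = 0.05,
                               hwe_p_min = 1e-6,
                               indiv_missing_max = 0.10) {
  stopifnot(inherits(panel, "reference_panel"),
            maf_min >= 0, maf_min <= 1,
            snp_missing_max >= 0, snp_missing_max <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            indiv_missing_max >= 0, indiv_missing_max <= 1)
  ind_miss <- colMeans(is.na(panel$geno))
  keep_ind <- ind_miss <= indiv_missing_max
  if (!any(keep_ind)) {
    stop("individual missingness filter removed all individuals")
  }
  panel$geno <- panel$geno[, keep_ind, drop = FALSE]
  panel$n_ind <- ncol(panel$geno)
  panel <- recompute_panel_stats(panel)

  pass_maf <- panel$maf >= maf_min
  pass_miss <- panel$missingness <= snp_missing_max
  pass_hwe <- panel$hwe_p >= hwe_p_min
  keep <- pass_maf & pass_miss & pass_hwe
  if (!any(keep)) {
    culprit <- if (!any(pass_maf)) "MAF" else if (!any(pass_miss)) {
      "SNP missingness"
    } else if (!any(pass_hwe)) "HWE" else "combined SNP"
    stop(culprit, " filter removed all SNPs from the panel")
  }
  panel$snps <- panel$snps[keep, , drop = FALSE]
  panel$geno <- panel$geno[keep, , drop = FALSE]
  panel$maf <- panel$maf[keep]
  panel$missingness <- panel$missingness[keep]
  panel$hwe_p <- panel$hwe_p[keep]
  panel
}

#' Read a reference panel from a TSV genotype matrix
#'
#' Expects a header line and columns `id`, `chrom`, `pos`, followed by one
#' dosage column per individual (0/1/2, `NA` or `.` for missing).
#'
#' @param path File path.
#' @return A [reference_panel()].
#' @export
read_panel_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", "."))
  stopifnot(all(c("id", "chrom", "pos") %in% names(d)))
  dose_cols <- setdiff(names(d), c("id", "chrom", "pos"))
  geno <- as.matrix(d[dose_cols])
  mode(geno) <- "numeric"
  reference_panel(d[c("id", "chrom", "pos")], geno)
}

#' Write a reference panel as a TSV genotype matrix
#'
#' @param panel A [reference_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  out <- cbind(panel$snps[c("id", "chrom", "pos")],
               as.data.frame(panel$geno))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference panel from VCF
#'
#' Reads bi-allelic SNP genotypes from a (possibly bgzipped) VCF into a
#' [reference_panel()], counting alternate alleles from the GT field.
#' Multi-allelic records are dropped with a message.
#'
#' @param path VCF path.
#' @return A [reference_panel()].
#' @export
read_panel_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  keep <- n_alt == 1L
  if (!all(keep)) {
    message("dropping ", sum(!keep), " multi-allelic records")
    gt <- gt[keep, , drop = FALSE]
    rr <- rr[keep]
  }
  dose <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean == "1/1"] <- 2
  colnames(dose) <- colnames(gt)
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("snp", seq_along(rr))
  snps <- data.frame(id = ids,
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     stringsAsFactors = FALSE)
  reference_panel(snps, dose)
}
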