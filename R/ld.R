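#' Windowed pairwise LD for tag SNPs
#'
#' For each tag SNP, computes r-squared (squared Pearson correlation of
#' allele dosages over individuals with non-missing genotypes at both SNPs)
#' against every panel SNP within `config$window` base pairs on the same
#' chromosome.  Pairs with r-squared below `config$r2_min` are discarded;
#' each tag SNP always carries a self pair with r-squared exactly 1.
#'
#' Tag SNPs absent from the panel are dropped with a message (their count
#' is recorded in the `n_dropped` attribute).  Pairs involving a
#' monomorphic partner have undefined correlation and are skipped with a
#' warning; a monomorphic tag SNP keeps only its self pair.
#'
#' @param panel A [reference_panel()].
#' @param tag_snps Character vector of tag SNP ids.
#' @param config A [scoring_config()].
#' @return An object of class `ld_neighborhoods`: a data.frame of pairs
#'   (`tag`, `id`, `r2`, `chrom`, `pos` of the partner) with attributes
#'   `tags` (data.frame id/chrom/pos of retained tags), `config` and
#'   `n_dropped`.
#' @export
compute_pairwise_ld <- function(panel, tag_snps, config = scoring_config()) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(config, "scoring_config"))
  tag_snps <- as.character(tag_snps)
  present <- tag_snps %in% panel$snps$id
  n_dropped <- sum(!present)
  if (n_dropped > 0L) {
    message(n_dropped, " tag SNP(s) not in the reference panel; dropped")
  }
  tag_snps <- tag_snps[present]
  if (length(tag_snps) == 0L) stop("no tag SNPs remain in the panel")

  snps <- panel$snps
  sdv <- apply(panel$geno, 1L, stats::sd, na.rm = TRUE)
  mono <- is.na(sdv) | sdv == 0
  n_mono_skipped <- 0L
  out <- list()
  k <- 0L
  for (ch in unique(snps$chrom[match(tag_snps, snps$id)])) {
    idx <- which(snps$chrom == ch)
    pos <- snps$pos[idx]
    tag_idx <- idx[snps$id[idx] %in% tag_snps]
    if (length(tag_idx) == 0L) next
    # process tags in position-sorted blocks sharing a candidate window
    tag_idx <- tag_idx[order(snps$pos[tag_idx])]
    blocks <- split(tag_idx, ceiling(seq_along(tag_idx) / 256))
    for (blk in blocks) {
      tpos <- snps$pos[blk]
      lo <- min(tpos) - config$window
      hi <- max(tpos) + config$window
      cand <- idx[pos >= lo & pos <= hi]
      cc <- suppressWarnings(
        stats::cor(t(panel$geno[blk, , drop = FALSE]),
                   t(panel$geno[cand, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r2 <- cc^2
      cpos <- snps$pos[cand]
      for (j in seq_along(blk)) {
        in_win <- abs(cpos - tpos[j]) <= config$window
        v <- r2[j, ]
        skipped <- in_win & (is.na(v) | mono[cand]) & cand != blk[j]
        n_mono_skipped <- n_mono_skipped + sum(skipped)
        take <- in_win & !is.na(v) & v >= config$r2_min &
          !mono[cand] & cand != blk[j]
        pid <- c(snps$id[blk[j]], snps$id[cand[take]])
        k <- k + 1L
        out[[k]] <- data.frame(
          tag = snps$id[blk[j]],
          id = pid,
          r2 = c(1.0, v[take]),
          chrom = ch,
          pos = c(tpos[j], cpos[take]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_mono_skipped > 0L) {
    warning(n_mono_skipped,
            " pair(s) skipped: monomorphic partner, r2 undefined")
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  tags <- snps[match(tag_snps, snps$id), c("id", "chrom", "pos")]
  rownames(tags) <- NULL
  structure(pairs, tags = tags, config = config, n_dropped = n_dropped,
            class = c("ld_neighborhoods", "data.frame"))
}

ld_tags <- function(neighborhoods) attr(neighborhoods, "tags")

#' @export
print.ld_neighborhoods <- function(x, ...) {
  tags <- ld_tags(x)
  cat(sprintf("ld_neighborhoods: %d tag SNPs, %d stored pairs\n",
              nrow(tags), nrow(x)))
  cat(sprintf("  mean partners per tag: %.1f\n", nrow(x) / nrow(tags)))
  invisible(x)
}

#' Random LD pruning
#'
#' Greedy pruning to an approximately independent SNP set: visit the SNPs
#' in a seeded random order and keep each one unless a previously kept SNP
#' is in LD with it at `r2_max` or above.  Deterministic given the seed.
#'
#' @param snp_ids Character vector of SNP ids to prune.
#' @param neighborhoods An `ld_neighborhoods` covering the ids.
#' @param r2_max Pairs at or above this r-squared conflict (default 0.2).
#' @param seed Integer seed.
#' @return Character vector of retained ids (in original `snp_ids` order).
#' @export
ld_prune_random <- function(snp_ids, neighborhoods, r2_max = 0.2, seed = 1L) {
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) == 0L) return(character(0))
  pr <- neighborhoods[neighborhoods$r2 >= r2_max &
                        neighborhoods$tag != neighborhoods$id, ,
                      drop = FALSE]
  keep_pair <- pr$tag %in% snp_ids & pr$id %in% snp_ids
  a <- c(pr$tag[keep_pair], pr$id[keep_pair])
  b <- c(pr$id[keep_pair], pr$tag[keep_pair])
  adj <- split(b, factor(a, levels = snp_ids))
  set.seed(seed)
  ord <- sample(snp_ids)
  kept <- new.env(hash = TRUE, parent = emptyenv())
  retained <- logical(length(ord))
  for (i in seq_along(ord)) {
    s <- ord[i]
    nb <- adj[[s]]
    conflict <- FALSE
    for (v in nb) {
      if (!is.null(kept[[v]])) { conflict <- TRUE; break }
    }
    if (!conflict) {
      kept[[s]] <- TRUE
      retained[i] <- TRUE
    }
  }
  snp_ids[snp_ids %in% ord[retained]]
}
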