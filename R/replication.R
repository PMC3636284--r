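#' Sub-study summary statistics set
#'
#' Aligns per-sub-study summary statistics on their common SNP set (ids
#' missing from any study are dropped with a message) and, optionally,
#' applies intergenic inflation control independently to each study.
#'
#' @param studies List of [sumstats()] tables.
#' @param labels Study labels (default `study1`, ...).
#' @param intergenic_ids Optional character vector of intergenic SNP ids;
#'   when given, each study is inflation-corrected on this subset.
#' @return A `substudy_set`: list with `z` (matrix SNPs x studies), `ids`,
#'   `labels` and `lambdas` (per-study inflation factors, `NA` when no
#'   correction was applied).
#' @export
substudy_set <- function(studies, labels = NULL, intergenic_ids = NULL) {
  stopifnot(is.list(studies), length(studies) >= 2L)
  if (is.null(labels)) labels <- paste0("study", seq_along(studies))
  common <- Reduce(intersect, lapply(studies, `[[`, "id"))
  if (length(common) == 0L) stop("studies share no SNP ids")
  n_drop <- sum(vapply(studies, nrow, 0L)) -
    length(common) * length(studies)
  if (n_drop > 0L) {
    message(n_drop, " study-SNP record(s) outside the common id set; dropped")
  }
  lambdas <- rep(NA_real_, length(studies))
  zmat <- matrix(NA_real_, nrow = length(common), ncol = length(studies),
                 dimnames = list(common, labels))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    if (!is.null(intergenic_ids)) {
      est <- estimate_lambda_gc(st, subset = intergenic_ids,
                                subset_label = "intergenic")
      st <- apply_inflation_control(st, est)
      lambdas[i] <- est$lambda
    }
    zmat[, i] <- st$z[match(common, st$id)]
  }
  structure(list(z = zmat, ids = common, labels = labels,
                 lambdas = lambdas),
            class = "substudy_set")
}

#' @export
print.substudy_set <- function(x, ...) {
  cat(sprintf("substudy_set: %d studies, %d common SNPs\n",
              length(x$labels), length(x$ids)))
  invisible(x)
}

#' Enumerate discovery/replication splits
#'
#' Every subset of `k` studies as discovery with the complementary `k`
#' studies as replication; with `n` studies this yields `choose(n, k)`
#' splits (8 studies in halves give 70).
#'
#' @param studies A `substudy_set` (or an integer study count).
#' @param k Discovery half size; must equal half the (even) study count.
#' @return List of lists with integer indices `discovery` and
#'   `replication`.
#' @export
enumerate_splits <- function(studies, k = NULL) {
  n <- if (inherits(studies, "substudy_set")) length(studies$labels)
       else as.integer(studies)
  if (n %% 2L != 0L) stop("study count must be even to split in halves")
  if (is.null(k)) k <- n %/% 2L
  if (k != n %/% 2L) stop("k must equal half the study count")
  combos <- utils::combn(n, k, simplify = FALSE)
  lapply(combos, function(d) {
    list(discovery = d, replication = setdiff(seq_len(n), d))
  })
}

#' Combine z-scores across studies
#'
#' Equal-weight meta z-score: the mean of the per-study z-scores multiplied
#' by the square root of the number of studies, so that combining k
#' independent N(0,1) draws stays N(0,1).  Rows with any missing study
#' value return `NA` (the caller drops them per split, with a message).
#'
#' @param per_study_z Numeric vector (one SNP) or matrix (SNPs x studies).
#' @return Combined z (scalar or vector).
#' @export
combine_z <- function(per_study_z) {
  if (is.matrix(per_study_z)) {
    k <- ncol(per_study_z)
    return(rowMeans(per_study_z) * sqrt(k))
  }
  mean(per_study_z) * sqrt(length(per_study_z))
}

#' Discovery and replication p-values
#'
#' Discovery z-scores convert to two-tailed p-values; replication z-scores
#' convert to one-tailed p-values preserving the discovery direction of
#' effect: `p_rep = 1 - pnorm(z_rep * sign(z_disc))`.  A discovery z of
#' exactly zero is treated as positive with a warning.
#'
#' @param z_disc,z_rep Numeric vectors of combined discovery and
#'   replication z-scores.
#' @return data.frame with `p_disc` and `p_rep`.
#' @export
discovery_replication_pvalues <- function(z_disc, z_rep) {
  stopifnot(length(z_disc) == length(z_rep))
  sgn <- sign(z_disc)
  if (any(sgn == 0, na.rm = TRUE)) {
    warning(sum(sgn == 0, na.rm = TRUE),
            " discovery z-score(s) are exactly 0; treating sign as +")
    sgn[sgn == 0] <- 1
  }
  data.frame(p_disc = 2 * stats::pnorm(-abs(z_disc)),
             p_rep = 1 - stats::pnorm(z_rep * sgn))
}

#' Cumulative replication-rate curves
#'
#' For every discovery/replication split and every stratum, computes over
#' `n_bins` equally spaced bins spanning the observed -log10 discovery
#' p-value range the proportion of stratum SNPs whose -log10 discovery
#' p-value exceeds the bin's lower bound and whose one-tailed replication
#' p-value is below `rep_alpha`; the curve is averaged across splits.
#' Bins with no qualifying SNPs in a split are undefined (`NA`) and are
#' excluded from the average.  The overall replication rate of a stratum
#' (the curve's vertical intercept) is the replication proportion among all
#' its SNPs, averaged across splits.
#'
#' @param studies A `substudy_set`.
#' @param strata List of [stratum()] objects (need not be disjoint; an
#'   `"all"` stratum is appended when absent).
#' @param n_bins Number of bins (default 1000).
#' @param rep_alpha One-tailed replication significance threshold (default
#'   0.05).
#' @param splits Optional list from [enumerate_splits()] (defaults to all
#'   half splits).
#' @return A `replication_curve`: list with `curve` (data.frame: stratum,
#'   bin_lower, rate), `overall` (data.frame: stratum, rate), `n_bins`,
#'   `rep_alpha`, `n_splits`.
#' @export
cumulative_replication_curve <- function(studies, strata, n_bins = 1000L,
                                         rep_alpha = 0.05, splits = NULL) {
  stopifnot(inherits(studies, "substudy_set"), n_bins >= 1L)
  if (inherits(strata, "stratum")) strata <- list(strata)
  labels <- vapply(strata, `[[`, "", "label")
  if (!"all" %in% labels) {
    strata <- c(strata, list(stratum("all", studies$ids, source = "all")))
    labels <- c(labels, "all")
  }
  if (is.null(splits)) splits <- enumerate_splits(studies)
  # per split: combined z and p-values
  split_p <- lapply(splits, function(sp) {
    zd <- combine_z(studies$z[, sp$discovery, drop = FALSE])
    zr <- combine_z(studies$z[, sp$replication, drop = FALSE])
    ok <- !is.na(zd) & !is.na(zr)
    if (!all(ok)) {
      message(sum(!ok), " SNP(s) with missing study values dropped ",
              "from a split")
    }
    pv <- suppressWarnings(
      discovery_replication_pvalues(zd[ok], zr[ok]))
    pv$id <- studies$ids[ok]
    pv
  })
  rng <- range(unlist(lapply(split_p, function(d) -log10(d$p_disc))))
  bounds <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-(n_bins + 1L)]
  curve_sum <- matrix(0, nrow = length(strata), ncol = n_bins)
  curve_n <- matrix(0L, nrow = length(strata), ncol = n_bins)
  overall_sum <- numeric(length(strata))
  overall_n <- integer(length(strata))
  for (d in split_p) {
    nlp <- -log10(d$p_disc)
    hit <- d$p_rep < rep_alpha
    for (si in seq_along(strata)) {
      sel <- d$id %in% strata[[si]]$ids
      if (!any(sel)) next  # stratum empty in this split
      x <- sort(nlp[sel])
      h <- hit[sel][order(nlp[sel])]
      n_tot <- length(x)
      csum <- c(rev(cumsum(rev(h))), 0)  # successes strictly above rank i-1
      idx <- findInterval(bounds, x)     # SNPs with nlp <= bound
      n_above <- n_tot - idx
      s_above <- csum[idx + 1L]
      def <- n_above > 0L
      curve_sum[si, def] <- curve_sum[si, def] +
        s_above[def] / n_above[def]
      curve_n[si, def] <- curve_n[si, def] + 1L
      overall_sum[si] <- overall_sum[si] + mean(h)
      overall_n[si] <- overall_n[si] + 1L
    }
  }
  rate <- curve_sum / ifelse(curve_n > 0, curve_n, NA)
  curve <- data.frame(
    stratum = rep(labels, each = n_bins),
    bin_lower = rep(bounds, times = length(strata)),
    rate = as.vector(t(rate)),
    stringsAsFactors = FALSE)
  overall <- data.frame(stratum = labels,
                        rate = overall_sum / ifelse(overall_n > 0,
                                                    overall_n, NA),
                        stringsAsFactors = FALSE)
  structure(list(curve = curve, overall = overall, n_bins = n_bins,
                 rep_alpha = rep_alpha, n_splits = length(splits)),
            class = "replication_curve")
}

#' @export
print.replication_curve <- function(x, ...) {
  cat(sprintf("replication_curve: %d splits, %d bins, rep alpha %.3g\n",
              x$n_splits, x$n_bins, x$rep_alpha))
  cat("overall replication rates:\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Replication of top-ranked SNPs: pooled vs stratum-adjusted ranking
#'
#' For each discovery/replication split and each rank cutoff, computes the
#' proportion of the top-ranked discovery SNPs that replicate (one-tailed
#' replication p below `rep_alpha`) under (a) pooled p-value ranking and
#' (b) stratum-adjusted ranking, where SNPs are ordered by the
#' within-stratum FDR level at which they are first rejected
#' (within-stratum Benjamini-Hochberg adjusted p-value), ties broken by
#' nominal p.  Proportions are averaged across splits.
#'
#' @param studies A `substudy_set`.
#' @param strata Disjoint [stratum()] list covering the common SNP set.
#' @param ranks Integer rank cutoffs (default `c(100, 500, 1000)`).
#' @param rep_alpha Replication threshold (default 0.05).
#' @param splits Optional list from [enumerate_splits()].
#' @return data.frame: `rank`, `prop_pooled`, `prop_stratified`.
#' @export
rank_replication_comparison <- function(studies, strata,
                                        ranks = c(100L, 500L, 1000L),
                                        rep_alpha = 0.05, splits = NULL) {
  stopifnot(inherits(studies, "substudy_set"))
  if (inherits(strata, "stratum")) strata <- list(strata)
  if (is.null(splits)) splits <- enumerate_splits(studies)
  n_snp <- length(studies$ids)
  if (any(ranks > n_snp)) {
    warning("rank cutoff(s) above the SNP count truncated to ", n_snp)
    ranks <- pmin(ranks, n_snp)
  }
  strat_of <- rep(NA_integer_, n_snp)
  for (si in seq_along(strata)) {
    strat_of[studies$ids %in% strata[[si]]$ids] <- si
  }
  if (anyNA(strat_of)) stop("strata do not cover the common SNP set")
  acc_pooled <- acc_strat <- matrix(0, nrow = length(splits),
                                    ncol = length(ranks))
  for (si_ in seq_along(splits)) {
    sp <- splits[[si_]]
    zd <- combine_z(studies$z[, sp$discovery, drop = FALSE])
    zr <- combine_z(studies$z[, sp$replication, drop = FALSE])
    pv <- suppressWarnings(discovery_replication_pvalues(zd, zr))
    hit <- pv$p_rep < rep_alpha
    ord_pooled <- order(pv$p_disc)
    qv <- numeric(n_snp)
    for (k in unique(strat_of)) {
      sel <- strat_of == k
      qv[sel] <- bh_adjust(pv$p_disc[sel])
    }
    ord_strat <- order(qv, pv$p_disc)
    for (ri in seq_along(ranks)) {
      r <- ranks[ri]
      acc_pooled[si_, ri] <- mean(hit[ord_pooled[seq_len(r)]])
      acc_strat[si_, ri] <- mean(hit[ord_strat[seq_len(r)]])
    }
  }
  data.frame(rank = ranks,
             prop_pooled = colMeans(acc_pooled),
             prop_stratified = colMeans(acc_strat))
}
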