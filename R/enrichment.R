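#' SNP stratum
#'
#' A labelled set of SNP ids, the unit of all stratified analyses.  Strata
#' can come from annotation category memberships, the intergenic flag, the
#' full SNP set, or arbitrary user definitions (MAF bins, predicted-variance
#' ranks, ...).
#'
#' @param label Stratum label.
#' @param ids Character vector of SNP ids (non-empty).
#' @param source One of `"category"`, `"intergenic"`, `"all"`,
#'   `"user"`.
#' @return An object of class `stratum`.
#' @export
stratum <- function(label, ids, source = "user") {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("stratum '", label, "' is empty")
  structure(list(label = as.character(label), ids = unique(ids),
                 source = source),
            class = "stratum")
}

#' @export
print.stratum <- function(x, ...) {
  cat(sprintf("stratum '%s' (%s): %d SNPs\n", x$label, x$source,
              length(x$ids)))
  invisible(x)
}

#' Build strata from annotation profiles
#'
#' One stratum per category membership (`in_*` columns), plus the
#' intergenic stratum and the all-SNPs stratum.  Empty categories are
#' dropped with a message.
#'
#' @param profiles An `annotation_profiles` data.frame.
#' @param include Which strata to build: subset of
#'   `c(genic_categories(), "intergenic", "all")`.
#' @return Named list of [stratum()] objects.
#' @export
annotation_strata <- function(profiles,
                              include = c(genic_categories(),
                                          "intergenic", "all")) {
  out <- list()
  for (cat in intersect(include, genic_categories())) {
    ids <- profiles$id[profiles[[paste0("in_", cat)]]]
    if (length(ids) == 0L) {
      message("category ", cat, " has no member SNPs; stratum skipped")
      next
    }
    out[[cat]] <- stratum(cat, ids, source = "category")
  }
  if ("intergenic" %in% include) {
    ids <- profiles$id[profiles$intergenic]
    if (length(ids) > 0L) {
      out[["intergenic"]] <- stratum("intergenic", ids,
                                     source = "intergenic")
    } else {
      message("no intergenic SNPs; stratum skipped")
    }
  }
  if ("all" %in% include) {
    out[["all"]] <- stratum("all", profiles$id, source = "all")
  }
  out
}

#' Empirical cumulative distribution of p-values
#'
#' `q(p) = #\{p_i <= p\} / N`, evaluated at the observed p-values
#' themselves; ties share the same value (at-or-below counting).
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Vector `q` aligned with `p_values`.
#' @export
empirical_cdf <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must be in (0, 1]")
  }
  rank(p_values, ties.method = "max") / length(p_values)
}

#' Stratified Q-Q curves
#'
#' For each stratum, pairs each SNP's nominal p-value with the stratum's
#' empirical quantile `q` and the -log10 transforms of both; an `"all"`
#' stratum is appended when absent.  Enrichment appears as `-log10 p`
#' exceeding `-log10 q` (a leftward shift of the curve from the x = y
#' line).  FDR/TDR columns are filled by [estimate_fdr_tdr()].
#'
#' @param stats A [sumstats()] table.
#' @param strata List of [stratum()] objects.
#' @param min_snps Strata smaller than this trigger a warning but are still
#'   produced (default 10).
#' @return A `stratified_curves` data.frame: `stratum`, `id`, `p`, `q`,
#'   `nlog_p`, `nlog_q`, `fdr` (NA), `tdr` (NA), ordered by p within
#'   stratum.
#' @export
stratified_qq <- function(stats, strata, min_snps = 10L) {
  stopifnot(inherits(stats, "sumstats"))
  if (inherits(strata, "stratum")) strata <- list(strata)
  labels <- vapply(strata, `[[`, "", "label")
  if (!"all" %in% labels) {
    strata <- c(strata, list(stratum("all", stats$id, source = "all")))
  }
  out <- vector("list", length(strata))
  for (i in seq_along(strata)) {
    s <- strata[[i]]
    sel <- stats$id %in% s$ids
    if (!any(sel)) stop("stratum '", s$label, "' shares no ids with stats")
    if (sum(sel) < min_snps) {
      warning("stratum '", s$label, "' has fewer than ", min_snps,
              " SNPs; curve is unstable")
    }
    p <- stats$p[sel]
    q <- empirical_cdf(p)
    ord <- order(p)
    out[[i]] <- data.frame(stratum = s$label,
                           id = stats$id[sel][ord],
                           p = p[ord], q = q[ord],
                           nlog_p = -log10(p[ord]),
                           nlog_q = -log10(q[ord]),
                           fdr = NA_real_, tdr = NA_real_,
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out),
            class = c("stratified_curves", "data.frame"))
}

#' Conservative FDR and TDR estimates along Q-Q curves
#'
#' With the null cdf uniform and the null proportion conservatively set to
#' one, the false discovery rate at a nominal p-value is estimated by
#' `FDR(p) = p / q`, clamped to at most 1, and `TDR = 1 - FDR`.  On the
#' log scale the pre-clamp estimate is the horizontal shift of the Q-Q
#' curve: `-log10 FDR = -log10 p - (-log10 q)`.
#'
#' @param curves A `stratified_curves` from [stratified_qq()].
#' @return The same object with `fdr` and `tdr` columns filled.
#' @export
estimate_fdr_tdr <- function(curves) {
  stopifnot(inherits(curves, "stratified_curves"))
  curves$fdr <- pmin(1, curves$p / curves$q)
  curves$tdr <- 1 - curves$fdr
  curves
}

#' @export
print.stratified_curves <- function(x, ...) {
  for (s in unique(x$stratum)) {
    sub <- x[x$stratum == s, ]
    cat(sprintf("%-12s n=%6d  max -log10(p)=%.2f\n", s, nrow(sub),
                max(sub$nlog_p)))
  }
  invisible(x)
}

#' Write stratified curves as TSV
#'
#' @param curves A `stratified_curves`.
#' @param path Output path.
#' @param cap_nlog_p Optional display cap: rows with `nlog_p` above it are
#'   dropped (presentation only; pass 7.3 to keep only sub-genome-wide
#'   significant p-values).
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, cap_nlog_p = NULL) {
  out <- as.data.frame(curves)
  if (!is.null(cap_nlog_p)) out <- out[out$nlog_p <= cap_nlog_p, ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Categorical enrichment scores
#'
#' Enrichment of a stratum is the sample mean of z-squared minus one: a
#' conservative estimate of the variance attributable to non-null SNPs
#' under a standard-normal null.  Scores are normalized by the largest raw
#' score across the supplied strata so the maximal stratum scores exactly
#' 1.
#'
#' @param stats A [sumstats()] table (inflation-corrected).
#' @param strata List of [stratum()] objects.
#' @return data.frame: `stratum`, `n`, `raw` (mean z^2 - 1), `normalized`.
#' @export
enrichment_scores <- function(stats, strata) {
  stopifnot(inherits(stats, "sumstats"))
  if (inherits(strata, "stratum")) strata <- list(strata)
  raw <- vapply(strata, function(s) {
    z <- stats$z[stats$id %in% s$ids]
    if (length(z) == 0L) return(NA_real_)
    mean(z^2) - 1
  }, 0)
  n <- vapply(strata, function(s) sum(stats$id %in% s$ids), 0L)
  mx <- max(raw, na.rm = TRUE)
  norm <- if (is.finite(mx) && mx > 0) raw / mx else {
    warning("maximum raw enrichment is not positive; ",
            "normalized scores undefined")
    rep(NA_real_, length(raw))
  }
  data.frame(stratum = vapply(strata, `[[`, "", "label"),
             n = n, raw = raw, normalized = norm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kolmogorov-Smirnov enrichment test with random LD pruning
#'
#' Compares the distribution of test statistics in a stratum against a
#' reference stratum (typically a genic category vs the intergenic SNPs).
#' Because LD correlates test statistics, both strata are randomly pruned
#' to approximate independence before each comparison; the procedure is
#' repeated (default 10 times) with fresh pruning seeds and the reported
#' p-value is the one belonging to the median KS statistic.
#'
#' @param stats A [sumstats()] table.
#' @param stratum_ A [stratum()] to test.
#' @param reference The reference [stratum()].
#' @param neighborhoods `ld_neighborhoods` covering both strata.
#' @param repetitions Number of prune-and-test repetitions (default 10).
#' @param seed Base seed; repetition r uses `seed + r`.
#' @param r2_max Pruning threshold (default 0.2).
#' @param statistic `"z"` (signed, default) or `"abs_z"`.
#' @return A `ks_enrichment` result: list with `stratum`, `reference`,
#'   `ks_statistic` (median), `p_value`, `repetitions`, `seed`, and the
#'   per-repetition `statistics`.
#' @export
ks_enrichment_test <- function(stats, stratum_, reference, neighborhoods,
                               repetitions = 10L, seed = 1L,
                               r2_max = 0.2,
                               statistic = c("z", "abs_z")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(stats, "sumstats"), repetitions >= 1L)
  vals <- function(ids) {
    z <- stats$z[stats$id %in% ids]
    if (statistic == "abs_z") abs(z) else z
  }
  ks_stat <- numeric(repetitions)
  ks_p <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    s_ids <- ld_prune_random(stratum_$ids, neighborhoods, r2_max,
                             seed = seed + r)
    r_ids <- ld_prune_random(reference$ids, neighborhoods, r2_max,
                             seed = seed + repetitions + r)
    if (length(s_ids) == 0L || length(r_ids) == 0L) {
      stop("stratum empty after LD pruning")
    }
    kt <- suppressWarnings(stats::ks.test(vals(s_ids), vals(r_ids)))
    ks_stat[r] <- unname(kt$statistic)
    ks_p[r] <- kt$p.value
  }
  med_idx <- order(ks_stat)[ceiling(repetitions / 2)]
  structure(list(stratum = stratum_$label, reference = reference$label,
                 ks_statistic = ks_stat[med_idx],
                 p_value = ks_p[med_idx],
                 repetitions = repetitions, seed = seed,
                 statistics = ks_stat),
            class = "ks_enrichment")
}

#' @export
print.ks_enrichment <- function(x, ...) {
  cat(sprintf("KS enrichment: %s vs %s, median D = %.4f, p = %.3g (%d reps)\n",
              x$stratum, x$reference, x$ks_statistic, x$p_value,
              x$repetitions))
  invisible(x)
}

#' Covariate-adjusted enrichment regression
#'
#' Ordinary least squares of z-squared (or log z-squared) on the eight
#' continuous LD-weighted annotation scores plus total LD, tagged-SNP
#' count, and MAF when available.  Used to check that categorical
#' enrichment persists after adjusting for the amount of LD each tag SNP
#' represents.
#'
#' @param stats A [sumstats()] table.
#' @param profiles An `annotation_profiles` aligned by id.
#' @param response `"z2"` or `"log_z2"`.
#' @return data.frame of coefficients with `estimate`, `se`, `t`,
#'   `p_value`.
#' @export
covariate_regression <- function(stats, profiles,
                                 response = c("z2", "log_z2")) {
  response <- match.arg(response)
  stopifnot(inherits(stats, "sumstats"),
            inherits(profiles, "annotation_profiles"))
  m <- match(stats$id, profiles$id)
  if (anyNA(m)) stop("profiles missing for ", sum(is.na(m)), " SNP(s)")
  X <- as.matrix(profiles[m, score_columns()])
  X <- cbind(X, total_ld = profiles$total_ld[m],
             n_tagged = profiles$n_tagged[m])
  if ("maf" %in% names(stats) && !anyNA(stats$maf)) {
    X <- cbind(X, maf = stats$maf)
  }
  y <- if (response == "z2") stats$z^2 else {
    z2 <- stats$z^2
    if (any(z2 == 0)) {
      warning("dropping ", sum(z2 == 0), " SNP(s) with z = 0 from the ",
              "log z^2 regression")
      X <- X[z2 > 0, , drop = FALSE]
      z2 <- z2[z2 > 0]
    }
    log(z2)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qd <- qr(Xd)
  if (qd$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qd$pivot[seq.int(qd$rank + 1L, ncol(Xd))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(Xd, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(Xd)
  sigma2 <- rss / df
  XtXinv <- solve(crossprod(Xd))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  data.frame(term = colnames(Xd), estimate = unname(est), se = se,
             t = tval,
             p_value = 2 * stats::pt(-abs(tval), df = df),
             row.names = NULL, stringsAsFactors = FALSE)
}
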