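#' GWAS summary statistics table
#'
#' Validated per-SNP summary statistics.  Either `z` or `p` (with an
#' optional effect `sign`) must be provided; the other is derived under the
#' two-tailed normal model `p = 2 * pnorm(-|z|)`.  When both are supplied
#' they must agree to within `tol`.
#'
#' @param df data.frame with column `id` plus `z` and/or `p`; optional
#'   `chrom`, `pos`, `sign` (`"+"`, `"-"` or `NA`), `maf`, `n`.
#' @param p_floor p-values below this are clipped, with a message (default
#'   1e-300; avoids infinite z-scores).
#' @param tol Tolerance for p/z consistency (default 1e-6).
#' @return A `sumstats` data.frame with columns `id`, `chrom`, `pos`, `z`,
#'   `p` (plus `maf`/`n` when given).
#' @export
sumstats <- function(df, p_floor = 1e-300, tol = 1e-6) {
  df <- as.data.frame(df)
  if (!"id" %in% names(df)) stop("`df` must have an `id` column")
  if (anyDuplicated(df$id)) stop("duplicate SNP ids in summary statistics")
  df$id <- as.character(df$id)
  has_z <- "z" %in% names(df)
  has_p <- "p" %in% names(df)
  if (!has_z && !has_p) stop("need a `z` or `p` column")
  if (has_p) {
    if (any(df$p <= 0 | df$p > 1, na.rm = TRUE)) {
      stop("p-values must be in (0, 1]; clip zeros at p_floor (",
           format(p_floor), ") before constructing")
    }
    if (any(df$p < p_floor, na.rm = TRUE)) {
      message("clipping ", sum(df$p < p_floor, na.rm = TRUE),
              " p-value(s) at the floor ", format(p_floor))
      df$p <- pmax(df$p, p_floor)
    }
  }
  if (has_z && has_p) {
    pp <- 2 * stats::pnorm(-abs(df$z))
    if (any(abs(pp - df$p) > tol, na.rm = TRUE)) {
      stop("p and |z| inconsistent beyond tolerance ", format(tol))
    }
  } else if (has_p) {
    sgn <- if ("sign" %in% names(df)) df$sign else rep(NA_character_,
                                                       nrow(df))
    df$z <- p_to_z(df$p, sgn)
  } else {
    df$p <- z_to_p(df$z)
  }
  if (!"chrom" %in% names(df)) df$chrom <- NA_character_
  if (!"pos" %in% names(df)) df$pos <- NA_integer_
  keep <- intersect(c("id", "chrom", "pos", "z", "p", "maf", "n"),
                    names(df))
  structure(df[keep], class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: %d SNPs; lambda_GC (median z^2) = %.3f\n",
              nrow(x),
              stats::median(x$z^2) / stats::qchisq(0.5, 1)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Convert p-values to z-scores and back
#'
#' `p_to_z` maps a two-tailed p-value to `|z| = qnorm(1 - p/2)`, signed by
#' the effect sign; an unknown sign yields the magnitude with a message.
#' `z_to_p` is its inverse, `p = 2 * pnorm(-|z|)`.
#'
#' @param p Two-tailed p-values in (0, 1].
#' @param sign Optional vector of `"+"`, `"-"` or `NA`.
#' @return Numeric vector.
#' @export
p_to_z <- function(p, sign = NULL) {
  if (any(p <= 0)) {
    stop("p-value of 0 (or below) cannot be converted; ",
         "clip at a small floor such as 1e-300 first")
  }
  if (any(p > 1)) stop("p-values must be in (0, 1]")
  z <- stats::qnorm(1 - p / 2)
  if (is.null(sign)) return(z)
  sgn <- rep(NA_real_, length(p))
  sgn[sign %in% c("+", "1", "plus")] <- 1
  sgn[sign %in% c("-", "-1", "minus")] <- -1
  if (anyNA(sgn)) {
    message(sum(is.na(sgn)), " z-score(s) have unknown sign; ",
            "magnitudes returned")
    sgn[is.na(sgn)] <- 1
  }
  z * sgn
}

#' @rdname p_to_z
#' @param z z-scores.
#' @export
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Read summary statistics from a delimited file
#'
#' Accepts TSV with a header; recognized columns (case-insensitive):
#' `id`/`snp`/`rsid`, `chrom`/`chr`, `pos`/`bp`, `z`, `p`/`pval`/`pvalue`,
#' `sign`, `maf`, `n`.
#'
#' @param path File path.
#' @param ... Passed to [sumstats()].
#' @return A `sumstats` data.frame.
#' @export
read_sumstats <- function(path, ...) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(d))
  ren <- c(snp = "id", rsid = "id", chr = "chrom", bp = "pos",
           pval = "p", pvalue = "p", p_value = "p")
  nm[nm %in% names(ren)] <- ren[nm[nm %in% names(ren)]]
  names(d) <- nm
  sumstats(d, ...)
}

#' Write summary statistics as TSV
#'
#' @param stats A `sumstats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate the genomic inflation factor
#'
#' `lambda_GC` is the chosen quantile of the squared z-scores divided by
#' the matching quantile of the chi-square distribution with one degree of
#' freedom.  The default quantile is the median; a 0.95 quantile variant is
#' available for phenotypes whose enrichment is confined to the tails.
#' Restricting the estimate to intergenic SNPs ("intergenic inflation
#' control") keeps it from being contaminated by true polygenic signal.
#'
#' @param stats A [sumstats()] table.
#' @param subset Optional logical vector (length `nrow(stats)`) or
#'   character vector of SNP ids selecting the estimation subset.
#' @param quantile Quantile of z-squared used (default 0.5).
#' @param subset_label Label recorded on the estimate (`"intergenic"`,
#'   `"all"`, ...).
#' @param min_snps Warn when the subset is smaller than this (default 100).
#' @return An `inflation_estimate`: list with `lambda`, `quantile`, `n`,
#'   `subset_label`.
#' @export
estimate_lambda_gc <- function(stats, subset = NULL, quantile = 0.5,
                               subset_label = if (is.null(subset)) "all"
                               else "subset",
                               min_snps = 100L) {
  stopifnot(inherits(stats, "sumstats"), quantile > 0, quantile < 1)
  z <- stats$z
  if (!is.null(subset)) {
    z <- if (is.logical(subset)) z[subset] else z[stats$id %in% subset]
  }
  if (length(z) == 0L) stop("empty SNP subset for lambda_GC estimation")
  if (length(z) < min_snps) {
    warning("lambda_GC estimated from only ", length(z), " SNPs")
  }
  lam <- stats::quantile(z^2, quantile, names = FALSE) /
    stats::qchisq(quantile, df = 1)
  structure(list(lambda = lam, quantile = quantile, n = length(z),
                 subset_label = subset_label),
            class = "inflation_estimate")
}

#' @export
print.inflation_estimate <- function(x, ...) {
  cat(sprintf("lambda_GC = %.4f (quantile %.2f, %d %s SNPs)\n",
              x$lambda, x$quantile, x$n, x$subset_label))
  invisible(x)
}

#' Apply genomic inflation control
#'
#' Divides the squared test statistics by `lambda_GC`, i.e. replaces `z`
#' with `z / sqrt(lambda_GC)` (signs preserved) and recomputes two-tailed
#' p-values.  `lambda_GC < 1` is permitted and scales statistics up, which
#' occurs when the input was previously over-corrected by standard genomic
#' control.
#'
#' @param stats A [sumstats()] table.
#' @param est An `inflation_estimate` from [estimate_lambda_gc()] (or a
#'   bare positive number).
#' @return The corrected `sumstats`.
#' @export
apply_inflation_control <- function(stats, est) {
  stopifnot(inherits(stats, "sumstats"))
  lam <- if (inherits(est, "inflation_estimate")) est$lambda else est
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0)
  stats$z <- stats$z / sqrt(lam)
  stats$p <- z_to_p(stats$z)
  stats
}
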