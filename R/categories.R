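#' Genic annotation category labels
#'
#' The eight positional categories used throughout the package, ordered as
#' they appear along a transcript on the plus strand: distal upstream flank
#' (10 kb), proximal upstream flank (1 kb), 5' UTR, exon, intron, 3' UTR,
#' proximal downstream flank (1 kb) and distal downstream flank (10 kb).
#' Flanks are measured along the direction of transcription.
#'
#' @return Character vector of the eight category labels.
#' @export
genic_categories <- function() {
  c("10k_up", "1k_up", "utr5", "exon", "intron", "utr3",
    "1k_down", "10k_down")
}

#' Default precedence order for positional annotation
#'
#' When a position is covered by elements of more than one gene, a single
#' mutually exclusive category is chosen by precedence.  The default favors
#' the rarer, more specific elements: UTRs first, then exon, intron, and
#' finally the flanking windows (proximal before distal).
#'
#' @return Character vector: category labels from highest to lowest priority.
#' @export
default_precedence <- function() {
  c("utr5", "utr3", "exon", "intron", "1k_up", "1k_down",
    "10k_up", "10k_down")
}

# Column names used on annotation profile data frames.
score_columns <- function() paste0("score_", genic_categories())
member_columns <- function() paste0("in_", genic_categories())

# Element-level categories that can appear inside a transcript body.
element_categories <- function() c("utr5", "exon", "intron", "utr3")

#' LD-weighted scoring configuration
#'
#' Bundles the tunable parameters of the LD-weighted annotation scoring:
#' the r-squared threshold below which pairwise LD is zeroed, the window
#' (in base pairs, both directions from the tag SNP) within which LD is
#' computed, the score threshold used to binarize continuous scores into
#' category memberships, and the category precedence order used for
#' positional assignment.
#'
#' The defaults (r2 >= 0.2 within 1 Mb, membership at score >= 1.0) are the
#' primary parameter set; `scoring_config(r2_min = 0.05, window = 2e6)`
#' gives the more inclusive alternate set.
#'
#' @param r2_min Minimum r-squared retained (default 0.2); values below are
#'   treated as 0.  Must be in (0, 1).
#' @param window Window in base pairs around the tag SNP (default 1e6).
#' @param score_threshold Continuous score at or above which a tag SNP is a
#'   member of a category (default 1.0).
#' @param precedence Category precedence order (highest priority first);
#'   must be a permutation of [genic_categories()].
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(r2_min = 0.2, window = 1e6,
                           score_threshold = 1.0,
                           precedence = default_precedence()) {
  stopifnot(is.numeric(r2_min), length(r2_min) == 1L,
            r2_min > 0, r2_min < 1,
            is.numeric(window), length(window) == 1L, window > 0,
            is.numeric(score_threshold), length(score_threshold) == 1L,
            score_threshold > 0)
  if (!setequal(precedence, genic_categories()) ||
      anyDuplicated(precedence)) {
    stop("`precedence` must be a permutation of genic_categories()")
  }
  structure(list(r2_min = r2_min, window = window,
                 score_threshold = score_threshold,
                 precedence = as.character(precedence)),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("LD-weighted scoring configuration\n")
  cat(sprintf("  r2 threshold:    %.3g\n", x$r2_min))
  cat(sprintf("  window:          %s bp\n", format(x$window, big.mark = ",")))
  cat(sprintf("  score threshold: %.3g\n", x$score_threshold))
  cat("  precedence:     ", paste(x$precedence, collapse = " > "), "\n")
  invisible(x)
}
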