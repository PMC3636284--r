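#' Assign mutually exclusive positional categories
#'
#' Assigns each position exactly one of the eight genic categories, or none.
#' Element categories (5' UTR, exon, intron, 3' UTR) come from the gene
#' track; flanking categories are derived from the transcription start/end
#' with upstream/downstream measured along the transcription direction
#' (strand-aware): on the plus strand the 1 kb upstream window covers the
#' 1,000 bases before the transcription start and the 10 kb upstream window
#' the 9,000 bases before that, mirrored on the minus strand.
#'
#' When elements of several transcripts overlap a position, the precedence
#' order in `config` resolves to a single category.  The track is reduced
#' to one transcript per gene with [select_transcripts()] first.
#'
#' @param positions data.frame with columns `chrom` and `pos` (1-based).
#' @param track A [gene_track()].
#' @param config A [scoring_config()] (for the precedence order).
#' @param transcript `"first"` or `"longest"`: which transcript represents
#'   each gene.
#' @return Character vector of category labels, `NA` for unannotated
#'   positions.
#' @export
assign_positional_category <- function(positions, track,
                                       config = scoring_config(),
                                       transcript = "first") {
  stopifnot(inherits(track, "gene_track"),
            all(c("chrom", "pos") %in% names(positions)))
  track <- select_transcripts(track, transcript)
  iv <- category_intervals(track)
  if (nrow(iv) == 0L) return(rep(NA_character_, nrow(positions)))

  q <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos, positions$pos))
  # internal 0-based half-open [start, end) covers 1-based bases start+1..end
  s <- GenomicRanges::GRanges(iv$chrom,
                              IRanges::IRanges(iv$start + 1L, iv$end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  res <- rep(NA_character_, nrow(positions))
  if (length(hits) > 0L) {
    prec <- match(iv$category[S4Vectors::subjectHits(hits)],
                  config$precedence)
    qh <- S4Vectors::queryHits(hits)
    best <- tapply(prec, qh, which.min)
    first_of <- tapply(seq_along(qh), qh, function(i) i)
    for (nm in names(best)) {
      i <- first_of[[nm]][best[[nm]]]
      res[as.integer(nm)] <-
        iv$category[S4Vectors::subjectHits(hits)[i]]
    }
  }
  res
}

# Expand a (single-transcript-per-gene) track into a flat interval table of
# all eight categories, 0-based half-open coordinates.
category_intervals <- function(track) {
  tx <- track$transcripts
  el <- merge(track$elements, tx[c("transcript", "chrom")], by = "transcript")
  rows <- el[c("chrom", "category", "start", "end")]
  flank <- function(chrom, start, end, category) {
    data.frame(chrom = chrom, category = rep(category, length(chrom)),
               start = pmax(start, 0), end = end,
               stringsAsFactors = FALSE)
  }
  plus <- tx$strand == "+"
  f <- rbind(
    flank(tx$chrom[plus], tx$tx_start[plus] - 1000L, tx$tx_start[plus],
          "1k_up"),
    flank(tx$chrom[plus], tx$tx_start[plus] - 10000L,
          tx$tx_start[plus] - 1000L, "10k_up"),
    flank(tx$chrom[plus], tx$tx_end[plus], tx$tx_end[plus] + 1000L,
          "1k_down"),
    flank(tx$chrom[plus], tx$tx_end[plus] + 1000L,
          tx$tx_end[plus] + 10000L, "10k_down"),
    flank(tx$chrom[!plus], tx$tx_end[!plus], tx$tx_end[!plus] + 1000L,
          "1k_up"),
    flank(tx$chrom[!plus], tx$tx_end[!plus] + 1000L,
          tx$tx_end[!plus] + 10000L, "10k_up"),
    flank(tx$chrom[!plus], tx$tx_start[!plus] - 1000L, tx$tx_start[!plus],
          "1k_down"),
    flank(tx$chrom[!plus], tx$tx_start[!plus] - 10000L,
          tx$tx_start[!plus] - 1000L, "10k_down"))
  out <- rbind(rows, f)
  out[out$end > out$start, , drop = FALSE]
}

#' LD-weighted annotation profiles
#'
#' Computes, for each tag SNP, the LD-weighted annotation score of every
#' category: the sum of r-squared between the tag SNP and all reference
#' panel SNPs whose positional category is that category (the self pair
#' contributes r-squared 1 to the tag's own positional category).  A tag
#' SNP is a member of every category whose score reaches
#' `config$score_threshold`; memberships are not mutually exclusive.
#'
#' @param neighborhoods An `ld_neighborhoods` from [compute_pairwise_ld()].
#' @param positional Named character vector mapping every panel SNP id
#'   appearing in the neighborhoods to its positional category (`NA` for
#'   none), as returned by [assign_positional_category()].
#' @param config A [scoring_config()].
#' @return An `annotation_profiles` data.frame: `id`, `chrom`, `pos`,
#'   `positional` (the tag's own category), eight `score_*` columns, eight
#'   logical `in_*` columns, `intergenic` (initialized `FALSE`; see
#'   [flag_intergenic()]), `total_ld` and `n_tagged`.
#' @export
ld_weighted_scores <- function(neighborhoods, positional,
                               config = scoring_config()) {
  stopifnot(inherits(neighborhoods, "ld_neighborhoods"))
  tags <- ld_tags(neighborhoods)
  pairs <- as.data.frame(neighborhoods)
  miss <- setdiff(pairs$id, names(positional))
  if (length(miss) > 0L) {
    stop("positional category lookup missing for ", length(miss),
         " neighborhood member(s)")
  }
  self_ok <- pairs$tag == pairs$id & pairs$r2 == 1
  has_self <- tags$id %in% pairs$tag[self_ok]
  if (!all(has_self)) {
    stop("internal consistency error: neighborhood missing self pair for ",
         sum(!has_self), " tag(s)")
  }
  cats <- genic_categories()
  pcat <- positional[pairs$id]
  known <- !is.na(pcat)
  tag_f <- factor(pairs$tag, levels = tags$id)
  scores <- matrix(0, nrow = nrow(tags), ncol = length(cats),
                   dimnames = list(tags$id, cats))
  if (any(known)) {
    ti <- as.integer(tag_f)[known]
    ci <- match(pcat[known], cats)
    lin <- (ci - 1L) * nrow(tags) + ti  # linear index into the score matrix
    agg <- rowsum(pairs$r2[known], group = lin)
    scores[as.integer(rownames(agg))] <- agg[, 1L]
  }
  total_ld <- as.numeric(rowsum(pairs$r2, tag_f))
  n_tagged <- as.integer(table(tag_f))
  prof <- data.frame(id = tags$id, chrom = tags$chrom, pos = tags$pos,
                     positional = unname(positional[tags$id]),
                     stringsAsFactors = FALSE)
  sc <- as.data.frame(scores)
  names(sc) <- score_columns()
  mb <- as.data.frame(scores >= config$score_threshold)
  names(mb) <- member_columns()
  prof <- cbind(prof, sc, mb)
  prof$intergenic <- FALSE
  prof$total_ld <- total_ld
  prof$n_tagged <- n_tagged
  rownames(prof) <- NULL
  structure(prof, config = config,
            class = c("annotation_profiles", "data.frame"))
}

#' Flag intergenic tag SNPs
#'
#' A tag SNP is intergenic when all eight LD-weighted scores are zero and
#' no SNP in its LD neighborhood (including itself) lies within
#' `gene_margin` base pairs of any protein-coding gene, nor inside any of
#' the provided interval masks (intended for noncoding RNA, transcription
#' factor binding sites and microRNA binding sites).  If `masks` is `NULL`
#' the mask criterion is skipped with a warning.
#'
#' @param profiles An `annotation_profiles` from [ld_weighted_scores()].
#' @param neighborhoods The matching `ld_neighborhoods`.
#' @param track The [gene_track()] of protein-coding genes.
#' @param masks Optional list of data.frames with columns `chrom`, `start`,
#'   `end` (0-based half-open, BED-style).
#' @param gene_margin Distance to a gene within which a neighborhood SNP
#'   disqualifies intergenic status (default 100,000 bp).
#' @return `profiles` with the `intergenic` column filled in.
#' @export
flag_intergenic <- function(profiles, neighborhoods, track, masks = NULL,
                            gene_margin = 1e5) {
  stopifnot(inherits(profiles, "annotation_profiles"),
            inherits(neighborhoods, "ld_neighborhoods"),
            inherits(track, "gene_track"))
  tags <- ld_tags(neighborhoods)
  if (!setequal(profiles$id, tags$id)) {
    stop("profiles and neighborhoods are not aligned by SNP id")
  }
  pairs <- as.data.frame(neighborhoods)
  tx <- track$transcripts
  bad <- rep(FALSE, nrow(pairs))
  if (nrow(tx) > 0L) {
    g <- GenomicRanges::GRanges(
      tx$chrom,
      IRanges::IRanges(pmax(tx$tx_start + 1L - gene_margin, 1L),
                       tx$tx_end + gene_margin))
    q <- GenomicRanges::GRanges(pairs$chrom,
                                IRanges::IRanges(pairs$pos, pairs$pos))
    bad <- IRanges::overlapsAny(q, g, ignore.strand = TRUE)
  }
  if (is.null(masks)) {
    warning("no masks provided; intergenic definition skips the ",
            "noncoding-RNA/TFBS/miRNA mask criterion")
  } else {
    q <- GenomicRanges::GRanges(pairs$chrom,
                                IRanges::IRanges(pairs$pos, pairs$pos))
    for (mk in masks) {
      if (nrow(mk) == 0L) next
      m <- GenomicRanges::GRanges(mk$chrom,
                                  IRanges::IRanges(mk$start + 1L, mk$end))
      bad <- bad | IRanges::overlapsAny(q, m, ignore.strand = TRUE)
    }
  }
  tainted <- unique(pairs$tag[bad])
  zero <- rowSums(as.matrix(profiles[score_columns()])) == 0
  profiles$intergenic <- zero & !(profiles$id %in% tainted)
  profiles
}

#' Read BED3 interval masks
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write annotation profiles as TSV
#'
#' @param profiles An `annotation_profiles`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_profiles <- function(profiles, path) {
  out <- as.data.frame(profiles)
  for (mc in member_columns()) out[[mc]] <- as.integer(out[[mc]])
  out$intergenic <- as.integer(out$intergenic)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read annotation profiles from TSV
#'
#' @param path Path written by [write_annotation_profiles()].
#' @param config The [scoring_config()] the profiles were computed under.
#' @return An `annotation_profiles` data.frame.
#' @export
read_annotation_profiles <- function(path, config = scoring_config()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (mc in member_columns()) d[[mc]] <- as.logical(d[[mc]])
  d$intergenic <- as.logical(d$intergenic)
  d$id <- as.character(d$id)
  structure(d, config = config,
            class = c("annotation_profiles", "data.frame"))
}
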