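#' Gene model track
#'
#' Container for protein-coding gene models used for positional annotation.
#' A track holds one row per transcript (gene id, transcript id, chromosome,
#' strand, transcription start/end) and one row per transcript element
#' (5' UTR, exon, intron or 3' UTR interval).
#'
#' Coordinates are stored internally as 0-based half-open intervals
#' (`start` inclusive, `end` exclusive), the BED convention, which makes
#' interval arithmetic unambiguous.  Inputs may be supplied 1-based
#' inclusive (the GTF convention) via `coords = "1based"`, in which case
#' starts are shifted down by one.
#'
#' @param transcripts data.frame with columns `gene`, `transcript`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `tx_start`, `tx_end`.
#' @param elements data.frame with columns `transcript`, `category` (one of
#'   `"utr5"`, `"exon"`, `"intron"`, `"utr3"`), `start`, `end`.
#' @param coords `"0based"` (default; half-open) or `"1based"` (inclusive).
#' @return An object of class `gene_track`.
#' @export
gene_track <- function(transcripts, elements,
                       coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  need_t <- c("gene", "transcript", "chrom", "strand", "tx_start", "tx_end")
  need_e <- c("transcript", "category", "start", "end")
  if (!all(need_t %in% names(transcripts))) {
    stop("`transcripts` must have columns: ", paste(need_t, collapse = ", "))
  }
  if (!all(need_e %in% names(elements))) {
    stop("`elements` must have columns: ", paste(need_e, collapse = ", "))
  }
  transcripts <- as.data.frame(transcripts)[need_t]
  elements <- as.data.frame(elements)[need_e]
  if (coords == "1based") {
    transcripts$tx_start <- transcripts$tx_start - 1L
    elements$start <- elements$start - 1L
  }
  transcripts$chrom <- as.character(transcripts$chrom)
  transcripts$strand <- as.character(transcripts$strand)
  elements$category <- as.character(elements$category)

  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!all(elements$category %in% element_categories())) {
    stop("element categories must be one of: ",
         paste(element_categories(), collapse = ", "))
  }
  if (any(elements$end <= elements$start)) {
    stop("malformed gene model: element with end <= start")
  }
  if (any(transcripts$tx_end <= transcripts$tx_start)) {
    stop("malformed gene model: transcript with tx_end <= tx_start")
  }
  if (!all(elements$transcript %in% transcripts$transcript)) {
    stop("elements reference unknown transcripts")
  }
  # elements within transcript bounds
  m <- match(elements$transcript, transcripts$transcript)
  if (any(elements$start < transcripts$tx_start[m]) ||
      any(elements$end > transcripts$tx_end[m])) {
    stop("malformed gene model: element outside transcript bounds")
  }
  # exon/intron intervals must not overlap within a transcript
  ei <- elements[elements$category %in% c("exon", "intron"), ]
  for (tx in unique(ei$transcript)) {
    e <- ei[ei$transcript == tx, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("malformed gene model: overlapping exon/intron intervals in ",
           "transcript ", tx)
    }
  }
  structure(list(transcripts = transcripts, elements = elements),
            class = "gene_track")
}

#' @export
print.gene_track <- function(x, ...) {
  cat(sprintf("gene_track: %d transcripts (%d genes), %d elements\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene)),
              nrow(x$elements)))
  tab <- table(x$elements$category)
  cat("  elements:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Reduce a track to one transcript per gene
#'
#' Annotation uses a single transcript per gene.  `"first"` keeps the first
#' transcript in file order for each gene (mirroring "first transcript
#' listed" conventions); `"longest"` keeps the transcript spanning the most
#' base pairs.
#'
#' @param track A [gene_track()].
#' @param method `"first"` or `"longest"`.
#' @return A `gene_track` with one transcript per gene.
#' @export
select_transcripts <- function(track, method = c("first", "longest")) {
  method <- match.arg(method)
  stopifnot(inherits(track, "gene_track"))
  tx <- track$transcripts
  keep <- if (method == "first") {
    tx$transcript[!duplicated(tx$gene)]
  } else {
    len <- tx$tx_end - tx$tx_start
    ord <- order(tx$gene, -len)
    tx$transcript[ord][!duplicated(tx$gene[ord])]
  }
  gene_track(tx[tx$transcript %in% keep, , drop = FALSE],
             track$elements[track$elements$transcript %in% keep, ,
                            drop = FALSE])
}

#' Read gene models from GTF/GFF3 or BED12
#'
#' Builds a [gene_track()] from standard gene-model formats.  For GTF/GFF3,
#' exon features define exons, gaps between exons define introns, and UTRs
#' are taken from explicit UTR features when present or derived from the
#' CDS extent otherwise (exonic sequence outside the CDS span, 5' or 3'
#' according to strand).  For BED12, blocks define exons and the thick
#' interval defines the CDS span.
#'
#' Note exon intervals are kept whole (UTR sub-intervals are not excised);
#' the positional precedence order gives UTR categories priority over exon
#' where they overlap.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"bed"`.
#' @return A `gene_track`.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                     gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed",
                     stop("cannot infer format from extension; pass `format`"))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    return(track_from_bed12(gr))
  }
  gr <- rtracklayer::import(path, format = format)
  track_from_gff(gr)
}

# Build a gene_track from a GRanges as imported from GTF/GFF3.
track_from_gff <- function(gr) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  txid <- as.character(md$transcript_id)
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else txid
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features found")
  ex <- data.frame(
    transcript = txid[is_exon],
    gene = gid[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript = txid[type == "CDS"],
    start = GenomicRanges::start(gr)[type == "CDS"] - 1L,
    end = GenomicRanges::end(gr)[type == "CDS"])
  utr5_types <- c("five_prime_utr", "five_prime_UTR", "5UTR")
  utr3_types <- c("three_prime_utr", "three_prime_UTR", "3UTR")
  utr <- data.frame(
    transcript = txid[type %in% c(utr5_types, utr3_types)],
    category = ifelse(type[type %in% c(utr5_types, utr3_types)] %in%
                        utr5_types, "utr5", "utr3"),
    start = GenomicRanges::start(gr)[type %in% c(utr5_types, utr3_types)] - 1L,
    end = GenomicRanges::end(gr)[type %in% c(utr5_types, utr3_types)])
  assemble_track(ex, cds, utr)
}

# Build a gene_track from a BED12 GRanges (blocks = exons, thick = CDS).
track_from_bed12 <- function(gr) {
  md <- S4Vectors::mcols(gr)
  if (!"blocks" %in% names(md)) stop("BED input lacks 12-column block info")
  n <- length(gr)
  txid <- as.character(md$name)
  if (anyDuplicated(txid)) {
    txid <- make.unique(txid)
  }
  blocks <- md$blocks
  ex_list <- vector("list", n)
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    ex_list[[i]] <- data.frame(
      transcript = txid[i], gene = txid[i],
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      start = GenomicRanges::start(gr)[i] - 1L + IRanges::start(b) - 1L,
      end = GenomicRanges::start(gr)[i] - 1L + IRanges::end(b),
      stringsAsFactors = FALSE)
  }
  ex <- do.call(rbind, ex_list)
  thick <- md$thick
  cds <- data.frame(transcript = txid,
                    start = IRanges::start(thick) - 1L,
                    end = IRanges::end(thick))
  cds <- cds[cds$end > cds$start, , drop = FALSE]
  assemble_track(ex, cds, utr = NULL)
}

# Shared assembly: derive introns from exon gaps and UTRs from CDS extent
# when explicit UTR features were absent.  All coordinates 0-based half-open.
assemble_track <- function(ex, cds, utr) {
  txs <- unique(ex$transcript)
  t_rows <- vector("list", length(txs))
  e_rows <- vector("list", length(txs))
  for (i in seq_along(txs)) {
    tx <- txs[i]
    e <- ex[ex$transcript == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    tx_start <- min(e$start); tx_end <- max(e$end)
    strand <- e$strand[1L]
    rows <- data.frame(transcript = tx, category = "exon",
                       start = e$start, end = e$end,
                       stringsAsFactors = FALSE)
    if (nrow(e) > 1L) {
      rows <- rbind(rows, data.frame(
        transcript = tx, category = "intron",
        start = e$end[-nrow(e)], end = e$start[-1L]))
    }
    has_utr <- !is.null(utr) && any(utr$transcript == tx)
    if (has_utr) {
      u <- utr[utr$transcript == tx, c("transcript", "category",
                                       "start", "end")]
      rows <- rbind(rows, u)
    } else if (any(cds$transcript == tx)) {
      cd <- cds[cds$transcript == tx, , drop = FALSE]
      cs <- min(cd$start); ce <- max(cd$end)
      # exonic sequence outside the CDS span, split 5'/3' by strand
      for (j in seq_len(nrow(e))) {
        if (e$start[j] < cs) {
          lo <- e$start[j]; hi <- min(e$end[j], cs)
          rows <- rbind(rows, data.frame(
            transcript = tx,
            category = if (strand == "+") "utr5" else "utr3",
            start = lo, end = hi))
        }
        if (e$end[j] > ce) {
          lo <- max(e$start[j], ce); hi <- e$end[j]
          rows <- rbind(rows, data.frame(
            transcript = tx,
            category = if (strand == "+") "utr3" else "utr5",
            start = lo, end = hi))
        }
      }
    }
    t_rows[[i]] <- data.frame(gene = e$gene[1L], transcript = tx,
                              chrom = e$chrom[1L], strand = strand,
                              tx_start = tx_start, tx_end = tx_end,
                              stringsAsFactors = FALSE)
    e_rows[[i]] <- rows
  }
  gene_track(do.call(rbind, t_rows), do.call(rbind, e_rows))
}
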