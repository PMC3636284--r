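# Shared fixtures, all built in code.

# Two-gene track on chromosome "1": a plus-strand gene with 1-based
# transcription start 5000 and a minus-strand gene whose biological
# transcription start sits at 1-based position 10000 (tx span 9000..10000).
# Internal coordinates are 0-based half-open.
tiny_track <- function() {
  transcripts <- data.frame(
    gene = c("gA", "gB"), transcript = c("tA", "tB"),
    chrom = "1", strand = c("+", "-"),
    tx_start = c(4999, 8999), tx_end = c(6000, 10000))
  elements <- data.frame(
    transcript = c("tA", "tA", "tA", "tB"),
    category = c("utr5", "exon", "intron", "exon"),
    start = c(4999, 5099, 5299, 8999),
    end = c(5099, 5299, 5999, 10000))
  gene_track(transcripts, elements)
}

# Reference panel from an explicit dosage matrix.
panel_from_matrix <- function(geno, pos = NULL, chrom = "1", ids = NULL) {
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  reference_panel(data.frame(id = ids, chrom = chrom, pos = pos),
                  as.matrix(geno))
}

# Hand-built LD neighborhoods (same shape as compute_pairwise_ld output).
fake_neighborhoods <- function(pairs, tags) {
  structure(as.data.frame(pairs), tags = as.data.frame(tags),
            config = scoring_config(), n_dropped = 0L,
            class = c("ld_neighborhoods", "data.frame"))
}

# Annotation profiles with random continuous scores (no LD backing);
# used where only the score matrix matters (regressions, strata).
fake_profiles <- function(n, seed = 1L) {
  set.seed(seed)
  cats <- genic_categories()
  prof <- data.frame(id = sprintf("s%04d", seq_len(n)), chrom = "1",
                     pos = seq_len(n) * 100L,
                     positional = sample(c(cats, NA), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  for (sc in paste0("score_", cats)) {
    prof[[sc]] <- stats::rexp(n, rate = 2)
  }
  for (cat in cats) {
    prof[[paste0("in_", cat)]] <- prof[[paste0("score_", cat)]] >= 1
  }
  prof$intergenic <- FALSE
  prof$total_ld <- rowSums(as.matrix(prof[paste0("score_", cats)])) +
    stats::runif(n, 0.5, 2)  # untagged LD, keeps the design full rank
  prof$n_tagged <- stats::rpois(n, 10) + 1L
  structure(prof, config = scoring_config(),
            class = c("annotation_profiles", "data.frame"))
}

# sumstats straight from a z vector.
stats_from_z <- function(z, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%06d", seq_along(z))
  sumstats(data.frame(id = ids, z = z))
}

# One annotated synthetic world (panel + track + LD + profiles), cached per
# session because several test files reuse it.
annotated_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_reference_panel(n_ind = 200, n_snp = 2000,
                                        chr_length = 2e6, seed = 42)
      track <- simulate_gene_track(chr_length = 2e6, seed = 43)
      cfg <- scoring_config()
      nb <- suppressMessages(
        compute_pairwise_ld(panel, panel$snps$id, cfg))
      pcat <- assign_positional_category(panel$snps, track, cfg)
      names(pcat) <- panel$snps$id
      prof <- ld_weighted_scores(nb, pcat, cfg)
      prof <- suppressWarnings(
        flag_intergenic(prof, nb, track, masks = NULL))
      cache <<- list(panel = panel, track = track, config = cfg,
                     neighborhoods = nb, positional = pcat,
                     profiles = prof)
    }
    cache
  }
})
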