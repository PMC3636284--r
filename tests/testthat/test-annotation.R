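test_that("panel QC applies the MAF, missingness and HWE filters", {
  n_ind <- 200
  set.seed(5)
  filler <- matrix(rbinom(40 * n_ind, 2, 0.3), nrow = 40)
  rownames(filler) <- paste0("f", 1:40)
  geno <- rbind(
    ok = rbinom(n_ind, 2, 0.3),
    rare = c(1, rep(0, n_ind - 1)),            # MAF 0.0025 < 1%
    holes = c(rep(NA, 12), rbinom(n_ind - 12, 2, 0.3)),  # 6% missing
    hwe = rep(1, n_ind),                       # all het: HWE p << 1e-6
    filler)  # keeps per-individual missingness below the 10% cutoff
  panel <- panel_from_matrix(geno, ids = rownames(geno))
  out <- qc_reference_panel(panel)
  expect_false(any(c("rare", "holes", "hwe") %in% out$snps$id))
  expect_true("ok" %in% out$snps$id)

  # identity case: clean panel passes unchanged
  clean <- panel_from_matrix(rbind(a = rbinom(n_ind, 2, 0.3),
                                   b = rbinom(n_ind, 2, 0.4)),
                             ids = c("a", "b"))
  expect_equal(qc_reference_panel(clean)$snps$id, c("a", "b"))
})

test_that("panel QC drops high-missingness individuals and recomputes stats", {
  set.seed(1)
  geno <- matrix(rbinom(50 * 20, 2, 0.4), nrow = 20)
  geno[, 1] <- NA          # individual 1 missing 100% > 10%
  geno[1, 2] <- NA         # SNP 1 additionally missing in individual 2
  panel <- panel_from_matrix(geno)
  out <- qc_reference_panel(panel)
  expect_equal(out$n_ind, 49)
  # missingness recomputed after individual removal
  expect_equal(out$missingness[["s1"]], 1 / 49)

  all_rare <- panel_from_matrix(matrix(0, nrow = 2, ncol = 50))
  expect_error(qc_reference_panel(all_rare), "MAF")
})

test_that("positional categories are strand-aware and precedence-resolved", {
  tr <- tiny_track()
  cfg <- scoring_config()
  pos <- data.frame(
    chrom = "1",
    pos = c(5150,    # inside tA exon
            4500,    # 500 bp before plus-strand TSS -> 1k_up
            10500,   # 500 bp beyond minus-strand TSS (pos 10000) -> 1k_up
            3500,    # 1.5 kb before TSS -> 10k_up
            5050,    # tA utr5 (overlaps nothing else)
            150000)) # far from everything
  got <- assign_positional_category(pos, tr, cfg)
  expect_equal(got, c("exon", "1k_up", "1k_up", "10k_up", "utr5", NA))

  # overlapping genes: exon of one gene inside intron of another resolves
  # by precedence (exon > intron), and utr5 beats exon
  tx <- data.frame(gene = c("g1", "g2"), transcript = c("t1", "t2"),
                   chrom = "1", strand = "+",
                   tx_start = c(0, 400), tx_end = c(1000, 600))
  el <- data.frame(transcript = c("t1", "t2", "t2"),
                   category = c("intron", "exon", "utr5"),
                   start = c(0, 400, 400), end = c(1000, 600, 450))
  tr2 <- gene_track(tx, el)
  got2 <- assign_positional_category(
    data.frame(chrom = "1", pos = c(500, 425)), tr2, cfg)
  expect_equal(got2, c("exon", "utr5"))
})

test_that("pairwise LD respects threshold, window and self pair", {
  set.seed(7)
  base <- rbinom(120, 2, 0.4)
  geno <- rbind(a = base,
                b = base,                       # identical: r2 = 1
                c = rbinom(120, 2, 0.4),        # independent
                d = base)                       # identical but 1.2 Mb away
  panel <- panel_from_matrix(geno, pos = c(1e5, 1.1e5, 1.2e5, 1.4e6),
                             ids = rownames(geno))
  nb <- compute_pairwise_ld(panel, c("a", "b"), scoring_config())
  pairs_a <- nb[nb$tag == "a", ]
  expect_true(all(c("a", "b") %in% pairs_a$id))
  expect_equal(pairs_a$r2[pairs_a$id == "a"], 1.0)
  expect_equal(pairs_a$r2[pairs_a$id == "b"], 1.0)
  expect_false("c" %in% pairs_a$id)  # sample r2 far below 0.2
  expect_false("d" %in% pairs_a$id)  # r2 = 1 but outside the 1 Mb window
  # window relaxed: d appears
  nb2 <- compute_pairwise_ld(panel, "a", scoring_config(window = 2e6))
  expect_true("d" %in% nb2$id)
})

test_that("absent tags are dropped and monomorphic partners skipped", {
  geno <- rbind(a = rbinom(100, 2, 0.4), mono = rep(0, 100))
  panel <- panel_from_matrix(geno, ids = rownames(geno))
  expect_message(
    expect_warning(nb <- compute_pairwise_ld(panel, c("a", "zzz"),
                                             scoring_config()),
                   "monomorphic"),
    "dropped")
  expect_equal(attr(nb, "n_dropped"), 1L)
  expect_equal(nb$id, "a")  # only the self pair survives
  expect_error(compute_pairwise_ld(panel, "zzz", scoring_config()),
               "no tag SNPs")
})

test_that("LD-weighted scores sum r2 by category and binarize at 1.0", {
  tags <- data.frame(id = "t1", chrom = "1", pos = 1000)
  pairs <- data.frame(tag = "t1", id = c("t1", "n1", "n2", "n3"),
                      r2 = c(1.0, 0.5, 0.6, 0.25),
                      chrom = "1", pos = c(1000, 2000, 3000, 4000))
  nb <- fake_neighborhoods(pairs, tags)
  pcat <- c(t1 = "exon", n1 = "intron", n2 = "intron", n3 = "exon")
  prof <- ld_weighted_scores(nb, pcat, scoring_config())
  expect_equal(prof$score_exon, 1.25)
  expect_equal(prof$score_intron, 1.10)
  expect_true(prof$in_exon && prof$in_intron)
  expect_false(any(as.logical(
    prof[paste0("in_", setdiff(genic_categories(), c("exon", "intron")))])))
  expect_equal(prof$total_ld, 2.35)
  expect_equal(prof$n_tagged, 4L)

  # no neighbors: only the self term in its own category
  solo <- ld_weighted_scores(
    fake_neighborhoods(pairs[1, ], tags), pcat, scoring_config())
  expect_equal(solo$score_exon, 1.0)
  expect_true(solo$in_exon)
  expect_equal(sum(as.matrix(solo[score_cols <- paste0(
    "score_", genic_categories())])), 1.0)

  # sub-threshold score: member of nothing
  sub <- ld_weighted_scores(
    fake_neighborhoods(
      data.frame(tag = "t1", id = c("t1", "n1"), r2 = c(1.0, 0.9),
                 chrom = "1", pos = c(1000, 2000)),
      tags),
    c(t1 = NA, n1 = "intron"), scoring_config())
  expect_equal(sub$score_intron, 0.9)
  expect_false(any(as.logical(sub[paste0("in_", genic_categories())])))

  # missing self pair is an internal-consistency error
  noself <- fake_neighborhoods(pairs[-1, ], tags)
  expect_error(ld_weighted_scores(noself, pcat, scoring_config()),
               "self pair")
  expect_error(ld_weighted_scores(nb, pcat[-2], scoring_config()),
               "missing")
})

test_that("intergenic requires zero scores and no LD partner near genes", {
  tr <- tiny_track()  # genes at ~5-10 kb on chromosome 1
  tags <- data.frame(id = c("far", "near", "genic"), chrom = "1",
                     pos = c(9e5, 9e5, 5150))
  pairs <- data.frame(
    tag = c("far", "near", "near", "genic"),
    id = c("far", "near", "buddy", "genic"),
    r2 = c(1, 1, 0.5, 1),
    chrom = "1",
    pos = c(9e5, 9e5, 56000, 5150))  # buddy is 50 kb from gene gA
  nb <- fake_neighborhoods(pairs, tags)
  pcat <- c(far = NA, near = NA, buddy = NA, genic = "exon")
  prof <- ld_weighted_scores(nb, pcat, scoring_config())
  expect_warning(out <- flag_intergenic(prof, nb, tr, masks = NULL),
                 "mask")
  expect_true(out$intergenic[out$id == "far"])
  expect_false(out$intergenic[out$id == "near"])   # partner 50 kb from gene
  expect_false(out$intergenic[out$id == "genic"])  # exon member

  # a mask over the far SNP disqualifies it, and no warning is raised
  mask <- data.frame(chrom = "1", start = 899000, end = 901000)
  out2 <- flag_intergenic(prof, nb, tr, masks = list(mask))
  expect_false(out2$intergenic[out2$id == "far"])
})

test_that("scores match a brute-force pairwise oracle on a small panel", {
  set.seed(11)
  n_snp <- 40
  geno <- matrix(rbinom(n_snp * 150, 2, runif(n_snp, 0.1, 0.5)),
                 nrow = n_snp)
  pos <- sort(sample.int(3e6, n_snp))
  panel <- panel_from_matrix(geno, pos = pos)
  cfg <- scoring_config(r2_min = 0.2, window = 1e6)
  cats <- genic_categories()
  pcat <- setNames(sample(c(cats, NA), n_snp, replace = TRUE),
                   panel$snps$id)

  nb <- compute_pairwise_ld(panel, panel$snps$id, cfg)
  prof <- ld_weighted_scores(nb, pcat, cfg)

  # oracle: double loop over all pairs applying window/threshold rules
  oracle <- matrix(0, n_snp, length(cats), dimnames = list(panel$snps$id,
                                                           cats))
  for (i in seq_len(n_snp)) {
    for (j in seq_len(n_snp)) {
      r2 <- if (i == j) 1.0 else
        suppressWarnings(cor(geno[i, ], geno[j, ]))^2
      if (is.na(r2) || r2 < cfg$r2_min) next
      if (abs(pos[i] - pos[j]) > cfg$window) next
      cj <- pcat[[j]]
      if (!is.na(cj)) oracle[i, cj] <- oracle[i, cj] + r2
    }
  }
  got <- as.matrix(prof[paste0("score_", cats)])
  dimnames(got) <- dimnames(oracle)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("score invariants: self-membership, exclusivity, monotonicity", {
  w <- annotated_world()
  prof <- w$profiles
  # genic tag SNP is always a member of its own positional category
  genic <- !is.na(prof$positional)
  own <- mapply(function(i, cat) prof[[paste0("in_", cat)]][i],
                which(genic), prof$positional[genic])
  expect_true(all(own))
  # intergenic excludes every membership
  any_member <- rowSums(as.matrix(prof[paste0("in_", genic_categories())]))
  expect_true(all(any_member[prof$intergenic] == 0))

  # raising the r2 threshold never increases any score; the permissive
  # alternate configuration (r2 > 0.05, 2 Mb) never decreases any score
  strict <- scoring_config(r2_min = 0.5)
  loose <- scoring_config(r2_min = 0.05, window = 2e6)
  sub <- w$panel$snps$id[seq(1, 2000, by = 20)]
  base_nb <- suppressMessages(compute_pairwise_ld(w$panel, sub, w$config))
  s_base <- as.matrix(ld_weighted_scores(base_nb, w$positional,
                                         w$config)[paste0("score_",
                                                          genic_categories())])
  s_strict <- as.matrix(ld_weighted_scores(
    suppressMessages(compute_pairwise_ld(w$panel, sub, strict)),
    w$positional, strict)[paste0("score_", genic_categories())])
  s_loose <- as.matrix(ld_weighted_scores(
    suppressMessages(compute_pairwise_ld(w$panel, sub, loose)),
    w$positional, loose)[paste0("score_", genic_categories())])
  expect_true(all(s_strict <= s_base + 1e-12))
  expect_true(all(s_loose >= s_base - 1e-12))
})
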