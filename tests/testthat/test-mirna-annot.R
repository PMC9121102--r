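# Construct a window + alignments fixture around a synthetic hairpin so
# the criteria checklist can be exercised without the full pipeline.
hairpin_fixture <- function(seed = 481, n_mismatch = 0L, star_count = 4L,
                            junk_count = 0L, gc_arms = FALSE) {
  set.seed(seed)
  hp <- mircascade:::.make_hairpin(21L, arm5_mature = TRUE,
                                   n_mismatch = n_mismatch,
                                   gc_arms = gc_arms)
  flank5 <- paste0(random_dna(240), strrep("A", 10))
  flank3 <- paste0(strrep("A", 10), random_dna(240))
  wseq <- paste0(flank5, hp$precursor, flank3)
  win <- data.frame(chrom = "chr1", strand = "+", win_start = 0L,
                    win_end = nchar(wseq), stack_start = 250L,
                    stack_end = 271L, stack_count = 60,
                    seq = wseq, stringsAsFactors = FALSE)
  ms <- 250L + hp$off_mature
  ss <- 250L + hp$off_star
  aln <- data.frame(
    seq = c(hp$mature, hp$star),
    chrom = "chr1", start = c(ms, ss),
    end = c(ms + nchar(hp$mature), ss + hp$star_len),
    strand = "+", mismatches = 0L,
    lib1 = c(40L, star_count), stringsAsFactors = FALSE)
  if (junk_count > 0L) {
    for (off in c(4L, 7L, 10L)) {
      aln <- rbind(aln, data.frame(
        seq = substring(wseq, ms + off + 1L, ms + off + 21L),
        chrom = "chr1", start = ms + off, end = ms + off + 21L,
        strand = "+", mismatches = 0L, lib1 = junk_count))
    }
  }
  list(win = win, aln = aln, hp = hp, ms = ms, ss = ss)
}

test_that("a clean hairpin with star evidence passes every criterion", {
  fx <- hairpin_fixture(n_mismatch = 2L)
  res <- evaluate_criteria(fx$win, fx$aln)
  expect_true(res$pass)
  expect_identical(res$report$duplex_mismatches, 2L)
  expect_lte(res$report$max_asym_bulge, 3L)
  expect_gte(res$report$precision, 0.75)
  expect_identical(res$locus$mature_seq, fx$hp$mature)
  # the structure-implied star matches the planted star coordinates
  expect_lte(abs(res$locus$star_start - fx$ss), 1L)
  expect_lte(abs(res$locus$star_end - (fx$ss + fx$hp$star_len)), 1L)
})

test_that("violated criteria fail with the right first failure", {
  # six facing mismatches exceed the 5-mismatch allowance
  fx6 <- hairpin_fixture(seed = 482, n_mismatch = 6L, gc_arms = TRUE)
  res6 <- evaluate_criteria(fx6$win, fx6$aln)
  expect_false(res6$pass)
  expect_identical(res6$first_fail, "duplex_mismatches")
  expect_gte(res6$report$duplex_mismatches, 6L)

  # no star-mapped reads
  fx0 <- hairpin_fixture(seed = 483, star_count = 0L)
  fx0$aln <- fx0$aln[fx0$aln$lib1 > 0, ]
  res0 <- evaluate_criteria(fx0$win, fx0$aln)
  expect_false(res0$pass)
  expect_identical(res0$first_fail, "star_reads")

  # abundant off-duplex reads destroy the precision
  fxj <- hairpin_fixture(seed = 484, junk_count = 35L)
  resj <- evaluate_criteria(fxj$win, fxj$aln)
  expect_false(resj$pass)
  expect_identical(resj$first_fail, "precision")
  expect_lt(resj$report$precision, 0.75)
})

test_that("candidate windows cover planted stacks and clip at edges", {
  fx <- hairpin_fixture()
  genome <- setNames(fx$win$seq, "chr1")
  wins <- extract_candidate_precursors(fx$aln, genome,
                                       annot_config(min_stack_count = 5L))
  expect_gte(nrow(wins), 1L)
  expect_true(all(wins$win_start >= 0 & wins$win_end <= nchar(genome)))
  covering <- wins$stack_start <= fx$ms & wins$stack_end >= fx$ms
  expect_true(any(covering))
  # stacks below the count threshold produce no window
  wins2 <- extract_candidate_precursors(
    fx$aln, genome, annot_config(min_stack_count = 1000L))
  expect_identical(nrow(wins2), 0L)
})

test_that("conservation classes follow catalogue lineages", {
  cat_df <- data.frame(
    name = c("ath-miR156a", "osa-miR156a", "osa-miR9999", "zma-miR9999"),
    seq = c("TGACAGAAGAGAGTGAGCACA", "TGACAGAAGAGAGTGAGCACT",
            "GGGTCGATGCTAGCTAGCTAA", "GGGTCGATGCTAGCTAGCTAC"),
    species = c("ath", "osa", "osa", "zma"),
    lineage = c("non-Poaceae", "Poaceae", "Poaceae", "Poaceae"),
    family = c("miR156", "miR156", "miR9999", "miR9999"),
    stringsAsFactors = FALSE)
  q <- c("TGACAGAAGAGAGTGAGCACA",      # identical to the ath entry
         "GGGTCGATGCTAGCTAGCTAA",      # Poaceae entries only
         "AAAAACCCCCGGGGGTTTTTA")      # no hit
  cls <- classify_conservation(q, cat_df)
  expect_identical(cls$class, c("conserved", "poaceae_specific",
                                "species_specific"))
  expect_identical(cls$best_family[1], "miR156")
  # three mismatches exceed the allowance
  q3 <- "TGACAGAAGAGAGTGAGATGT"
  expect_identical(classify_conservation(q3, cat_df)$class,
                   "species_specific")
  cat_na <- cat_df
  cat_na$lineage[2] <- NA
  expect_error(classify_conservation(q, cat_na), "lineage")
})

test_that("novel families equal brute-force transitive closure", {
  set.seed(485)
  base <- replicate(8, random_dna(21))
  seqs <- character(0)
  for (b in base) {
    seqs <- c(seqs, b)
    if (runif(1) < 0.5) {
      v <- b
      p <- sample(5:17, 1)
      substr(v, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substring(v, p, p))[1]
      seqs <- c(seqs, v)
    }
  }
  loci <- data.frame(mature_seq = seqs, chrom = "chr1",
                     pre_start = seq_along(seqs) * 1000L,
                     stringsAsFactors = FALSE)
  out <- assign_family(loci, catalogue = NULL)
  # oracle: transitive closure over the <=2-mismatch relation
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- !is.na(mircascade:::.mature_match(seqs[i], seqs[j]))
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # same partition (family labels may differ)
  expect_identical(
    as.integer(factor(out$family, levels = unique(out$family))),
    as.integer(factor(comp, levels = unique(comp))))
})

test_that("clusters chain loci under the strict 10-kb rule", {
  loci <- data.frame(
    locus_id = paste0("x", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pre_start = c(1000L, 9000L, 25000L, 0L, 10000L),
    stringsAsFactors = FALSE)
  cl <- detect_clusters(loci)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$members, "x1,x2")        # 25,000 is > 10 kb away
  # chr2 pair at exactly 10 kb is not a cluster (strict <)
  expect_false(any(grepl("x4", cl$members)))
  # order invariance
  cl2 <- detect_clusters(loci[sample(5), ])
  expect_identical(cl[, -1], cl2[, -1])
})

test_that("synteny anchoring equals brute-force interval intersection", {
  loci <- data.frame(
    locus_id = c("a", "b", "c"), family = c("miR1", "miR1", "miR2"),
    chrom = c("chr1", "chr2", "chr1"),
    pre_start = c(100L, 5000L, 90000L), pre_end = c(200L, 5100L, 90100L),
    stringsAsFactors = FALSE)
  blocks <- data.frame(
    block_id = c("B1", "B2"),
    a_chrom = c("chr1", "chr1"), a_start = c(50L, 200L),
    a_end = c(5000L, 300L),
    b_chrom = c("chr2", "chr2"), b_start = c(4000L, 1L),
    b_end = c(9000L, 10L), stringsAsFactors = FALSE)
  anch <- anchor_synteny(loci, blocks)
  # same-family loci on the two sides of B1 -> syntenic pair
  pair_rows <- anch[anch$block_id == "B1", ]
  expect_true(all(pair_rows$syntenic_pair))
  expect_identical(sort(pair_rows$locus_id), c("a", "b"))
  expect_identical(anch$partner_locus_id[anch$locus_id == "a"], "b")
  # locus c overlaps nothing
  expect_false("c" %in% anch$locus_id)
  # brute-force overlap on random intervals
  set.seed(486)
  for (rep in 1:20) {
    l <- data.frame(locus_id = "L", family = "f", chrom = "chr1",
                    pre_start = sample(1000L, 1),
                    stringsAsFactors = FALSE)
    l$pre_end <- l$pre_start + sample(50L, 1)
    b <- data.frame(block_id = "B", a_chrom = "chr1",
                    a_start = sample(1000L, 1), b_chrom = "chr9",
                    b_start = 1L, b_end = 2L, stringsAsFactors = FALSE)
    b$a_end <- b$a_start + sample(200L, 1)
    got <- nrow(anchor_synteny(l, b)) > 0
    want <- l$pre_start < b$a_end && l$pre_end > b$a_start
    expect_identical(got, want)
  }
  expect_error(anchor_synteny(loci, blocks[, -2]), "malformed block")
})
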