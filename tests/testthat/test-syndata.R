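test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(n_true_loci = 0))
  expect_error(sim_config(repression_strength = 1.5))
  expect_error(sim_config(promoter_plant_rate = -0.1))
  expect_error(sim_config(tissues = c("A", "B")))
  # chromosome too short to host the requested entities
  short_cfg <- small_sim_config()
  short_cfg$chrom_len <- 5000L
  expect_error(make_genome(short_cfg), "too short")
})

test_that("truth tables have the planted counts and coordinates", {
  sim <- small_sim()
  cfg <- sim$config
  loci <- sim$truth$loci
  expect_identical(nrow(loci), cfg$n_true_loci + cfg$n_decoy_loci)
  expect_identical(sum(loci$is_decoy), cfg$n_decoy_loci)
  expect_true(all(nzchar(loci$violation[loci$is_decoy])))
  # planted coordinates live inside the genome and the precursor
  for (i in seq_len(nrow(loci))) {
    expect_lte(loci$pre_end[i], nchar(sim$genome[[loci$chrom[i]]]))
    expect_gte(loci$mature_start[i], loci$pre_start[i])
    expect_lte(loci$mature_end[i], loci$pre_end[i])
    expect_gte(loci$star_start[i], loci$pre_start[i])
    expect_lte(loci$star_end[i], loci$pre_end[i])
  }
  # genome sequence at the mature interval matches the truth sequence
  for (i in seq_len(nrow(loci))) {
    s <- substring(sim$genome[[loci$chrom[i]]], loci$mature_start[i] + 1,
                   loci$mature_end[i])
    if (loci$strand[i] == "-") s <- revcomp(s)
    expect_identical(s, loci$mature_seq[i])
  }
  # target sites are perfect complements planted inside transcripts
  ts <- sim$truth$target_sites
  for (p in seq_len(nrow(ts))) {
    site <- substring(sim$transcripts[[ts$transcript_id[p]]],
                      ts$site_start[p] + 1, ts$site_end[p])
    mat <- loci$mature_seq[loci$locus_id == ts$mirna[p]]
    expect_identical(site, revcomp(mat))
  }
  # TF sites: the promoter sequence carries the consensus at the offset
  tf <- sim$truth$tf_sites
  owners <- rbind(
    data.frame(id = loci$locus_id[!loci$is_decoy],
               chrom = loci$chrom[!loci$is_decoy],
               start = loci$pre_start[!loci$is_decoy],
               end = loci$pre_end[!loci$is_decoy],
               strand = loci$strand[!loci$is_decoy]),
    data.frame(id = sim$features$id[sim$features$type == "mRNA"],
               chrom = sim$features$chrom[sim$features$type == "mRNA"],
               start = sim$features$start[sim$features$type == "mRNA"],
               end = sim$features$end[sim$features$type == "mRNA"],
               strand = sim$features$strand[sim$features$type == "mRNA"]))
  prom <- extract_promoters(owners, sim$genome)
  for (p in seq_len(nrow(tf))) {
    pr <- prom$seq[prom$id == tf$owner_id[p]]
    cons <- sim$pwms[[tf$motif_id[p]]]$consensus
    word <- substring(pr, tf$offset[p] + 1,
                      tf$offset[p] + nchar(cons))
    expect_identical(word,
                     if (tf$strand[p] == "+") cons else revcomp(cons))
  }
})

test_that("every decoy fails exactly its labelled criterion", {
  sim <- small_sim()
  loci <- sim$truth$loci
  reads <- simulate_srna_reads(sim)
  clean <- lapply(reads, clean_reads)
  pred <- lapply(clean, select_prediction_set)
  collapsed <- filter_ncrna(collapse_unique(pred), sim$ncrna)
  aln <- map_reads(collapsed, sim$genome)
  wins <- extract_candidate_precursors(aln, sim$genome)
  for (i in which(loci$is_decoy)) {
    wi <- which(wins$chrom == loci$chrom[i] &
                  wins$strand == loci$strand[i] &
                  wins$stack_start < loci$pre_end[i] + 5 &
                  wins$stack_end > loci$pre_start[i] - 5)
    for (w in wi) {
      res <- evaluate_criteria(wins[w, ], aln)
      expect_false(res$pass)
      expect_identical(res$first_fail, loci$violation[i],
                       info = loci$locus_id[i])
    }
  }
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  cfg <- small_sim_config(seed = 77L)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
  # a different seed changes the data
  d3 <- tempfile("gen3")
  simulate_dataset(small_sim_config(seed = 78L), d3)
  h3 <- unname(tools::md5sum(file.path(d3, sort(list.files(
    d3, recursive = TRUE)))))
  expect_false(identical(h1, h3))
})

test_that("background read lengths peak at 24 nt", {
  sim <- small_sim()
  reads <- simulate_srna_reads(sim)
  h <- length_distribution(clean_reads(reads[[1]])$seq)
  expect_identical(h$mode, 24L)
})

test_that("expression coupling follows the repression model", {
  sim <- small_sim()
  # repression 0: planted pair correlations center at zero
  cfg0 <- small_sim_config(seed = 21L)
  cfg0$repression_strength <- 0
  sim0 <- make_genome(cfg0)
  ex0 <- simulate_expression_matrices(sim0, cfg0)
  mi0 <- average_by_tissue(ex0$mirna_rpm, ex0$mirna_tissue_of)
  tx0 <- average_by_tissue(ex0$fpkm, ex0$fpkm_tissue_of)
  r0 <- correlate_pairs(mi0, tx0, data.frame(
    mirna_id = sim0$truth$pairs$mirna_id,
    target_id = sim0$truth$pairs$transcript_id))
  expect_lt(abs(mean(r0$r[r0$defined])), 0.45)
  # strong repression: planted pairs go negative
  ex9 <- simulate_expression_matrices(sim)
  mi9 <- average_by_tissue(ex9$mirna_rpm, ex9$mirna_tissue_of)
  tx9 <- average_by_tissue(ex9$fpkm, ex9$fpkm_tissue_of)
  r9 <- correlate_pairs(mi9, tx9, data.frame(
    mirna_id = sim$truth$pairs$mirna_id,
    target_id = sim$truth$pairs$transcript_id))
  expect_lt(median(r9$r[r9$defined]), 0)
  # within-block transcript correlation is high
  blocks <- sim$truth$modules
  b1 <- blocks$transcript_id[blocks$block == "block1"]
  cm <- cor(t(ex9$fpkm[b1, ]))
  expect_gte(mean(cm[upper.tri(cm)]), 0.8)
})
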