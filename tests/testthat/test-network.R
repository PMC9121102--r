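toy_pwm <- function(consensus, id = "PWM1", fam = "WRKY", major = 0.85) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mat <- matrix((1 - major) / 3, 4, length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(ch)) mat[ch[j], j] <- major
  list(motif_id = id, tf_family = fam, mat = mat, consensus = consensus)
}

test_that("promoters are the 2 kb upstream of the strand-aware start", {
  genome <- c(chr1 = random_dna(10000))
  feats <- data.frame(id = c("gplus", "gedge", "gminus"),
                      chrom = "chr1",
                      start = c(5000L, 500L, 1000L),
                      end = c(6000L, 900L, 2000L),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  pr <- extract_promoters(feats, genome, upstream = 2000L)
  expect_identical(pr$start[pr$id == "gplus"], 3000L)
  expect_identical(pr$end[pr$id == "gplus"], 5000L)
  expect_identical(pr$seq[pr$id == "gplus"],
                   substring(genome[[1]], 3001, 5000))
  # truncation at the chromosome edge, realized length recorded
  expect_identical(pr$start[pr$id == "gedge"], 0L)
  expect_identical(pr$length[pr$id == "gedge"], 500L)
  # minus strand: downstream in genome coordinates, reverse-complemented
  expect_identical(pr$start[pr$id == "gminus"], 2000L)
  expect_identical(pr$end[pr$id == "gminus"], 4000L)
  expect_identical(pr$seq[pr$id == "gminus"],
                   revcomp(substring(genome[[1]], 2001, 4000)))
  feats$strand[1] <- "."
  expect_error(extract_promoters(feats, genome), "strand")
})

test_that("PWM files round-trip in JASPAR and MEME minimal formats", {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(">M1 WRKY",
               "A [ 10  1  1 80 ]",
               "C [ 10  1  1 10 ]",
               "G [ 70 97  1  5 ]",
               "T [ 10  1 97  5 ]"), f)
  pw <- read_pwms(f)
  expect_identical(names(pw), "M1")
  expect_identical(pw$M1$tf_family, "WRKY")
  expect_equal(colSums(pw$M1$mat), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(pw$M1$mat["G", 1]), 0.70)

  f2 <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M2 MYB",
               "letter-probability matrix: alength= 4 w= 4 nsites= 20",
               " 0.10 0.10 0.70 0.10",
               " 0.01 0.01 0.97 0.01",
               " 0.01 0.01 0.01 0.97",
               " 0.80 0.10 0.05 0.05"), f2)
  pw2 <- read_pwms(f2)
  expect_identical(pw2$M2$tf_family, "MYB")
  expect_equal(unname(pw2$M2$mat["G", 1]), 0.70, tolerance = 1e-6)
  expect_equal(unname(pw2$M2$mat["A", 4]), 0.80, tolerance = 1e-6)
})

test_that("score p-values equal exhaustive enumeration over all words", {
  set.seed(461)
  for (L in c(5, 6, 8)) {
    pwm <- toy_pwm(random_dna(L), major = 0.8)
    int_mat <- mircascade:::.pwm_int_scores(pwm$mat)
    tailf <- mircascade:::.pwm_tail(int_mat)
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    w_scores <- rowSums(int_mat[cbind(as.vector(words),
                                      rep(seq_len(L), each = 4^L))] |>
                          matrix(nrow = 4^L))
    for (q in c(0.999, 0.9, 0.5, 0.1, 0.001)) {
      s <- as.integer(quantile(w_scores, q))
      expect_equal(tailf(s), mean(w_scores >= s), tolerance = 1e-12,
                   info = paste("L =", L, "q =", q))
    }
  }
})

test_that("planted consensus is found; false positives stay near p_cut", {
  set.seed(462)
  pwm <- toy_pwm("GATTACAG")
  prom <- paste0(random_dna(600), "GATTACAG", random_dna(600))
  hits <- scan_motifs(setNames(prom, "p1"), list(pwm), p_cut = 1e-4)
  expect_true(any(hits$offset == 600 & hits$strand == "+"))
  best <- hits[which.min(hits$p_value), ]
  expect_identical(best$offset, 600L)
  # strand symmetry: the reverse-complemented promoter hits on "-"
  hits_rc <- scan_motifs(setNames(revcomp(prom), "p1"), list(pwm),
                         p_cut = 1e-4)
  expect_true(any(hits_rc$strand == "-" &
                    hits_rc$offset == nchar(prom) - 8L - 600L))
  # false-positive rate per window is bounded by p_cut (binomial check)
  n_win <- 0
  n_hit <- 0
  for (rep in 1:20) {
    bg <- setNames(random_dna(2000), "bg")
    h <- scan_motifs(bg, list(pwm), p_cut = 1e-3)
    n_hit <- n_hit + nrow(h)
    n_win <- n_win + 2 * (2000 - 8 + 1)
  }
  # expected ~ n_win * 1e-3; allow 4 sd of binomial noise
  expect_lt(n_hit, n_win * 1e-3 + 4 * sqrt(n_win * 1e-3))
})

test_that("edge building deduplicates and drops TF self-edges", {
  hits_mi <- data.frame(promoter_id = c("mirA", "mirA", "mirB"),
                        motif_id = c("M1", "M1", "M2"),
                        offset = c(10L, 500L, 20L), strand = "+",
                        score = 1, p_value = 1e-5,
                        stringsAsFactors = FALSE)
  hits_g <- data.frame(promoter_id = c("tf1", "g2"),
                       motif_id = c("M1", "M1"),
                       offset = c(5L, 6L), strand = "+", score = 1,
                       p_value = 1e-5, stringsAsFactors = FALSE)
  inter <- data.frame(mirna_id = c("mirA", "mirB"),
                      transcript_id = c("g2", "g3"),
                      stringsAsFactors = FALSE)
  tf_map <- data.frame(motif_id = c("M1", "M2"), tf_id = c("tf1", "tf2"),
                       stringsAsFactors = FALSE)
  edges <- build_edges(hits_mi, hits_g, inter, tf_map)
  # same TF hitting the same promoter twice -> one edge, two evidences
  tmA <- edges$tmi[edges$tmi$mirna_id == "mirA", ]
  expect_identical(nrow(tmA), 1L)
  expect_identical(tmA$n_evidence, 2L)
  # TTI self-edge tf1 -> tf1 dropped
  expect_false(any(edges$tti$tf_id == edges$tti$target_id))
  expect_identical(edges$tti$target_id, "g2")
  # MTI equals the interaction pairs
  expect_identical(nrow(edges$mti), nrow(inter))
})

test_that("cascade and FFL counts equal brute-force triple loops", {
  tmi <- data.frame(tf_id = c("T1", "T2"), mirna_id = c("m1", "m1"))
  mti <- data.frame(mirna_id = c("m1", "m1"), target_id = c("g1", "g2"))
  tti <- data.frame(tf_id = "T1", target_id = "g1")
  mot <- enumerate_motifs(list(tmi = tmi, mti = mti, tti = tti))
  expect_identical(unname(mot$counts["n_cascades"]), 4L)
  expect_identical(unname(mot$counts["n_ffls"]), 1L)
  # emptying TTI keeps cascades, removes FFLs
  mot0 <- enumerate_motifs(list(tmi = tmi, mti = mti,
                                tti = tti[0, , drop = FALSE]))
  expect_identical(unname(mot0$counts["n_cascades"]), 4L)
  expect_identical(unname(mot0$counts["n_ffls"]), 0L)

  set.seed(463)
  for (rep in 1:10) {
    n_tf <- sample(5:20, 1); n_mi <- sample(3:10, 1)
    n_g <- sample(10:40, 1)
    tmi <- unique(data.frame(
      tf_id = paste0("T", sample(n_tf, 40, TRUE)),
      mirna_id = paste0("m", sample(n_mi, 40, TRUE))))
    mti <- unique(data.frame(
      mirna_id = paste0("m", sample(n_mi, 50, TRUE)),
      target_id = paste0("g", sample(n_g, 50, TRUE))))
    tti <- unique(data.frame(
      tf_id = paste0("T", sample(n_tf, 60, TRUE)),
      target_id = paste0("g", sample(n_g, 60, TRUE))))
    mot <- enumerate_motifs(list(tmi = tmi, mti = mti, tti = tti))
    oracle <- oracle_motifs(tmi, mti, tti)
    expect_identical(unname(mot$counts["n_cascades"]),
                     unname(oracle["cascades"]))
    expect_identical(unname(mot$counts["n_ffls"]), unname(oracle["ffls"]))
    expect_lte(mot$counts["n_ffls"], mot$counts["n_cascades"])
  }
})

test_that("network export round-trips through SIF and GraphML", {
  edges <- list(
    tmi = data.frame(tf_id = "T1", mirna_id = "m1"),
    mti = data.frame(mirna_id = "m1", target_id = "g1"),
    tti = data.frame(tf_id = "T1", target_id = "g1"))
  prefix <- file.path(tempfile("net"), "network")
  g <- export_network(edges, prefix)
  sif <- readLines(paste0(prefix, ".sif"))
  expect_length(sif, 3L)
  expect_true(any(grepl("^T1\tTMI\tm1$", sif)))
  nodes <- read.delim(paste0(prefix, ".nodes.tsv"))
  expect_setequal(nodes$kind, c("TF", "miRNA", "target"))
  g2 <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  el <- igraph::as_data_frame(g2, what = "edges")
  expect_identical(nrow(el), 3L)
  expect_setequal(el$type, c("TMI", "MTI", "TTI"))
  # empty network still writes valid files
  empty <- lapply(edges, function(d) d[0, , drop = FALSE])
  prefix0 <- file.path(tempfile("net0"), "network")
  export_network(empty, prefix0)
  expect_length(readLines(paste0(prefix0, ".sif")), 0L)
})
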