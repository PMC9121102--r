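# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# a small synthetic dataset for stage tests (fast to generate)
small_sim_config <- function(seed = 11L) {
  sim_config(seed = seed, n_chrom = 2L, chrom_len = 80000L,
             n_true_loci = 6L, n_decoy_loci = 4L, n_transcripts = 30L,
             depth_per_lib = 400L, n_pairs = 6L, n_modules = 3L,
             n_module_genes = 6L, n_tf_genes = 6L)
}

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- make_genome(small_sim_config())
  }
  .fixture_env$sim
}

# brute-force maximum base pairing by exhaustive enumeration (oracle)
oracle_max_pairs <- function(seq, min_loop = 3L) {
  pairable <- function(a, b) {
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  best <- function(idx) {
    if (length(idx) < 2L) return(0L)
    i <- idx[1]
    # i unpaired
    b <- best(idx[-1])
    # i paired with some j
    for (jj in seq_along(idx)[-1]) {
      j <- idx[jj]
      if (j - i > min_loop && pairable(ch[i], ch[j])) {
        inside <- idx[idx > i & idx < j]
        outside <- idx[idx > j]
        b <- max(b, 1L + best(inside) + best(outside))
      }
    }
    b
  }
  best(seq_len(n))
}

# independent ungapped expectation scoring of one alignment (oracle)
oracle_expectation_ungapped <- function(mirna, site) {
  m <- nchar(mirna)
  stopifnot(nchar(site) == m)
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  st <- strsplit(site, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  e <- 0
  for (p in seq_len(m)) {
    b <- st[m - p + 1]
    pen <- if (comp[[mi[p]]] == b) {
      0
    } else if ((mi[p] == "G" && b == "T") || (mi[p] == "T" && b == "G")) {
      0.5
    } else {
      1
    }
    if (p >= 2 && p <= 13) pen <- pen * 2
    e <- e + pen
  }
  e
}

# independent degradome category derivation (oracle)
oracle_category <- function(profile, position) {
  d <- profile[position + 1]
  nz <- profile[profile >= 1]
  M <- max(nz)
  med <- median(nz)
  if (d == M) {
    if (sum(nz == M) == 1) 0L else 1L
  } else if (d > med) 2L else if (d > 1) 3L else 4L
}

# brute-force cascade/FFL enumeration by triple loop over edges (oracle)
oracle_motifs <- function(tmi, mti, tti) {
  cas <- 0L
  ffl <- 0L
  tti_key <- paste(tti$tf_id, tti$target_id)
  for (i in seq_len(nrow(tmi))) {
    for (j in seq_len(nrow(mti))) {
      if (tmi$mirna_id[i] == mti$mirna_id[j]) {
        cas <- cas + 1L
        if (paste(tmi$tf_id[i], mti$target_id[j]) %in% tti_key) {
          ffl <- ffl + 1L
        }
      }
    }
  }
  c(cascades = cas, ffls = ffl)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
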