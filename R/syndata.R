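# Synthetic dataset generator with machine-checkable truth tables.
#
# The generator emulates the study design the pipeline expects: 7 tissues
# (RS/SS/LS at shooting stage, RG/SG/LG/P at grain filling), 2 sRNA
# replicates, 3 mRNA replicates and 1 PARE library per tissue. A toy
# genome hosts hairpin loci whose mature:star duplex satisfies every
# annotation criterion by construction, plus decoy hairpins each violating
# exactly one named criterion; protein-coding transcripts carry planted
# miRNA target sites and 2,000-nt upstream promoters with planted TF
# motifs. Hairpins alternate strands. Loops and 10-nt buffers flanking
# each hairpin are composed of non-pairing letters relative to the arm
# design so the planted duplex is the unique maximum-pairing structure.
# Counts are negative binomial (per-tissue mean from the planted
# expression-pattern class, dispersion from the config); background reads
# are drawn uniformly from the non-locus genome with a designed 24-nt
# length peak. Every output file draws from its own RNG stream derived
# from the master seed by a stable label.

#' Simulation configuration
#'
#' @param seed master seed; all file-level streams derive from it.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length, bp.
#' @param n_true_loci planted true miRNA loci.
#' @param n_decoy_loci planted decoy hairpins (each violates one criterion).
#' @param n_transcripts protein-coding transcripts.
#' @param tissues tissue labels.
#' @param srna_reps,mrna_reps,pare_reps replicates per tissue.
#' @param depth_per_lib background reads per sRNA library (locus-derived
#'   reads come on top).
#' @param nb_dispersion negative-binomial dispersion (var = mu + mu^2 d).
#' @param repression_strength fraction in `[0, 1]`; expected target level is
#'   `base * (1 - repression_strength * normalized miRNA level)`.
#' @param n_pwms planted position weight matrices.
#' @param promoter_plant_rate fraction of promoters receiving a TF site.
#' @param n_pairs planted miRNA-target pairs (target sites, PARE signal and
#'   expression coupling).
#' @param n_modules planted co-expression blocks (first block is
#'   panicle-high).
#' @param n_module_genes transcripts per block.
#' @param n_tf_genes transcripts annotated as TFs.
#' @return validated config list.
#' @export
sim_config <- function(seed = 42L, n_chrom = 2L, chrom_len = 200000L,
                       n_true_loci = 30L, n_decoy_loci = 10L,
                       n_transcripts = 80L, tissues = TISSUES,
                       srna_reps = 2L, mrna_reps = 3L, pare_reps = 1L,
                       depth_per_lib = 2000L, nb_dispersion = 0.2,
                       repression_strength = 0.9, n_pwms = 5L,
                       promoter_plant_rate = 0.4, n_pairs = 20L,
                       n_modules = 3L, n_module_genes = 15L,
                       n_tf_genes = 12L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_true_loci >= 1, length(cfg$tissues) == 7,
            cfg$nb_dispersion > 0,
            cfg$repression_strength >= 0, cfg$repression_strength <= 1,
            cfg$promoter_plant_rate >= 0, cfg$promoter_plant_rate <= 1,
            cfg$n_pairs <= cfg$n_true_loci * cfg$n_transcripts,
            cfg$n_modules * cfg$n_module_genes + cfg$n_pairs +
              cfg$n_tf_genes <= cfg$n_transcripts)
  cfg
}

.rand_seq <- function(n, bases = DNA_BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

# mutate k interior positions (5..m-6, away from all constrained letters)
.mutate_interior <- function(s, k) {
  if (k == 0L) return(s)
  m <- nchar(s)
  pos <- sample(seq(5L, m - 6L), k)
  for (p in pos) {
    substr(s, p, p) <- sample(setdiff(DNA_BASES, substring(s, p, p)), 1)
  }
  s
}

# Build one hairpin. Returns list(precursor, mature, star, arm5,
# off_mature, off_star) with offsets 0-based within the precursor string.
# Mature letter constraints (loop-adjacent duplex positions G/C, 3'
# overhang A/C, mismatches planted as C:C) together with the all-A loop
# and buffers make the planted duplex the unique maximum-pairing
# structure. `mature` may be supplied to build a family member variant.
.make_hairpin <- function(mature_len, arm5_mature, n_mismatch = 0L,
                          bulge = 0L, mature = NULL, gc_arms = FALSE) {
  m <- mature_len
  if (is.null(mature)) {
    M <- character(m)
    if (gc_arms) {
      # decoy hairpins use a G/C-only duplex with A:A mismatches and
      # A-bulges: an A can pair nothing in a G/C arm, so the planted
      # defect cannot be refolded away by the maximum-pairing folder.
      # The G-skewed composition keeps each arm from pairing with itself.
      for (i in seq_len(m)) M[i] <- sample(c("G", "C"), 1,
                                           prob = c(0.8, 0.2))
    } else {
      for (i in seq_len(m)) M[i] <- sample(DNA_BASES, 1)
      M[c(1L, 2L, m - 3L, m - 2L)] <- sample(c("G", "C"), 4,
                                             replace = TRUE)
    }
    M[c(m - 1L, m)] <- sample(c("A", "C"), 2, replace = TRUE)
  } else {
    stopifnot(nchar(mature) == m)
    M <- strsplit(mature, "", fixed = TRUE)[[1]]
  }
  mm_letter <- if (gc_arms) "A" else "C"
  mm_pos <- integer(0)
  if (n_mismatch > 0L) {
    cand <- seq(5L, m - 6L)
    mm_pos <- sort(sample(cand, n_mismatch))
    M[mm_pos] <- mm_letter
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # S[k] pairs M[m-1-k] for k = 1..m-2; S[m-1], S[m] form the 3' overhang
  S <- character(m)
  for (k in seq_len(m - 2L)) S[k] <- comp[[M[m - 1L - k]]]
  if (length(mm_pos)) {
    # facing same-letter mismatches at the planted positions
    S[m - 1L - mm_pos] <- mm_letter
  }
  S[c(m - 1L, m)] <- sample(c("A", "C"), 2, replace = TRUE)
  if (bulge > 0L) {
    ins_at <- 3L  # after star position 3: long correctly-framed run remains
    S <- c(S[seq_len(ins_at)], rep(if (gc_arms) "A" else "C", bulge),
           S[seq.int(ins_at + 1L, length(S))])
  }
  loop <- rep("A", sample(12:18, 1))
  if (arm5_mature) {
    pre <- c(M, loop, S)
    off_m <- 0L
    off_s <- m + length(loop)
  } else {
    pre <- c(S, loop, M)
    off_s <- 0L
    off_m <- length(S) + length(loop)
  }
  list(precursor = paste(pre, collapse = ""),
       mature = paste(M, collapse = ""), star = paste(S, collapse = ""),
       arm5_mature = arm5_mature, off_mature = off_m, off_star = off_s,
       star_len = length(S), n_mismatch = n_mismatch, bulge = bulge)
}

# planted family / conservation plan for the true loci (recycled as needed)
.family_plan <- function(n) {
  plan <- data.frame(
    family = c("miR156", "miR156", "miR166", "miR166", "miR395", "miR395",
               "miR167", "miR169", "miR171", "miR396", "miR397", "miR398",
               "miR408", "miR2275", "miR160", "miR172", "miR159", "miR164",
               "miR319", "miR394", "miR827",
               "miR1432", "miR5179", "miR5384", "miR6300",
               NA, NA, NA, NA, NA),
    class = c(rep("conserved", 21), rep("poaceae_specific", 4),
              rep("species_specific", 5)),
    stringsAsFactors = FALSE)
  plan[rep(seq_len(nrow(plan)), length.out = n), ]
}

# planted expression-pattern plan (low classes go to species-specific
# single loci so that unrecoverable low-abundance loci never break the
# synteny truth)
.pattern_plan <- function(n, tissues) {
  cls <- rep("intermediate", n)
  cls[seq_len(min(6, n))] <- "housekeeping"
  ts_idx <- if (n >= 7) seq(7L, min(14L, n)) else integer(0)
  cls[ts_idx] <- "tissue_specific"
  if (n >= 27) cls[c(26, 27)] <- "low"
  peak <- rep(NA_character_, n)
  peak[ts_idx] <- tissues[((seq_along(ts_idx) - 1) %% length(tissues)) + 1]
  int_idx <- which(cls == "intermediate")
  hi1 <- tissues[((seq_along(int_idx) - 1) %% 7) + 1]
  hi2 <- tissues[(seq_along(int_idx) %% 7) + 1]
  data.frame(class = cls, peak_tissue = peak,
             int_hi1 = replace(rep(NA_character_, n), int_idx, hi1),
             int_hi2 = replace(rep(NA_character_, n), int_idx, hi2),
             stringsAsFactors = FALSE)
}

# per-library negative-binomial mean of mature reads for one locus/tissue
.read_mu <- function(pattern_row, tissue) {
  switch(pattern_row$class,
         housekeeping = 12,
         tissue_specific = if (tissue == pattern_row$peak_tissue) 30
                           else 0.02,
         intermediate = if (tissue %in% c(pattern_row$int_hi1,
                                          pattern_row$int_hi2)) 12
                        else 0.02,
         low = 0.02,
         decoy = 15)
}

#' Generate the toy genome, annotation and truth tables
#'
#' @param config configuration from [sim_config()].
#' @return list with `genome` (named chromosome sequences), `features`
#'   (gene/mRNA feature table), `transcripts` (named sequences), `ncrna`,
#'   `catalogue` (reference-catalogue data.frame), `pwms`, `tf_map`,
#'   `tf_genes`, `blocks`, and `truth` (loci, target_sites, tf_sites,
#'   patterns, pairs, modules).
#' @export
make_genome <- function(config = sim_config()) {
  with_seed(stable_seed(config$seed, "genome"), {
    n_loci <- config$n_true_loci + config$n_decoy_loci
    fam <- .family_plan(config$n_true_loci)
    pat <- .pattern_plan(config$n_true_loci, config$tissues)
    decoy_types <- rep(c("duplex_mismatches", "asym_bulge", "star_reads",
                         "precision"), length.out = config$n_decoy_loci)

    hairpins <- vector("list", n_loci)
    fam_first <- list()  # family -> mature of the first member
    for (i in seq_len(n_loci)) {
      is_decoy <- i > config$n_true_loci
      type <- if (is_decoy) decoy_types[i - config$n_true_loci] else "true"
      n_mm <- switch(type, true = sample(0:2, 1), duplex_mismatches = 7L, 0L)
      blg <- if (type == "asym_bulge") 5L else 0L
      fm <- if (is_decoy) NA_character_ else fam$family[i]
      if (!is.na(fm) && !is.null(fam_first[[fm]])) {
        # later family members: a 1-2 nt interior variant of member 1,
        # no extra planted mismatches (keeps them within the catalogue
        # matching distance)
        base_mat <- fam_first[[fm]]
        variant <- .mutate_interior(base_mat, sample(1:2, 1))
        hairpins[[i]] <- c(.make_hairpin(nchar(variant),
                                         arm5_mature = i %% 2L == 1L,
                                         n_mismatch = 0L, bulge = 0L,
                                         mature = variant),
                           list(type = type, is_decoy = is_decoy))
      } else {
        mlen <- sample(c(20L, 21L, 21L, 21L, 21L, 22L, 24L), 1)
        hairpins[[i]] <- c(.make_hairpin(
          mlen, arm5_mature = i %% 2L == 1L, n_mismatch = n_mm,
          bulge = blg,
          gc_arms = type %in% c("duplex_mismatches", "asym_bulge")),
          list(type = type, is_decoy = is_decoy))
        if (!is.na(fm)) fam_first[[fm]] <- hairpins[[i]]$mature
      }
    }

    # transcript bodies; pairs plant perfect complementary sites
    tf_ids <- sprintf("tx%03d", seq_len(config$n_tf_genes))
    target_start <- config$n_tf_genes + 1L
    pair_tx <- sprintf("tx%03d",
                       seq(target_start, target_start + config$n_pairs - 1L))
    pair_mirna_idx <- rep(seq_len(config$n_true_loci),
                          length.out = config$n_pairs)
    tx_seqs <- character(config$n_transcripts)
    tx_len <- sample(600:900, config$n_transcripts, replace = TRUE)
    sites <- list()
    for (j in seq_len(config$n_transcripts)) {
      tx_seqs[j] <- .rand_seq(tx_len[j])
    }
    for (p in seq_len(config$n_pairs)) {
      j <- target_start + p - 1L
      mi <- hairpins[[pair_mirna_idx[p]]]$mature
      L <- nchar(mi)
      off <- sample(seq(100L, tx_len[j] - 150L), 1)
      substr(tx_seqs[j], off + 1L, off + L) <- revcomp(mi)
      sites[[p]] <- data.frame(
        mirna = sprintf("mir%02d", pair_mirna_idx[p]),
        transcript_id = sprintf("tx%03d", j), site_start = off,
        site_end = off + L, cleavage_pos = off + L - 10L,
        stringsAsFactors = FALSE)
    }
    target_sites <- do.call(rbind, sites)

    # chromosome assembly: interleave transcripts and loci
    chrom_names <- sprintf("chr%d", seq_len(config$n_chrom))
    chrom <- lapply(chrom_names, function(cn) {
      strsplit(.rand_seq(config$chrom_len), "", fixed = TRUE)[[1]]
    })
    names(chrom) <- chrom_names
    entities <- character(0)
    ti <- li <- 1L
    while (ti <= config$n_transcripts || li <= n_loci) {
      for (k in 1:2) {
        if (ti <= config$n_transcripts) {
          entities <- c(entities, paste0("t", ti)); ti <- ti + 1L
        }
      }
      if (li <= n_loci) {
        entities <- c(entities, paste0("l", li)); li <- li + 1L
      }
    }
    per_chrom <- split(entities, cut(seq_along(entities),
                                     breaks = config$n_chrom,
                                     labels = FALSE))

    features <- list()
    loci_rows <- list()
    tx_coord <- list()
    for (ci in seq_along(per_chrom)) {
      cn <- chrom_names[ci]
      cursor <- 300L
      for (ent in per_chrom[[ci]]) {
        cursor <- cursor + sample(150:400, 1)
        kind <- substring(ent, 1, 1)
        idx <- as.integer(substring(ent, 2))
        if (kind == "t") {
          strand <- if (idx %% 4L == 0L) "-" else "+"
          blen <- tx_len[idx]
          need <- 2000L + blen
          if (cursor + need > config$chrom_len - 300L) {
            stop(sprintf(
              "chromosome too short to host requested loci/transcripts: %s needs %d bp at offset %d (chrom_len = %d)",
              ent, need, cursor, config$chrom_len), call. = FALSE)
          }
          if (strand == "+") {
            bs <- cursor + 2000L
          } else {
            bs <- cursor
          }
          be <- bs + blen
          body <- tx_seqs[idx]
          seg <- if (strand == "+") body else revcomp(body)
          chrom[[cn]][(bs + 1L):be] <- strsplit(seg, "", fixed = TRUE)[[1]]
          tid <- sprintf("tx%03d", idx)
          features[[length(features) + 1L]] <- data.frame(
            chrom = cn, start = bs, end = be, strand = strand,
            type = "gene", id = paste0(tid, ".g"), parent = "",
            stringsAsFactors = FALSE)
          features[[length(features) + 1L]] <- data.frame(
            chrom = cn, start = bs, end = be, strand = strand,
            type = "mRNA", id = tid, parent = paste0(tid, ".g"),
            stringsAsFactors = FALSE)
          tx_coord[[tid]] <- list(chrom = cn, start = bs, end = be,
                                  strand = strand)
          cursor <- cursor + need
        } else {
          hp <- hairpins[[idx]]
          strand <- if (idx %% 2L == 1L) "+" else "-"
          plen <- nchar(hp$precursor)
          need <- plen + 20L
          if (cursor + need > config$chrom_len - 300L) {
            stop(sprintf(
              "chromosome too short to host requested loci/transcripts: %s needs %d bp at offset %d (chrom_len = %d)",
              ent, need, cursor, config$chrom_len), call. = FALSE)
          }
          ps <- cursor + 10L
          pe <- ps + plen
          seg <- paste0(strrep("A", 10), hp$precursor, strrep("A", 10))
          if (strand == "-") seg <- revcomp(seg)
          chrom[[cn]][(cursor + 1L):(cursor + need)] <-
            strsplit(seg, "", fixed = TRUE)[[1]]
          # oriented offsets -> genomic intervals
          o2g <- function(off, len) {
            if (strand == "+") c(ps + off, ps + off + len)
            else c(pe - off - len, pe - off)
          }
          gm <- o2g(hp$off_mature, nchar(hp$mature))
          gs <- o2g(hp$off_star, hp$star_len)
          is_decoy <- hp$is_decoy
          lid <- if (is_decoy) sprintf("dec%02d", idx - config$n_true_loci)
                 else sprintf("mir%02d", idx)
          loci_rows[[length(loci_rows) + 1L]] <- data.frame(
            locus_id = lid, chrom = cn, strand = strand,
            pre_start = ps, pre_end = pe,
            mature_start = gm[1], mature_end = gm[2],
            star_start = gs[1], star_end = gs[2],
            mature_seq = hp$mature, star_seq = hp$star,
            is_decoy = is_decoy,
            violation = if (is_decoy) hp$type else "",
            family = if (is_decoy) NA_character_
                     else fam$family[idx],
            conservation_class = if (is_decoy) NA_character_
                                 else fam$class[idx],
            stringsAsFactors = FALSE)
          cursor <- cursor + need
        }
      }
    }
    features <- do.call(rbind, features)
    loci <- do.call(rbind, loci_rows)
    loci <- loci[order(loci$locus_id), , drop = FALSE]
    rownames(loci) <- NULL
    true_loci <- loci[!loci$is_decoy, , drop = FALSE]

    # novel families get synthetic family names for the truth table
    nov <- which(is.na(true_loci$family))
    true_loci$family[nov] <- sprintf("novel%02d", seq_along(nov))
    loci$family[match(true_loci$locus_id, loci$locus_id)] <- true_loci$family

    # reference catalogue with species/lineage metadata; multi-member
    # families use member 1's mature verbatim so every member stays within
    # the 2-mismatch matching distance
    cat_rows <- list()
    for (fm in unique(true_loci$family)) {
      sub <- true_loci[true_loci$family == fm, ]
      cl <- sub$conservation_class[1]
      if (cl == "species_specific") next
      ref <- if (nrow(sub) > 1L) sub$mature_seq[1] else
        .mutate_interior(sub$mature_seq[1], sample(0:1, 1))
      if (cl == "conserved") {
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          name = paste0("ath-", fm), seq = ref,
          species = "Arabidopsis_thaliana", lineage = "non-Poaceae",
          family = fm)
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          name = paste0("osa-", fm), seq = .mutate_interior(ref, 1),
          species = "Oryza_sativa", lineage = "Poaceae", family = fm)
      } else {
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          name = paste0("osa-", fm), seq = ref, species = "Oryza_sativa",
          lineage = "Poaceae", family = fm)
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          name = paste0("zma-", fm), seq = .mutate_interior(ref, 1),
          species = "Zea_mays", lineage = "Poaceae", family = fm)
      }
    }
    catalogue <- do.call(rbind, cat_rows)

    true_loci <- loci[!loci$is_decoy, , drop = FALSE]

    # synteny blocks around the two-member families + two empty decoy blocks
    multi <- Filter(function(fm) {
      sum(true_loci$family == fm) >= 2
    }, unique(true_loci$family))
    blocks <- list()
    for (fm in head(multi, 3)) {
      idx <- which(true_loci$family == fm)
      a <- true_loci[idx[1], ]; b <- true_loci[idx[2], ]
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = sprintf("block%02d", length(blocks) + 1L),
        a_chrom = a$chrom, a_start = max(0L, a$pre_start - 2000L),
        a_end = a$pre_end + 2000L,
        b_chrom = b$chrom, b_start = max(0L, b$pre_start - 2000L),
        b_end = b$pre_end + 2000L, stringsAsFactors = FALSE)
    }
    for (z in 1:2) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = sprintf("block%02d", length(blocks) + 1L),
        a_chrom = chrom_names[1], a_start = 10L + z, a_end = 60L + z,
        b_chrom = chrom_names[config$n_chrom], b_start = 10L + z,
        b_end = 60L + z, stringsAsFactors = FALSE)
    }
    blocks <- do.call(rbind, blocks)

    # PWMs + TF map
    pwms <- list()
    tf_map <- list()
    for (w in seq_len(config$n_pwms)) {
      L <- 8L
      cons <- strsplit(.rand_seq(L), "", fixed = TRUE)[[1]]
      mat <- matrix(0.05, 4, L, dimnames = list(DNA_BASES, NULL))
      for (j in seq_len(L)) mat[cons[j], j] <- 0.85
      id <- sprintf("PWM%02d", w)
      fams <- c("WRKY", "MYB", "ERF", "NAC", "SBP", "AP2", "bZIP")
      pwms[[id]] <- list(motif_id = id,
                         tf_family = fams[((w - 1) %% length(fams)) + 1],
                         mat = mat, consensus = paste(cons, collapse = ""))
      carriers <- tf_ids[((w - 1L) %% config$n_tf_genes) + c(1L, 2L)]
      carriers <- carriers[!is.na(carriers)]
      tf_map[[length(tf_map) + 1L]] <- data.frame(
        motif_id = id, tf_id = carriers, stringsAsFactors = FALSE)
    }
    tf_map <- do.call(rbind, tf_map)
    tf_genes <- data.frame(
      gene_id = tf_ids,
      family = vapply(seq_along(tf_ids), function(i) {
        hit <- tf_map$motif_id[tf_map$tf_id == tf_ids[i]][1]
        if (is.na(hit)) "unknown" else pwms[[hit]]$tf_family
      }, character(1)), stringsAsFactors = FALSE)

    # plant TF sites into promoters (transcripts and true loci)
    owners <- rbind(
      data.frame(id = names(tx_coord),
                 chrom = vapply(tx_coord, `[[`, "", "chrom"),
                 start = vapply(tx_coord, function(x) x$start, 0),
                 end = vapply(tx_coord, function(x) x$end, 0),
                 strand = vapply(tx_coord, `[[`, "", "strand"),
                 stringsAsFactors = FALSE),
      data.frame(id = true_loci$locus_id, chrom = true_loci$chrom,
                 start = true_loci$pre_start, end = true_loci$pre_end,
                 strand = true_loci$strand, stringsAsFactors = FALSE))
    reserved <- rbind(
      data.frame(chrom = loci$chrom, start = loci$pre_start - 12L,
                 end = loci$pre_end + 12L),
      do.call(rbind, lapply(seq_len(nrow(target_sites)), function(p) {
        tc <- tx_coord[[target_sites$transcript_id[p]]]
        if (tc$strand == "+") {
          data.frame(chrom = tc$chrom,
                     start = tc$start + target_sites$site_start[p],
                     end = tc$start + target_sites$site_end[p])
        } else {
          data.frame(chrom = tc$chrom,
                     start = tc$end - target_sites$site_end[p],
                     end = tc$end - target_sites$site_start[p])
        }
      })))
    tf_sites <- list()
    for (oi in seq_len(nrow(owners))) {
      if (runif(1) > config$promoter_plant_rate) next
      pwm <- pwms[[sample(length(pwms), 1)]]
      L <- nchar(pwm$consensus)
      motif_strand <- sample(c("+", "-"), 1)
      ok <- FALSE
      for (try in 1:20) {
        off <- sample(100:(2000L - L - 100L), 1)
        if (owners$strand[oi] == "+") {
          gs <- owners$start[oi] - 2000L + off
        } else {
          gs <- owners$end[oi] + 2000L - off - L
        }
        ge <- gs + L
        if (gs < 0 || ge > config$chrom_len) next
        clash <- any(reserved$chrom == owners$chrom[oi] &
                       reserved$start < ge & reserved$end > gs)
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) next
      word <- if (motif_strand == "+") pwm$consensus
              else revcomp(pwm$consensus)
      gseg <- if (owners$strand[oi] == "+") word else revcomp(word)
      chrom[[owners$chrom[oi]]][(gs + 1L):ge] <-
        strsplit(gseg, "", fixed = TRUE)[[1]]
      reserved <- rbind(reserved, data.frame(chrom = owners$chrom[oi],
                                             start = gs, end = ge))
      tf_sites[[length(tf_sites) + 1L]] <- data.frame(
        motif_id = pwm$motif_id, owner_id = owners$id[oi], offset = off,
        strand = motif_strand, stringsAsFactors = FALSE)
    }
    tf_sites <- if (length(tf_sites)) do.call(rbind, tf_sites) else
      data.frame(motif_id = character(0), owner_id = character(0),
                 offset = integer(0), strand = character(0))

    genome <- vapply(chrom, paste, character(1), collapse = "")
    # transcript sequences re-extracted from the (patched) genome
    transcripts <- vapply(names(tx_coord), function(tid) {
      tc <- tx_coord[[tid]]
      s <- substring(genome[[tc$chrom]], tc$start + 1L, tc$end)
      if (tc$strand == "-") revcomp(s) else s
    }, character(1))

    ncrna <- setNames(
      vapply(c(80, 120, 95, 140), .rand_seq, character(1)),
      c("tRNA1", "rRNA1", "snRNA1", "snoRNA1"))

    patterns <- data.frame(
      mirna_id = sprintf("mir%02d", seq_len(config$n_true_loci)),
      pat, stringsAsFactors = FALSE, row.names = NULL)
    modules <- data.frame(
      transcript_id = sprintf("tx%03d", seq_len(config$n_transcripts)),
      block = "none", stringsAsFactors = FALSE)
    mod_start <- config$n_tf_genes + config$n_pairs + 1L
    for (b in seq_len(config$n_modules)) {
      idx <- mod_start + (b - 1L) * config$n_module_genes +
        seq_len(config$n_module_genes) - 1L
      modules$block[idx] <- sprintf("block%d", b)
    }
    pairs <- data.frame(mirna_id = target_sites$mirna,
                        transcript_id = target_sites$transcript_id,
                        stringsAsFactors = FALSE)

    list(genome = genome, features = features, transcripts = transcripts,
         ncrna = ncrna, catalogue = catalogue, pwms = pwms,
         tf_map = tf_map, tf_genes = tf_genes, blocks = blocks,
         truth = list(loci = loci, target_sites = target_sites,
                      tf_sites = tf_sites, patterns = patterns,
                      pairs = pairs, modules = modules),
         config = config)
  })
}

.rnb <- function(n, mu, dispersion) {
  if (mu <= 0) return(integer(n))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate small-RNA FASTQ libraries
#'
#' Mature and star reads are sampled at the planted coordinates (80%
#' exact, 15% 1-nt shift, 5% 2-nt shift; star reads about one quarter of
#' mature reads), decoys receive reads matching their violation label,
#' structural-ncRNA reads are added, and background reads are drawn from
#' the non-locus genome with a designed 24-nt length peak. A small
#' fraction of background reads carries polyA tails or out-of-range
#' lengths to exercise cleaning.
#'
#' @param sim output of [make_genome()].
#' @param config simulation config.
#' @return named list (one element per library `TISSUE_r<rep>`) of
#'   data.frames with `id`, `seq`.
#' @export
simulate_srna_reads <- function(sim, config = sim$config) {
  truth <- sim$truth$loci
  pat <- sim$truth$patterns
  genome <- sim$genome
  libs <- list()
  shift_probs <- c(`0` = 0.8, `1` = 0.075, `-1` = 0.075, `2` = 0.025,
                   `-2` = 0.025)
  get_read <- function(chrom, start, end, strand) {
    s <- substring(genome[[chrom]], start + 1L, end)
    if (strand == "-") revcomp(s) else s
  }
  for (tissue in config$tissues) {
    for (rep_i in seq_len(config$srna_reps)) {
      lib <- sprintf("%s_r%d", tissue, rep_i)
      with_seed(stable_seed(config$seed, paste0("srna/", lib)), {
        seqs <- character(0)
        emit_stack <- function(n, chrom, start, end, strand) {
          if (n <= 0) return(character(0))
          sh <- as.integer(sample(names(shift_probs), n, replace = TRUE,
                                  prob = shift_probs))
          vapply(sh, function(d) {
            get_read(chrom, start + d, end + d, strand)
          }, character(1))
        }
        for (i in seq_len(nrow(truth))) {
          row <- truth[i, ]
          pr <- if (row$is_decoy) list(class = "decoy")
                else as.list(pat[pat$mirna_id == row$locus_id, ])
          mu <- .read_mu(pr, tissue)
          n_m <- .rnb(1, mu, config$nb_dispersion)
          seqs <- c(seqs, emit_stack(n_m, row$chrom, row$mature_start,
                                     row$mature_end, row$strand))
          if (!(row$is_decoy && row$violation == "star_reads")) {
            n_s <- .rnb(1, mu / 4, config$nb_dispersion)
            seqs <- c(seqs, emit_stack(n_s, row$chrom, row$star_start,
                                       row$star_end, row$strand))
          }
          if (row$is_decoy && row$violation == "precision") {
            mlen <- row$mature_end - row$mature_start
            for (off in c(4L, 6L, 8L, 10L, 12L, 14L)) {
              n_j <- .rnb(1, mu * 0.4, config$nb_dispersion)
              if (row$strand == "+") {
                js <- row$mature_start + off
              } else {
                js <- row$mature_start - off
              }
              if (n_j > 0) {
                seqs <- c(seqs, rep(get_read(row$chrom, js, js + mlen,
                                             row$strand), n_j))
              }
            }
          }
        }
        # ncRNA-derived reads
        n_nc <- round(0.05 * config$depth_per_lib)
        for (z in seq_len(n_nc)) {
          src <- sim$ncrna[[sample(length(sim$ncrna), 1)]]
          w <- sample(19:25, 1)
          st <- sample(nchar(src) - w, 1)
          seqs <- c(seqs, substring(src, st + 1L, st + w))
        }
        # background reads from the non-locus genome
        len_w <- setNames(c(2, 3, 5, 6, 8, 10, 30, 9, 6, 4, 3, 2, 2), 18:30)
        mask <- sim$truth$loci[, c("chrom", "pre_start", "pre_end")]
        n_bg <- config$depth_per_lib
        bg <- character(0)
        while (length(bg) < n_bg) {
          k <- n_bg - length(bg)
          cn <- sample(names(genome), k, replace = TRUE)
          w <- as.integer(sample(names(len_w), k, replace = TRUE,
                                 prob = len_w))
          st <- floor(runif(k, 0, nchar(genome[cn]) - w))
          strand <- sample(c("+", "-"), k, replace = TRUE)
          keep <- vapply(seq_len(k), function(z) {
            !any(mask$chrom == cn[z] & st[z] < mask$pre_end + 50L &
                   st[z] + w[z] > mask$pre_start - 50L)
          }, logical(1))
          bg <- c(bg, vapply(which(keep), function(z) {
            get_read(cn[z], st[z], st[z] + w[z], strand[z])
          }, character(1)))
        }
        seqs <- c(seqs, bg)
        # cleaning exercise: a few polyA tails and length outliers
        n_odd <- max(2L, round(0.005 * config$depth_per_lib))
        odd <- c(paste0(substring(bg[seq_len(n_odd)], 1, 21),
                        strrep("A", 10)),
                 substring(bg[n_odd + seq_len(n_odd)], 1, 16))
        seqs <- c(seqs, odd)
        libs[[lib]] <- data.frame(
          id = sprintf("%s_r%06d", lib, seq_along(seqs)), seq = seqs,
          stringsAsFactors = FALSE)
      })
    }
  }
  libs
}

#' Simulate degradome (PARE) 5'-tag libraries
#'
#' Planted cleavage sites get a dominant tag (the transcript maximum by
#' construction); background tags are sparse single reads.
#'
#' @param sim output of [make_genome()].
#' @param config simulation config.
#' @return named list (one element per tissue) of data.frames `id`, `seq`.
#' @export
simulate_degradome_reads <- function(sim, config = sim$config) {
  sites <- sim$truth$target_sites
  tx <- sim$transcripts
  libs <- list()
  tag_len <- 20L
  for (tissue in config$tissues) {
    with_seed(stable_seed(config$seed, paste0("pare/", tissue)), {
      seqs <- character(0)
      for (p in seq_len(nrow(sites))) {
        s <- tx[[sites$transcript_id[p]]]
        cut <- sites$cleavage_pos[p]
        n <- 8L + .rnb(1, 12, config$nb_dispersion)
        seqs <- c(seqs, rep(substring(s, cut + 1L, cut + tag_len), n))
      }
      for (tid in names(tx)) {
        s <- tx[[tid]]
        pos <- sample(nchar(s) - tag_len, 3)
        seqs <- c(seqs, vapply(pos, function(z) {
          substring(s, z + 1L, z + tag_len)
        }, character(1)))
      }
      libs[[tissue]] <- data.frame(
        id = sprintf("%s_t%06d", tissue, seq_along(seqs)), seq = seqs,
        stringsAsFactors = FALSE)
    })
  }
  libs
}

#' Simulate direct expression matrices
#'
#' Produces a miRNA RPM matrix (7 tissues x `srna_reps`) whose rows follow
#' the planted pattern classes, and a transcript FPKM matrix (7 x
#' `mrna_reps`) with planted co-expression blocks (block 1 panicle-high)
#' and miRNA-repressed targets: the expected target level is
#' `base * (1 - repression_strength * m)` with `m` the miRNA tissue mean
#' normalized to its maximum.
#'
#' @param sim output of [make_genome()].
#' @param config simulation config.
#' @return list with `mirna_rpm`, `fpkm`, `mirna_tissue_of`,
#'   `fpkm_tissue_of`.
#' @export
simulate_expression_matrices <- function(sim, config = sim$config) {
  with_seed(stable_seed(config$seed, "expr"), {
    tissues <- config$tissues
    pat <- sim$truth$patterns
    n_mi <- nrow(pat)
    class_mu <- function(row) {
      vapply(tissues, function(ts) {
        switch(row$class,
               housekeeping = 300,
               tissue_specific = if (ts == row$peak_tissue) 500 else 20,
               intermediate = if (ts %in% c(row$int_hi1, row$int_hi2)) 200
                              else 20,
               low = 3)
      }, numeric(1))
    }
    mi_mean <- t(vapply(seq_len(n_mi), function(i) {
      class_mu(as.list(pat[i, ])) * exp(rnorm(7, 0, 0.25))
    }, numeric(7)))
    rownames(mi_mean) <- pat$mirna_id
    mi_samples <- as.vector(outer(tissues, seq_len(config$srna_reps),
                                  function(t, r) sprintf("%s_r%d", t, r)))
    mi_tissue_of <- sub("_r\\d+$", "", mi_samples)
    mirna_rpm <- matrix(0, n_mi, length(mi_samples),
                        dimnames = list(pat$mirna_id, mi_samples))
    for (j in seq_along(mi_samples)) {
      mu <- mi_mean[, mi_tissue_of[j]]
      mirna_rpm[, j] <- mu * exp(rnorm(n_mi, 0, 0.2))
    }

    tx_ids <- sim$truth$modules$transcript_id
    n_tx <- length(tx_ids)
    tx_samples <- as.vector(outer(tissues, seq_len(config$mrna_reps),
                                  function(t, r) sprintf("%s_m%d", t, r)))
    tx_tissue_of <- sub("_m\\d+$", "", tx_samples)
    block_profile <- rbind(
      c(20, 20, 20, 20, 20, 20, 200),       # panicle-high
      c(180, 20, 20, 180, 20, 20, 20),      # root-high
      c(20, 20, 180, 20, 20, 180, 20),      # leaf-high
      c(20, 180, 20, 20, 180, 20, 20))      # stem-high (extra blocks cycle)
    tx_mean <- matrix(0, n_tx, 7, dimnames = list(tx_ids, tissues))
    blocks <- sim$truth$modules$block
    pairs <- sim$truth$pairs
    for (i in seq_len(n_tx)) {
      b <- blocks[i]
      if (b != "none") {
        bi <- as.integer(sub("block", "", b))
        prof <- block_profile[((bi - 1) %% nrow(block_profile)) + 1, ]
        tx_mean[i, ] <- prof * rlnorm(1, 0, 0.3)
      } else if (tx_ids[i] %in% pairs$transcript_id) {
        mid <- pairs$mirna_id[match(tx_ids[i], pairs$transcript_id)]
        m_norm <- mi_mean[mid, ] / max(mi_mean[mid, ])
        tx_mean[i, ] <- 80 * (1 - config$repression_strength * m_norm) *
          exp(rnorm(7, 0, 0.1))
      } else {
        tx_mean[i, ] <- 40 * exp(rnorm(7, 0, 0.8))
      }
    }
    fpkm <- matrix(0, n_tx, length(tx_samples),
                   dimnames = list(tx_ids, tx_samples))
    for (j in seq_along(tx_samples)) {
      fpkm[, j] <- tx_mean[, tx_tissue_of[j]] * exp(rnorm(n_tx, 0, 0.2))
    }
    list(mirna_rpm = mirna_rpm, fpkm = fpkm,
         mirna_tissue_of = mi_tissue_of, fpkm_tissue_of = tx_tissue_of)
  })
}

#' Generate and write the complete synthetic dataset
#'
#' @param config configuration from [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, the in-memory `sim` object with an added `paths`
#'   element.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  sim <- make_genome(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$genome <- file.path(out_dir, "genome.fa")
  write_fasta(sim$genome, p$genome)
  p$gff <- file.path(out_dir, "genes.gff3")
  write_gff3(sim$features, p$gff)
  p$transcripts <- file.path(out_dir, "transcripts.fa")
  write_fasta(sim$transcripts, p$transcripts)
  p$ncrna <- file.path(out_dir, "ncrna.fa")
  write_fasta(sim$ncrna, p$ncrna)
  p$catalogue <- file.path(out_dir, "mirna_catalogue.fa")
  cat_seqs <- setNames(chartr("T", "U", sim$catalogue$seq),
                       sprintf("%s species=%s lineage=%s family=%s",
                               sim$catalogue$name, sim$catalogue$species,
                               sim$catalogue$lineage, sim$catalogue$family))
  write_fasta(cat_seqs, p$catalogue)
  p$blocks <- file.path(out_dir, "synteny_blocks.tsv")
  write_tsv(sim$blocks, p$blocks)
  p$pwms <- file.path(out_dir, "motifs.jaspar")
  pw_lines <- unlist(lapply(sim$pwms, function(pw) {
    c(sprintf(">%s %s", pw$motif_id, pw$tf_family),
      vapply(DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(pw$mat[b, ] * 100, trim = TRUE),
                      collapse = " "))
      }, character(1)))
  }))
  writeLines(pw_lines, p$pwms)
  p$tf_map <- file.path(out_dir, "tf_map.tsv")
  write_tsv(sim$tf_map, p$tf_map)
  p$tf_genes <- file.path(out_dir, "tf_genes.tsv")
  write_tsv(sim$tf_genes, p$tf_genes)

  srna <- simulate_srna_reads(sim, config)
  p$srna <- character(0)
  for (lib in names(srna)) {
    f <- file.path(out_dir, "srna", paste0(lib, ".fastq"))
    write_fastq(srna[[lib]]$id, srna[[lib]]$seq, f)
    p$srna <- c(p$srna, f)
  }
  pare <- simulate_degradome_reads(sim, config)
  p$pare <- character(0)
  for (tissue in names(pare)) {
    f <- file.path(out_dir, "pare", paste0(tissue, ".fa"))
    write_fasta(setNames(pare[[tissue]]$seq, pare[[tissue]]$id), f)
    p$pare <- c(p$pare, f)
  }
  expr <- simulate_expression_matrices(sim, config)
  p$mirna_rpm <- file.path(out_dir, "expr", "mirna_rpm.tsv")
  write_tsv(data.frame(mirna_id = rownames(expr$mirna_rpm),
                       expr$mirna_rpm, check.names = FALSE), p$mirna_rpm)
  p$fpkm <- file.path(out_dir, "expr", "transcript_fpkm.tsv")
  write_tsv(data.frame(transcript_id = rownames(expr$fpkm), expr$fpkm,
                       check.names = FALSE), p$fpkm)

  for (tname in names(sim$truth)) {
    f <- file.path(out_dir, "truth", paste0(tname, ".tsv"))
    write_tsv(sim$truth[[tname]], f)
    p[[paste0("truth_", tname)]] <- f
  }
  sim$expr <- expr
  sim$reads <- list(srna = srna, pare = pare)
  sim$paths <- p
  invisible(sim)
}
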