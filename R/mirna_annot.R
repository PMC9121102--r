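# Criteria-based annotation of miRNA hairpin loci.
#
# Candidate windows are read stacks extended by flanking sequence. Within a
# window the mature candidate is the most abundant 19-25 nt read; the star
# arm is located by a complementarity scan (the duplex partner must sit
# within the maximum precursor span), the duplex-anchored precursor
# subsequence is folded, and the miRNA* is the duplex partner implied by
# the structure with 2-nt 3' overhangs. A locus passes when all criteria
# hold: <= 5 duplex mismatches, <= 3-nt asymmetric bulge, precursor <= 300
# nt, mature length 19-25 nt (20-24 flagged high-confidence), star reads
# at the expected coordinates (+/- 1 nt), and read precision >= 0.75.
# Rejections are logged with the first failing criterion.
#
# Folding the duplex-anchored precursor rather than the full flanked window
# keeps the maximum-pairing folder's degenerate optima from scattering the
# mature arm's partners across flanking sequence; the star call remains
# structure-derived.

#' Default annotation criteria
#'
#' All thresholds of the plant miRNA annotation checklist, overridable.
#'
#' @param max_duplex_mismatches maximum mature/star duplex mismatches.
#' @param max_asym_bulge maximum asymmetric bulge, nt.
#' @param max_precursor maximum precursor length, nt.
#' @param mature_len_range allowed mature length range (inclusive).
#' @param confident_len_range length range flagged "high-confidence".
#' @param min_precision minimum fraction of locus reads from mature + star.
#' @param min_star_reads minimum star read count at +/- `star_tolerance` nt.
#' @param star_tolerance coordinate tolerance for star read evidence, nt.
#' @param flank flanking sequence added on each side of a read stack.
#' @param min_stack_count minimum summed read count for a stack to become a
#'   candidate.
#' @param min_scan_matches minimum complementary positions for a candidate
#'   star arm in the duplex scan.
#' @param pad extra nucleotides folded on each side of the duplex span.
#' @return list of settings.
#' @export
annot_config <- function(max_duplex_mismatches = 5L, max_asym_bulge = 3L,
                         max_precursor = 300L,
                         mature_len_range = c(19L, 25L),
                         confident_len_range = c(20L, 24L),
                         min_precision = 0.75, min_star_reads = 1L,
                         star_tolerance = 1L, flank = 250L,
                         min_stack_count = 10L, min_scan_matches = 11L,
                         pad = 10L) {
  as.list(environment())
}

# map genomic alignments into oriented window coordinates
.window_reads <- function(alignments, chrom, strand, win_start, win_end) {
  sel <- alignments$chrom == chrom & alignments$strand == strand &
    alignments$start >= win_start & alignments$end <= win_end
  sub <- alignments[sel, , drop = FALSE]
  if (!nrow(sub)) return(sub)
  if (strand == "+") {
    sub$wstart <- sub$start - win_start
    sub$wend <- sub$end - win_start
  } else {
    sub$wstart <- win_end - sub$end
    sub$wend <- win_end - sub$start
  }
  sub
}

#' Extract candidate precursor windows from read stacks
#'
#' Overlapping same-strand alignments are chained into stacks; stacks with
#' a summed read count of at least `min_stack_count` yield one window each,
#' the stack interval extended by `flank` nt on both sides and clipped at
#' chromosome ends. Window sequences are reported 5' to 3' (minus-strand
#' windows reverse-complemented).
#'
#' @param alignments mapped prediction-set reads ([map_reads()] output with
#'   count columns).
#' @param genome named character vector of chromosomes.
#' @param config settings from [annot_config()].
#' @return data.frame with `chrom`, `strand`, `win_start`, `win_end`
#'   (genomic, 0-based half-open), `stack_start`, `stack_end`,
#'   `stack_count`, `seq` (oriented).
#' @export
extract_candidate_precursors <- function(alignments, genome,
                                         config = annot_config()) {
  count_cols <- setdiff(names(alignments),
                        c("seq", "chrom", "start", "end", "strand",
                          "mismatches", "wstart", "wend"))
  total <- rowSums(alignments[, count_cols, drop = FALSE])
  rows <- list()
  for (chrom in unique(alignments$chrom)) {
    clen <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      sel <- which(alignments$chrom == chrom & alignments$strand == strand)
      if (!length(sel)) next
      sel <- sel[order(alignments$start[sel])]
      st <- alignments$start[sel]
      en <- alignments$end[sel]
      grp <- cumsum(c(1L, as.integer(st[-1] >= cummax(en)[-length(en)])))
      for (g in split(seq_along(sel), grp)) {
        cnt <- sum(total[sel[g]])
        if (cnt < config$min_stack_count) next
        s0 <- min(st[g]); e0 <- max(en[g])
        ws <- max(0L, s0 - config$flank)
        we <- min(clen, e0 + config$flank)
        sq <- substring(genome[[chrom]], ws + 1L, we)
        if (strand == "-") sq <- revcomp(sq)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, win_start = ws, win_end = we,
          stack_start = s0, stack_end = e0, stack_count = cnt, seq = sq,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      win_start = integer(0), win_end = integer(0),
                      stack_start = integer(0), stack_end = integer(0),
                      stack_count = numeric(0), seq = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# complementarity scan for the star arm; returns up to `k_best` candidate
# 0-based window offsets ordered by (match count desc, precursor span asc),
# or an empty vector. mature occupies [ms, me) in window coordinates.
# Watson-Crick complementarity only: the planted duplex is exact while
# chance complementarity (inflated by G:U wobble) stays low.
.scan_star <- function(wseq, ms, me, config, k_best = 6L) {
  m <- me - ms
  n <- nchar(wseq)
  code <- match(strsplit(wseq, "", fixed = TRUE)[[1]], DNA_BASES)
  mi <- code[(ms + 1L):me]
  lim <- config$max_precursor
  cand <- 0:(n - m)
  span_lo <- pmin(cand, ms)
  span_hi <- pmax(cand + m, me)
  ok <- (span_hi - span_lo) <= lim &
    (cand + m <= ms | cand >= me)          # no overlap with the mature
  cand <- cand[ok]
  if (!length(cand)) return(integer(0))
  # star index k (1-based) pairs mature index m-1-k (1-based), k = 1..m-2
  k <- 1:(m - 2L)
  wc <- (.pairable_matrix & !.wobble_matrix)
  sc <- vapply(cand, function(o) {
    sum(wc[cbind(code[o + k], mi[m - 1L - k])])
  }, numeric(1))
  keep <- sc >= config$min_scan_matches
  if (!any(keep)) return(integer(0))
  cand <- cand[keep]; sc <- sc[keep]
  span <- pmax(cand + m, me) - pmin(cand, ms)
  ord <- order(-sc, span, cand)
  picked <- integer(0)
  for (o in cand[ord]) {
    if (length(picked) >= k_best) break
    if (all(abs(picked - o) >= m)) picked <- c(picked, o)
  }
  picked
}

#' Evaluate the annotation criteria on one candidate window
#'
#' @param window one row of [extract_candidate_precursors()] output (as a
#'   list or single-row data.frame).
#' @param alignments mapped prediction-set reads with count columns.
#' @param config settings from [annot_config()].
#' @param precomputed optional dot-bracket structure for the folded
#'   precursor subsequence (backend override).
#' @return list with `pass`, `first_fail` (NA when passing), `report`
#'   (criterion values), and on success `locus` (a one-row data.frame).
#' @export
evaluate_criteria <- function(window, alignments, config = annot_config(),
                              precomputed = NULL) {
  fail <- function(which, report = NULL) {
    list(pass = FALSE, first_fail = which, report = report, locus = NULL)
  }
  reads <- .window_reads(alignments, window$chrom, window$strand,
                         window$win_start, window$win_end)
  if (!nrow(reads)) return(fail("no_reads"))
  count_cols <- setdiff(names(reads),
                        c("seq", "chrom", "start", "end", "strand",
                          "mismatches", "wstart", "wend"))
  reads$total <- rowSums(reads[, count_cols, drop = FALSE])
  lens <- reads$wend - reads$wstart
  pred <- reads[lens >= config$mature_len_range[1] &
                  lens <= config$mature_len_range[2], , drop = FALSE]
  if (!nrow(pred)) return(fail("no_reads"))
  top <- pred[order(-pred$total, pred$wstart), ][1, ]
  ms <- top$wstart; me <- top$wend
  m <- me - ms
  wseq <- window$seq

  cands <- .scan_star(wseq, ms, me, config)
  if (!length(cands)) return(fail("star_reads"))
  # candidates whose arm has read support are tried first: the
  # read-supported duplex is the biologically meaningful one
  support <- vapply(cands, function(o) {
    any(abs(pred$wstart - o) <= 1L & abs(pred$wend - (o + m)) <= 1L)
  }, logical(1))
  cands <- c(cands[support], cands[!support])

  evaluate_candidate <- function(star_o) {
    pre_lo <- max(0L, min(ms, star_o) - config$pad)
    pre_hi <- min(nchar(wseq), max(me, star_o + m) + config$pad)
    pre_seq <- substring(wseq, pre_lo + 1L, pre_hi)
    fd <- fold(pre_seq, precomputed = precomputed)
    pt <- fd$ptable

    # partners of the mature positions, in precursor coordinates
    # (1-based); the star arm lies entirely on one side of the mature, so
    # partners on the minority side (stray pairings into flanking sequence
    # or the mature itself) are treated as unpaired
    mat_idx <- (ms - pre_lo + 1L):(me - pre_lo)
    partners <- pt[mat_idx]
    up <- partners > (me - pre_lo)
    dn <- partners > 0L & partners < (ms - pre_lo + 1L)
    keep_side <- if (sum(up) >= sum(dn)) up else dn
    partners[!keep_side] <- 0L
    paired <- which(partners > 0L)
    if (length(paired) < 6L) return(fail("star_reads"))

    # star arm implied by the structure with 2-nt 3' overhangs: the
    # antiparallel duplex has a constant frame i + partner(i); the modal
    # frame pins the star even when single pairings wobble-shift
    frames <- mat_idx[paired] + partners[paired]
    tab <- table(frames)
    f_star <- as.integer(names(tab)[which.max(tab)])
    a <- ms - pre_lo + 1L                 # first mature position
    b <- me - pre_lo                      # last mature position
    p_lo <- f_star - (b - 2L)
    p_hi <- f_star - a
    star_lo_w <- max(0L, pre_lo + p_lo - 1L)
    star_hi_w <- min(nchar(wseq), pre_lo + p_hi + 2L)

    # duplex statistics over the mature arm minus its own 2-nt 3' overhang.
    # Mismatches are duplex positions not paired on the modal frame: a
    # maximum-pairing folder can trade facing mismatches for off-frame
    # pairs plus compensating loops, but off-frame pairs are not duplex
    # pairs. Bulges come from the asymmetry of consecutive partner gaps.
    dup_idx <- seq_len(max(0L, m - 2L))
    dpair <- partners[dup_idx]
    # pairs within 2 nt of the modal frame are duplex pairs (wobble pairs
    # jitter the frame by a step or two); pairs further off-frame belong
    # to an alternative helix, not the mature:star duplex
    on_frame <- dpair > 0L & abs(mat_idx[dup_idx] + dpair - f_star) <= 3L
    mism <- length(dup_idx) - sum(on_frame)
    max_bulge <- 0L
    dp_on <- which(dpair > 0L)
    if (length(dp_on) >= 2L) {
      for (z in seq_len(length(dp_on) - 1L)) {
        gm <- dp_on[z + 1L] - dp_on[z] - 1L
        gs <- abs(dpair[dp_on[z]] - dpair[dp_on[z + 1L]]) - 1L
        max_bulge <- max(max_bulge, abs(gm - gs))
      }
    }

    pre_start_w <- min(ms, star_lo_w)
    pre_end_w <- max(me, star_hi_w)
    precursor_len <- pre_end_w - pre_start_w

    # star read evidence: reads whose ends both fall within the tolerance
    tol <- config$star_tolerance
    star_reads <- sum(pred$total[abs(pred$wstart - star_lo_w) <= tol &
                                   abs(pred$wend - star_hi_w) <= tol])

    # precision: locus reads from mature or star (+/- 2 nt) over all reads
    # overlapping the precursor
    loc <- reads[reads$wend > pre_start_w & reads$wstart < pre_end_w, ,
                 drop = FALSE]
    near <- function(a2, b2, x, y) abs(a2 - x) <= 2L & abs(b2 - y) <= 2L
    good <- near(loc$wstart, loc$wend, ms, me) |
      near(loc$wstart, loc$wend, star_lo_w, star_hi_w)
    precision <- sum(loc$total[good]) / sum(loc$total)

    report <- list(
      duplex_mismatches = mism, max_asym_bulge = max_bulge,
      precursor_len = precursor_len, mature_len = m,
      high_confidence_length = m >= config$confident_len_range[1] &
        m <= config$confident_len_range[2],
      star_read_count = star_reads, precision = precision,
      overhang_3p = c(mature = 2L, star = 2L))
    checks <- c(
      duplex_mismatches = mism <= config$max_duplex_mismatches,
      asym_bulge = max_bulge <= config$max_asym_bulge,
      precursor_len = precursor_len <= config$max_precursor,
      mature_len = m >= config$mature_len_range[1] &
        m <= config$mature_len_range[2],
      star_reads = star_reads >= config$min_star_reads,
      precision = precision >= config$min_precision)
    report$pass <- checks
    report$overall_pass <- all(checks)
    if (!report$overall_pass) {
      return(fail(names(checks)[!checks][1], report))
    }

    to_genomic <- function(lo, hi) {
      if (window$strand == "+") {
        c(window$win_start + lo, window$win_start + hi)
      } else {
        c(window$win_end - hi, window$win_end - lo)
      }
    }
    g_pre <- to_genomic(pre_start_w, pre_end_w)
    g_mat <- to_genomic(ms, me)
    g_star <- to_genomic(star_lo_w, star_hi_w)
    structure_sub <- substring(fd$structure, pre_start_w - pre_lo + 1L,
                               pre_end_w - pre_lo)
    locus <- data.frame(
      chrom = window$chrom, strand = window$strand,
      pre_start = g_pre[1], pre_end = g_pre[2],
      mature_start = g_mat[1], mature_end = g_mat[2],
      star_start = g_star[1], star_end = g_star[2],
      mature_seq = top$seq,
      star_seq = substring(wseq, star_lo_w + 1L, star_hi_w),
      structure = structure_sub,
      duplex_mismatches = mism, max_asym_bulge = max_bulge,
      precursor_len = precursor_len, star_read_count = star_reads,
      precision = precision, stringsAsFactors = FALSE)
    list(pass = TRUE, first_fail = NA_character_, report = report,
         locus = locus)
  }

  # Accept the first passing candidate; otherwise prefer the first whose
  # implied star arm has read support; otherwise report the best-scoring
  # candidate's failure.
  results <- vector("list", length(cands))
  for (ci in seq_along(cands)) {
    results[[ci]] <- evaluate_candidate(cands[ci])
    if (results[[ci]]$pass) return(results[[ci]])
    if (!is.null(results[[ci]]$report) &&
        results[[ci]]$report$star_read_count >= 1) {
      return(results[[ci]])
    }
  }
  results[[1]]
}

#' Annotate miRNA loci from mapped reads
#'
#' Runs the full criteria pipeline: candidate windows, per-window
#' evaluation, deduplication of windows converging on one mature, then
#' conservation classification, family assignment and id minting.
#'
#' @param alignments mapped prediction-set reads with count columns.
#' @param genome named character vector of chromosomes.
#' @param catalogue optional reference catalogue
#'   (see [read_mirna_catalogue()]); when NULL, conservation is skipped and
#'   all loci become species-specific novel families.
#' @param config settings from [annot_config()].
#' @param id_prefix species prefix for locus ids.
#' @return list with `loci` (annotated locus table) and `rejected`
#'   (data.frame of window coordinates and first failing criterion).
#' @export
annotate_mirnas <- function(alignments, genome, catalogue = NULL,
                            config = annot_config(), id_prefix = "syn") {
  wins <- extract_candidate_precursors(alignments, genome, config)
  loci <- list()
  rejected <- list()
  for (i in seq_len(nrow(wins))) {
    res <- evaluate_criteria(wins[i, ], alignments, config)
    if (res$pass) {
      loci[[length(loci) + 1L]] <- res$locus
    } else {
      rejected[[length(rejected) + 1L]] <- data.frame(
        chrom = wins$chrom[i], strand = wins$strand[i],
        stack_start = wins$stack_start[i], stack_end = wins$stack_end[i],
        first_fail = res$first_fail, stringsAsFactors = FALSE)
    }
  }
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(chrom = character(0), strand = character(0),
               stack_start = integer(0), stack_end = integer(0),
               first_fail = character(0))
  if (!length(loci)) {
    return(list(loci = data.frame(), rejected = rejected))
  }
  loci <- do.call(rbind, loci)
  key <- paste(loci$chrom, loci$strand, loci$mature_start, loci$mature_end)
  loci <- loci[!duplicated(key), , drop = FALSE]
  loci <- loci[order(loci$chrom, loci$pre_start), , drop = FALSE]
  rownames(loci) <- NULL

  if (!is.null(catalogue)) {
    cls <- classify_conservation(loci$mature_seq, catalogue)
    loci$conservation_class <- cls$class
    loci$best_hit <- cls$best_hit
    loci$best_family <- cls$best_family
  } else {
    loci$conservation_class <- "species_specific"
    loci$best_hit <- NA_character_
  }
  loci <- assign_family(loci, catalogue)
  loci$locus_id <- .mint_ids(loci, id_prefix)
  list(loci = loci, rejected = rejected)
}

# per-family letter suffixes in genomic order
.mint_ids <- function(loci, id_prefix) {
  ids <- character(nrow(loci))
  for (fam in unique(loci$family)) {
    idx <- which(loci$family == fam)
    idx <- idx[order(loci$chrom[idx], loci$pre_start[idx])]
    suffix <- if (length(idx) == 1L) "" else letters[seq_along(idx)]
    ids[idx] <- paste0(id_prefix, "-", fam, suffix)
  }
  ids
}

# ungapped match with <= max_shift terminal shift and <= max_mm mismatches
.mature_match <- function(query, ref, max_mm = 2L, max_shift = 2L) {
  nq <- nchar(query); nr <- nchar(ref)
  q <- utf8ToInt(query); r <- utf8ToInt(ref)
  for (d in -max_shift:max_shift) {
    # query position i aligns ref position i + d
    i_lo <- max(1L, 1L - d)
    i_hi <- min(nq, nr - d)
    if (i_hi - i_lo + 1L < max(nq, nr) - max_shift) next
    mm <- sum(q[i_lo:i_hi] != r[(i_lo + d):(i_hi + d)])
    if (mm <= max_mm) return(mm)
  }
  NA_integer_
}

#' Read a reference mature-miRNA catalogue
#'
#' FASTA headers carry `species=`, `lineage=` (Poaceae or non-Poaceae) and
#' `family=` attributes.
#'
#' @param path catalogue FASTA.
#' @return data.frame with `name`, `seq`, `species`, `lineage`, `family`.
#' @export
read_mirna_catalogue <- function(path) {
  seqs <- read_fasta(path)
  hdr <- read_fasta_headers(path)
  field <- function(key) {
    out <- sub(paste0(".*", key, "=(\\S+).*"), "\\1", hdr$desc)
    out[!grepl(paste0(key, "="), hdr$desc)] <- NA_character_
    out
  }
  data.frame(name = hdr$name, seq = unname(seqs), species = field("species"),
             lineage = field("lineage"), family = field("family"),
             stringsAsFactors = FALSE)
}

#' Classify conservation of mature sequences against a catalogue
#'
#' A hit allows up to `max_mm` mismatches and up to `max_shift` nt of
#' terminal shift. Any hit in a non-Poaceae species makes the miRNA
#' conserved; hits confined to Poaceae make it Poaceae-specific; no hit
#' makes it species-specific.
#'
#' @param mature_seqs character vector of mature sequences.
#' @param catalogue data.frame from [read_mirna_catalogue()].
#' @param max_mm mismatch allowance (default 2).
#' @param max_shift terminal shift allowance (default 2).
#' @return data.frame with `class`, `best_hit`, `best_family`.
#' @export
classify_conservation <- function(mature_seqs, catalogue, max_mm = 2L,
                                  max_shift = 2L) {
  if (any(is.na(catalogue$lineage))) {
    stop("catalogue entries lack lineage tags", call. = FALSE)
  }
  out <- data.frame(class = character(length(mature_seqs)),
                    best_hit = NA_character_,
                    best_family = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(mature_seqs)) {
    mm <- vapply(catalogue$seq, .mature_match, integer(1),
                 query = mature_seqs[i], max_mm = max_mm,
                 max_shift = max_shift, USE.NAMES = FALSE)
    hit <- which(!is.na(mm))
    if (!length(hit)) {
      out$class[i] <- "species_specific"
      next
    }
    best <- hit[order(mm[hit])][1]
    out$best_hit[i] <- catalogue$name[best]
    out$best_family[i] <- catalogue$family[best]
    out$class[i] <- if (any(catalogue$lineage[hit] != "Poaceae")) {
      "conserved"
    } else {
      "poaceae_specific"
    }
  }
  out
}

#' Assign miRNA families
#'
#' Catalogue hits inherit the reference family; unmatched loci are grouped
#' by single-linkage clustering at `max_mm` mismatches among themselves and
#' numbered `miRN0001`, ... in genomic order.
#'
#' @param loci locus table with `mature_seq`, `chrom`, `pre_start`, and
#'   `best_hit`/`best_family` columns when a catalogue was used.
#' @param catalogue catalogue data.frame or NULL.
#' @param max_mm mismatch allowance for novel-family grouping.
#' @return `loci` with a `family` column added.
#' @export
assign_family <- function(loci, catalogue = NULL, max_mm = 2L) {
  n <- nrow(loci)
  fam <- rep(NA_character_, n)
  if (!is.null(catalogue) && "best_family" %in% names(loci)) {
    fam <- loci$best_family
  }
  novel <- which(is.na(fam))
  if (length(novel)) {
    # single-linkage transitive closure on <= max_mm matches
    comp <- seq_along(novel)
    for (a in seq_along(novel)) {
      for (b in seq_len(a - 1L)) {
        if (!is.na(.mature_match(loci$mature_seq[novel[a]],
                                 loci$mature_seq[novel[b]],
                                 max_mm = max_mm))) {
          old <- comp[b]; new <- comp[a]
          comp[comp == old] <- new
        }
      }
    }
    ord <- order(loci$chrom[novel], loci$pre_start[novel])
    seen <- character(0)
    for (k in ord) {
      cid <- as.character(comp[k])
      if (!cid %in% seen) seen <- c(seen, cid)
    }
    lab <- setNames(sprintf("miRN%04d", seq_along(seen)), seen)
    fam[novel] <- lab[as.character(comp)]
  }
  loci$family <- fam
  loci
}

#' Detect genomic miRNA clusters
#'
#' Loci on one chromosome are chained while the start-to-start distance of
#' consecutive loci is strictly below `max_gap`; chains with at least two
#' members are clusters.
#'
#' @param loci locus table with `locus_id`, `chrom`, `pre_start`.
#' @param max_gap distance threshold in bp (strict `<`).
#' @return data.frame with `cluster_id`, `chrom`, `members`
#'   (comma-joined locus ids), `n`.
#' @export
detect_clusters <- function(loci, max_gap = 10000L) {
  rows <- list()
  for (chrom in sort(unique(loci$chrom))) {
    sub <- loci[loci$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$pre_start), , drop = FALSE]
    if (nrow(sub) < 2L) next
    gaps <- diff(sub$pre_start)
    grp <- cumsum(c(1L, as.integer(gaps >= max_gap)))
    for (g in split(seq_len(nrow(sub)), grp)) {
      if (length(g) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        members = paste(sub$locus_id[g], collapse = ","),
        n = length(g), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      members = character(0), n = integer(0)))
  }
  out <- do.call(rbind, rows)
  out$cluster_id <- sprintf("cluster%02d", seq_len(nrow(out)))
  out[, c("cluster_id", "chrom", "members", "n")]
}

#' Anchor miRNA loci into synteny blocks
#'
#' A locus anchors to a block side when its precursor overlaps the side by
#' at least 1 bp; two same-family loci anchored to the two sides of one
#' block pair are a syntenic pair.
#'
#' @param loci locus table with `locus_id`, `family`, `chrom`, `pre_start`,
#'   `pre_end`.
#' @param blocks data.frame with `block_id`, `a_chrom`, `a_start`, `a_end`,
#'   `b_chrom`, `b_start`, `b_end` (0-based half-open).
#' @return data.frame with `locus_id`, `block_id`, `side`,
#'   `partner_locus_id`, `syntenic_pair`.
#' @export
anchor_synteny <- function(loci, blocks) {
  need <- c("block_id", "a_chrom", "a_start", "a_end",
            "b_chrom", "b_start", "b_end")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) {
    stop(sprintf("malformed block table: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  overlaps <- function(chrom, s, e, bc, bs, be) {
    chrom == bc & s < be & e > bs
  }
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    for (side in c("a", "b")) {
      bc <- blocks[[paste0(side, "_chrom")]][b]
      bs <- blocks[[paste0(side, "_start")]][b]
      be <- blocks[[paste0(side, "_end")]][b]
      hit <- which(overlaps(loci$chrom, loci$pre_start, loci$pre_end,
                            bc, bs, be))
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = loci$locus_id[h], family = loci$family[h],
          block_id = blocks$block_id[b], side = side,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(locus_id = character(0), block_id = character(0),
                      side = character(0), partner_locus_id = character(0),
                      syntenic_pair = logical(0)))
  }
  anch <- do.call(rbind, rows)
  anch$partner_locus_id <- NA_character_
  anch$syntenic_pair <- FALSE
  for (b in unique(anch$block_id)) {
    a_side <- anch[anch$block_id == b & anch$side == "a", ]
    b_side <- anch[anch$block_id == b & anch$side == "b", ]
    for (fam in intersect(a_side$family, b_side$family)) {
      ai <- which(anch$block_id == b & anch$side == "a" &
                    anch$family == fam)
      bi <- which(anch$block_id == b & anch$side == "b" &
                    anch$family == fam)
      anch$syntenic_pair[c(ai, bi)] <- TRUE
      anch$partner_locus_id[ai] <- anch$locus_id[bi[1]]
      anch$partner_locus_id[bi] <- anch$locus_id[ai[1]]
    }
  }
  anch[, c("locus_id", "family", "block_id", "side", "partner_locus_id",
           "syntenic_pair")]
}
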