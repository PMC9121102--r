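# Small-RNA read cleaning, filtering, collapsing and genome mapping.
#
# Reads arrive pre-trimmed (adapter removal is a vendor step upstream); the
# cleaning stage removes length outliers and polyA tails, the prediction
# set keeps 19-25 nt reads, reads matching structural ncRNAs (<= 1
# mismatch, either strand, full length, ungapped) are discarded, and the
# remainder is collapsed to unique sequences with per-library counts and
# mapped exactly to the genome (all occurrences, both strands).

#' Clean raw small-RNA reads
#'
#' Trims homopolymer-A tails of at least `polya_min` terminal As, then
#' removes reads outside `[min_len, max_len]`.
#'
#' @param reads data.frame with a `seq` column (one row per read) or a
#'   character vector.
#' @param min_len,max_len retained length bounds (inclusive).
#' @param polya_min minimum terminal-A run length that counts as a polyA
#'   tail.
#' @return object of the same shape restricted to clean reads, with tails
#'   trimmed.
#' @export
clean_reads <- function(reads, min_len = 18L, max_len = 30L,
                        polya_min = 8L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (!length(seqs)) {
    warning("empty library")
    return(reads)
  }
  seqs <- sub(sprintf("A{%d,}$", polya_min), "", toupper(seqs))
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  if (is.data.frame(reads)) {
    out <- reads[keep, , drop = FALSE]
    out$seq <- seqs[keep]
    rownames(out) <- NULL
    out
  } else {
    seqs[keep]
  }
}

#' Restrict clean reads to the miRNA prediction length range
#'
#' @param reads data.frame with `seq` or character vector.
#' @param min_len,max_len prediction length bounds (default 19-25 nt).
#' @return reads within the bounds; warns when nothing survives.
#' @export
select_prediction_set <- function(reads, min_len = 19L, max_len = 25L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  if (length(seqs) && !any(keep)) warning("no reads in the prediction range")
  if (is.data.frame(reads)) {
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    seqs[keep]
  }
}

.match_any_ncrna <- function(seqs, ncrna, max_mm) {
  # which of `seqs` occur (full-length, ungapped, either strand) in any
  # ncRNA sequence with at most max_mm mismatches. For max_mm <= 1 the
  # 1-mismatch neighborhood of every ncRNA window is hashed once, turning
  # the filter into set membership; larger allowances fall back to
  # pattern counting.
  hit <- logical(length(seqs))
  subjects <- c(ncrna, revcomp(ncrna))
  if (max_mm <= 1L) {
    for (w in unique(nchar(seqs))) {
      idx <- which(nchar(seqs) == w)
      wins <- unlist(lapply(subjects, function(s) {
        n <- nchar(s)
        if (n < w) return(character(0))
        substring(s, 1:(n - w + 1L), w:n)
      }), use.names = FALSE)
      wins <- unique(wins)
      if (!length(wins)) next
      tab <- wins
      if (max_mm == 1L) {
        var_list <- vector("list", w)
        for (p in seq_len(w)) {
          pre <- substring(wins, 1L, p - 1L)
          suf <- substring(wins, p + 1L, w)
          var_list[[p]] <- paste0(rep(pre, each = 4L), DNA_BASES,
                                  rep(suf, each = 4L))
        }
        tab <- unique(c(wins, unlist(var_list, use.names = FALSE)))
      }
      hit[idx] <- seqs[idx] %in% tab
    }
    return(hit)
  }
  subj_set <- Biostrings::DNAStringSet(subjects)
  for (i in seq_along(seqs)) {
    for (s in seq_along(subj_set)) {
      if (Biostrings::countPattern(seqs[i], subj_set[[s]],
                                   max.mismatch = max_mm) > 0) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

#' Remove reads matching structural ncRNAs
#'
#' A read is removed when it aligns full-length and ungapped to any ncRNA
#' (either strand) with at most `max_mm` mismatches. Idempotent.
#'
#' @param reads data.frame with `seq` or character vector.
#' @param ncrna named character vector of ncRNA sequences (tRNA, rRNA,
#'   snRNA, snoRNA, ...).
#' @param max_mm mismatch allowance (default 1).
#' @return reads with ncRNA matches removed.
#' @export
filter_ncrna <- function(reads, ncrna, max_mm = 1L) {
  stopifnot(length(ncrna) > 0)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (!length(seqs)) return(reads)
  uniq <- unique(seqs)
  bad <- uniq[.match_any_ncrna(uniq, ncrna, max_mm)]
  keep <- !(seqs %in% bad)
  if (is.data.frame(reads)) {
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    seqs[keep]
  }
}

#' Collapse reads to unique sequences with per-library counts
#'
#' @param libraries named list of read sets (data.frames with `seq` or
#'   character vectors), one per library.
#' @return data.frame with `seq` and one integer count column per library;
#'   column sums equal the input read counts.
#' @export
collapse_unique <- function(libraries) {
  stopifnot(!is.null(names(libraries)))
  seq_of <- function(x) if (is.data.frame(x)) x$seq else x
  all_seqs <- sort(unique(unlist(lapply(libraries, seq_of))))
  out <- data.frame(seq = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(libraries)) {
    tab <- table(seq_of(libraries[[lib]]))
    cnt <- integer(length(all_seqs))
    idx <- match(names(tab), all_seqs)
    cnt[idx] <- as.integer(tab)
    out[[lib]] <- cnt
  }
  out
}

#' Map unique reads to a genome
#'
#' Exact matching (default) of every occurrence on both strands; minus
#' strand alignments are reported on forward-strand coordinates (the
#' genomic interval whose reverse complement equals the read).
#'
#' @param unique_reads data.frame from [collapse_unique()] (`seq` plus
#'   count columns).
#' @param genome named character vector of chromosome sequences.
#' @param max_mm mismatch allowance (0 = exact; the default, as mature
#'   miRNA quantification uses exact reads).
#' @return data.frame with `seq`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`, plus the count columns.
#' @export
map_reads <- function(unique_reads, genome, max_mm = 0L) {
  count_cols <- setdiff(names(unique_reads), "seq")
  seqs <- unique_reads$seq
  too_long <- nchar(seqs) > max(nchar(genome))
  if (any(too_long)) {
    warning(sprintf("%d read(s) longer than any chromosome; skipped",
                    sum(too_long)))
  }
  seqs_use <- which(!too_long)
  subj <- Biostrings::DNAStringSet(genome)
  rows <- list()
  by_len <- split(seqs_use, nchar(seqs[seqs_use]))
  for (grp in by_len) {
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") seqs[grp] else revcomp(seqs[grp])
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
      for (chrom in names(genome)) {
        hits <- Biostrings::matchPDict(pd, subj[[chrom]],
                                       max.mismatch = max_mm)
        starts <- Biostrings::startIndex(hits)
        for (g in seq_along(grp)) {
          st <- starts[[g]]
          if (is.null(st) || !length(st)) next
          w <- nchar(seqs[grp[g]])
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(seq = seqs[grp[g]], chrom = chrom, start = st - 1L,
                       end = st - 1L + w, strand = strand, mismatches = 0L,
                       stringsAsFactors = FALSE),
            unique_reads[grp[g], count_cols, drop = FALSE],
            row.names = NULL)
        }
      }
    }
  }
  if (!length(rows)) {
    empty <- data.frame(seq = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0))
    for (cc in count_cols) empty[[cc]] <- integer(0)
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-length distribution
#'
#' @param seqs character vector of read sequences.
#' @param counts optional weights (e.g. unique-read counts); default 1 per
#'   read.
#' @return list with `hist` (named counts over observed lengths, ascending)
#'   and `mode` (smallest length on ties).
#' @export
length_distribution <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  stopifnot(length(counts) == length(seqs))
  lens <- nchar(seqs)
  hist <- tapply(counts, lens, sum)
  hist <- hist[order(as.integer(names(hist)))]
  mode <- if (length(hist)) {
    as.integer(names(hist)[which.max(hist)])
  } else NA_integer_
  list(hist = hist, mode = mode)
}
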