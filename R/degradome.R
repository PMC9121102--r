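# Degradome (PARE) 5'-tag density profiles and cleavage-category calls.
#
# Category semantics (d = depth at the queried position, M = maximum depth
# over positions with at least one read, med = median over positions with
# at least one read):
#   0: d == M and the maximum is unique
#   1: d == M and the maximum is tied
#   2: med < d < M
#   3: 1 < d <= med
#   4: d == 1
# Only categories 0 and 1 count as cleavage confirmation by default.

#' Build 5'-tag depth profiles from PARE reads
#'
#' Each tag increments the depth at its 5'-end position on every transcript
#' it matches exactly (multi-transcript tags count once per hit).
#' Transcripts without any tag are omitted.
#'
#' @param tags character vector of 5'-tag sequences (one entry per read;
#'   min length 15 nt enforced).
#' @param transcripts named character vector of transcript sequences.
#' @param min_tag_len tags shorter than this are dropped.
#' @return named list of integer depth vectors (one per transcript with
#'   signal; positions 0-based, so `depth[i]` is position `i - 1`).
#' @export
build_density <- function(tags, transcripts, min_tag_len = 15L) {
  stopifnot(!is.null(names(transcripts)))
  tags <- tags[nchar(tags) >= min_tag_len]
  profiles <- list()
  if (!length(tags)) return(profiles)
  counts <- table(tags)
  uniq <- names(counts)
  subj <- Biostrings::DNAStringSet(transcripts)
  dict <- Biostrings::DNAStringSet(uniq)
  by_len <- split(seq_along(uniq), nchar(uniq))
  for (tid in names(transcripts)) {
    depth <- integer(nchar(transcripts[[tid]]))
    for (grp in by_len) {
      pd <- Biostrings::PDict(dict[grp])
      hits <- Biostrings::matchPDict(pd, subj[[tid]])
      starts <- Biostrings::startIndex(hits)
      for (g in seq_along(grp)) {
        st <- starts[[g]]
        if (is.null(st) || !length(st)) next
        cnt <- as.integer(counts[[uniq[grp[g]]]])
        for (s in st) depth[s] <- depth[s] + cnt
      }
    }
    if (any(depth > 0L)) profiles[[tid]] <- depth
  }
  profiles
}

#' Classify a cleavage position into degradome category 0-4
#'
#' @param profile integer depth vector for one transcript (index i is
#'   0-based position i - 1).
#' @param position 0-based transcript position of the tag 5' end.
#' @return integer category in 0..4.
#' @export
classify_category <- function(profile, position) {
  stopifnot(position >= 0, position < length(profile))
  d <- profile[position + 1L]
  if (d < 1L) {
    stop("no degradome signal at the queried position", call. = FALSE)
  }
  nz <- profile[profile >= 1L]
  M <- max(nz)
  med <- median(nz)
  if (d == M) {
    if (sum(nz == M) == 1L) 0L else 1L
  } else if (d > med) {
    2L
  } else if (d > 1L) {
    3L
  } else {
    4L
  }
}

#' Confirm predicted interactions against degradome profiles
#'
#' The expected cleavage position is the transcript nucleotide paired to
#' miRNA position `cut_pos` (1-based from the miRNA 5' end; 10 by default,
#' i.e. the canonical 10-11 cut). For a site occupying `[start, end)` on
#' the transcript, that nucleotide is `start + (end - start) - cut_pos`.
#'
#' @param interactions interaction table with `mirna_id`, `transcript_id`,
#'   `start`, `end` (0-based half-open site).
#' @param profiles depth profiles from [build_density()].
#' @param keep categories counting as confirmation (default `c(0, 1)`).
#' @param cut_pos miRNA position defining the cut site (default 10).
#' @return data.frame of confirmed interactions with `position`, `depth`,
#'   `category`.
#' @export
confirm_pairs <- function(interactions, profiles, keep = c(0L, 1L),
                          cut_pos = 10L) {
  out <- list()
  for (i in seq_len(nrow(interactions))) {
    row <- interactions[i, ]
    prof <- profiles[[row$transcript_id]]
    if (is.null(prof)) next
    pos <- row$start + (row$end - row$start) - cut_pos
    if (is.na(pos) || pos < 0 || pos >= length(prof)) {
      warning(sprintf("site %s:%s outside transcript bounds; skipped",
                      row$mirna_id, row$transcript_id))
      next
    }
    if (prof[pos + 1L] < 1L) next
    cat_i <- classify_category(prof, pos)
    if (cat_i %in% keep) {
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = row$mirna_id, transcript_id = row$transcript_id,
        start = row$start, end = row$end, position = pos,
        depth = prof[pos + 1L], category = cat_i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      position = integer(0), depth = integer(0),
                      category = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
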