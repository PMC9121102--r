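# miRNA target prediction.
#
# Two computational scoring families are implemented behind a common
# alignment engine:
#   * expectation penalty (psRNATarget-style): mismatch 1.0, G:U wobble 0.5,
#     bulged nucleotide 2.0, all doubled at miRNA positions 2-13 (1-based
#     from the 5' end); a site is kept when E < e_cutoff (strict).
#   * duplex energy ratio (RNAhybrid-style): simplified pair energies
#     G:C -3, A:U -2, G:U -1; MDE is the perfectly paired miRNA energy and
#     MFE the best attainable pairing of the candidate site; a site is kept
#     when MFE/MDE >= ratio_cutoff.
# Alignments are ungapped or carry at most one single-nucleotide bulge on
# either strand; the reported alignment is the exact optimum over that
# family. Degradome evidence is integrated downstream as a third method.

.mirna_code <- function(seq, what = "miRNA") {
  match(strsplit(normalize_seq(seq, what), "", fixed = TRUE)[[1]], DNA_BASES)
}

# penalty matrix rows = miRNA base, cols = target (site) base
.expectation_matrix <- local({
  m <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 0
  m["G", "T"] <- m["T", "G"] <- 0.5
  m
})

.energy_matrix <- local({
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["G", "C"] <- m["C", "G"] <- -3
  m["A", "T"] <- m["T", "A"] <- -2
  m["G", "T"] <- m["T", "G"] <- -1
  m
})

# Score all windows of one width class against a target sequence.
#
# mi: miRNA integer codes 5'->3'; tc: target integer codes; mat: 4x4 score
# contribution per (miRNA base, site base); weights: per-miRNA-position
# multiplier; bulge_cost: added cost of the single bulged nucleotide
# (already position-weighted by the caller via bulge_w); mode one of
# "ungapped", "site_bulge" (site one nt longer), "mirna_bulge" (site one nt
# shorter). Returns a numeric vector indexed by 0-based window offset.
.window_scores <- function(mi, tc, mat, weights, bulge_unit, mode) {
  m <- length(mi)
  n <- length(tc)
  width <- switch(mode, ungapped = m, site_bulge = m + 1L,
                  mirna_bulge = m - 1L)
  n_win <- n - width + 1L
  if (n_win < 1L) return(numeric(0))
  off <- seq_len(n_win)  # 1-based window start in tc
  seedw <- function(p) ifelse(p >= 2 & p <= 13, 2, 1)
  if (mode == "ungapped") {
    tot <- numeric(n_win)
    for (p in seq_len(m)) {
      tot <- tot + weights[p] * mat[mi[p], ][tc[off + (m - p)]]
    }
    return(tot)
  }
  if (mode == "site_bulge") {
    # site nt at index b (0-based in window) is bulged; q = m - b miRNA
    # positions pair below the bulge.
    lo <- matrix(0, n_win, m)  # contribution of p when p > q (site idx m-p)
    hi <- matrix(0, n_win, m)  # contribution of p when p <= q (idx m-p+1)
    for (p in seq_len(m)) {
      lo[, p] <- weights[p] * mat[mi[p], ][tc[off + (m - p)]]
      hi[, p] <- weights[p] * mat[mi[p], ][tc[off + (m - p + 1L)]]
    }
    cum_hi <- cbind(0, t(apply(hi, 1, cumsum)))          # q = 0..m
    cum_lo <- cbind(t(apply(lo[, m:1, drop = FALSE], 1, cumsum))[, m:1,
                                                                 drop = FALSE],
                    0)                                   # sum p > q
    best <- rep(Inf, n_win)
    for (q in 0:m) {
      wb <- if (q >= 1 && q <= 12) 2 else 1
      sc <- cum_hi[, q + 1L] + cum_lo[, q + 1L] + bulge_unit * wb
      best <- pmin(best, sc)
    }
    return(best)
  }
  # mirna_bulge: miRNA position j unpaired
  lo <- matrix(0, n_win, m)  # p < j: site idx m-1-p
  hi <- matrix(0, n_win, m)  # p > j: site idx m-p
  for (p in seq_len(m)) {
    i_lo <- m - 1L - p
    lo[, p] <- if (i_lo >= 0L) {
      weights[p] * mat[mi[p], ][tc[off + i_lo]]
    } else Inf
    hi[, p] <- weights[p] * mat[mi[p], ][tc[off + (m - p)]]
  }
  cum_lo <- cbind(0, t(apply(lo, 1, cumsum)))            # sum p < j
  cum_hi <- cbind(t(apply(hi[, m:1, drop = FALSE], 1, cumsum))[, m:1,
                                                               drop = FALSE],
                  0)                                     # sum p > j
  best <- rep(Inf, n_win)
  for (j in seq_len(m)) {
    wj <- seedw(j)
    sc <- cum_lo[, j] + cum_hi[, j + 1L] + bulge_unit * wj
    best <- pmin(best, sc)
  }
  best
}

.score_site <- function(mi, site_codes, mat, weights, bulge_unit) {
  m <- length(mi)
  L <- length(site_codes)
  mode <- if (L == m) "ungapped" else if (L == m + 1L) "site_bulge"
          else if (L == m - 1L) "mirna_bulge"
          else stop("site length must be within 1 nt of the miRNA length",
                    call. = FALSE)
  .window_scores(mi, site_codes, mat, weights, bulge_unit, mode)[1]
}

#' Expectation penalty score of one miRNA-site alignment
#'
#' The site sequence is the target-strand window written 5' to 3'; the
#' miRNA 5' end pairs the site 3' end. The score is the minimum cumulative
#' penalty over ungapped alignments and alignments with a single bulged
#' nucleotide on either strand.
#'
#' @param mirna_seq miRNA sequence, 5' to 3'.
#' @param site_seq candidate site sequence, 5' to 3', length within 1 nt of
#'   the miRNA length.
#' @return numeric expectation score E (0 for a perfect complement).
#' @export
expectation_score <- function(mirna_seq, site_seq) {
  mi <- .mirna_code(mirna_seq)
  sc <- .mirna_code(site_seq, what = "site")
  w <- ifelse(seq_along(mi) >= 2 & seq_along(mi) <= 13, 2, 1)
  unname(.score_site(mi, sc, .expectation_matrix, w, 2))
}

#' Duplex-energy ratio (MFE/MDE) of one miRNA-site alignment
#'
#' MDE is the energy of the miRNA paired perfectly (every G/C contributes
#' -3, every A/U -2); MFE is the minimum energy attainable by pairing the
#' miRNA to the given site (ungapped or one single-nucleotide bulge).
#'
#' @inheritParams expectation_score
#' @param ratio_cutoff minimum ratio for a pass (default 0.75).
#' @return list with `mfe`, `mde`, `ratio`, `pass`.
#' @export
hybrid_ratio <- function(mirna_seq, site_seq, ratio_cutoff = 0.75) {
  mi <- .mirna_code(mirna_seq)
  if (!length(mi)) stop("cannot compute MDE of an empty miRNA", call. = FALSE)
  sc <- .mirna_code(site_seq, what = "site")
  mde <- sum(ifelse(mi %in% c(2L, 3L), -3, -2))  # C,G -> -3; A,T -> -2
  if (mde == 0) stop("undefined MFE/MDE ratio: perfect duplex has zero energy",
                     call. = FALSE)
  w <- rep(1, length(mi))
  mfe <- unname(.score_site(mi, sc, .energy_matrix, w, 0))
  ratio <- mfe / mde
  list(mfe = mfe, mde = mde, ratio = ratio, pass = ratio >= ratio_cutoff)
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every window whose expectation score is below `e_cutoff` or whose
#' MFE/MDE ratio reaches `ratio_cutoff` is reported; overlapping windows of
#' one miRNA-transcript pair are merged to the minimum-E site, and the
#' methods supported anywhere in the merged group are recorded.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param e_cutoff strict upper bound on E for the expectation method.
#' @param ratio_cutoff minimum MFE/MDE ratio for the hybrid method.
#' @param methods computational methods to run (subset of
#'   `c("expectation", "hybrid")`).
#' @return data.frame of interactions: `mirna_id`, `transcript_id`, `start`,
#'   `end` (0-based half-open site on the transcript), `expectation_E`,
#'   `mfe`, `mde`, `ratio`, `methods` (comma-joined).
#' @export
scan_transcriptome <- function(mirnas, transcripts, e_cutoff = 3.0,
                               ratio_cutoff = 0.75,
                               methods = c("expectation", "hybrid")) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  out <- vector("list", length(mirnas) * length(transcripts))
  k <- 0L
  t_codes <- lapply(transcripts, .mirna_code, what = "transcript")
  for (mid in names(mirnas)) {
    mi <- .mirna_code(mirnas[[mid]])
    m <- length(mi)
    w_exp <- ifelse(seq_len(m) >= 2 & seq_len(m) <= 13, 2, 1)
    w_one <- rep(1, m)
    mde <- sum(ifelse(mi %in% c(2L, 3L), -3, -2))
    for (tid in names(transcripts)) {
      tc <- t_codes[[tid]]
      hits <- NULL
      for (mode in c("ungapped", "site_bulge", "mirna_bulge")) {
        width <- switch(mode, ungapped = m, site_bulge = m + 1L,
                        mirna_bulge = m - 1L)
        e <- .window_scores(mi, tc, .expectation_matrix, w_exp, 2, mode)
        if (!length(e)) next
        en <- .window_scores(mi, tc, .energy_matrix, w_one, 0, mode)
        ratio <- en / mde
        keep_e <- ("expectation" %in% methods) & (e < e_cutoff)
        keep_h <- ("hybrid" %in% methods) & (ratio >= ratio_cutoff)
        keep <- which(keep_e | keep_h)
        if (!length(keep)) next
        hits <- rbind(hits, data.frame(
          start = keep - 1L, end = keep - 1L + width,
          expectation_E = e[keep], mfe = en[keep], ratio = ratio[keep],
          expectation = keep_e[keep], hybrid = keep_h[keep]))
      }
      if (is.null(hits) || !nrow(hits)) next
      hits <- hits[order(hits$start, hits$end), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(
        hits$start[-1] >= cummax(hits$end)[-nrow(hits)])))
      merged <- lapply(split(hits, grp), function(g) {
        best <- which.min(g$expectation_E + 1e-9 * g$start)
        meths <- c(if (any(g$expectation)) "expectation",
                   if (any(g$hybrid)) "hybrid")
        data.frame(start = g$start[best], end = g$end[best],
                   expectation_E = g$expectation_E[best], mfe = g$mfe[best],
                   ratio = g$ratio[best],
                   methods = paste(meths, collapse = ","))
      })
      merged <- do.call(rbind, merged)
      k <- k + 1L
      out[[k]] <- cbind(data.frame(mirna_id = mid, transcript_id = tid,
                                   stringsAsFactors = FALSE),
                        merged, data.frame(mde = mde))
    }
  }
  if (k == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      expectation_E = numeric(0), mfe = numeric(0),
                      ratio = numeric(0), methods = character(0),
                      mde = numeric(0)))
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Integrate computational predictions with degradome confirmations
#'
#' The overall dataset is the union of all method hits; the overlap dataset
#' keeps every degradome-confirmed pair plus pairs predicted by at least
#' two computational methods.
#'
#' @param predictions interaction table from [scan_transcriptome()].
#' @param degradome_confirmed optional data.frame with columns `mirna_id`,
#'   `transcript_id`, `category` (confirmed pairs; categories already
#'   filtered by the caller).
#' @return `predictions` augmented with `degradome_category`, `in_overall`,
#'   `in_overlap`, and degradome-only pairs appended.
#' @export
integrate_methods <- function(predictions, degradome_confirmed = NULL) {
  preds <- predictions
  if (!nrow(preds) && is.null(degradome_confirmed)) {
    preds$degradome_category <- integer(0)
    preds$in_overall <- logical(0)
    preds$in_overlap <- logical(0)
    return(preds)
  }
  key <- function(d) paste(d$mirna_id, d$transcript_id, sep = "\r")
  preds$degradome_category <- NA_integer_
  if (!is.null(degradome_confirmed) && nrow(degradome_confirmed)) {
    idx <- match(key(preds), key(degradome_confirmed))
    hit <- !is.na(idx)
    preds$degradome_category[hit] <- degradome_confirmed$category[idx[hit]]
    preds$methods[hit] <- paste(preds$methods[hit], "degradome", sep = ",")
    preds$methods[hit] <- sub("^,", "", preds$methods[hit])
    extra <- degradome_confirmed[!(key(degradome_confirmed) %in% key(preds)), ,
                                 drop = FALSE]
    if (nrow(extra)) {
      add <- data.frame(mirna_id = extra$mirna_id,
                        transcript_id = extra$transcript_id,
                        start = if (!is.null(extra$start)) extra$start else NA,
                        end = if (!is.null(extra$end)) extra$end else NA,
                        expectation_E = NA_real_, mfe = NA_real_,
                        ratio = NA_real_, methods = "degradome",
                        mde = NA_real_,
                        degradome_category = extra$category,
                        stringsAsFactors = FALSE)
      preds <- rbind(preds[, names(add)], add)
    }
  }
  meth_list <- strsplit(preds$methods, ",", fixed = TRUE)
  n_comp <- vapply(meth_list, function(m) {
    sum(m %in% c("expectation", "hybrid"))
  }, integer(1))
  has_deg <- vapply(meth_list, function(m) "degradome" %in% m, logical(1))
  preds$in_overall <- n_comp >= 1L | has_deg
  preds$in_overlap <- has_deg | n_comp >= 2L
  stopifnot(all(!preds$in_overlap | preds$in_overall))
  rownames(preds) <- NULL
  preds
}
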