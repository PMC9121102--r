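# Quantification and expression-pattern classification.
#
# miRNA abundance is reads per million (RPM): a read counts toward a mature
# miRNA when it maps to the same strand with both end offsets within
# `max_shift` nt of the annotated mature coordinates. Transcript abundance
# is FPKM. Tissue-level matrices are replicate means; patterns are cut at
# RPM >= high_cut ("high") and RPM < low_cut ("low") into four classes.

#' Default tissue labels
#'
#' Root, stem and leaf at the shooting stage (RS, SS, LS); root, stem,
#' flag leaf and panicle at the grain-filling stage (RG, SG, LG, P).
#' @export
TISSUES <- c("RS", "SS", "LS", "RG", "SG", "LG", "P")

#' Quantify mature miRNA expression in RPM
#'
#' @param alignments data.frame of read alignments with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, and one count column per
#'   library (columns listed in `libraries`).
#' @param loci data.frame with `locus_id`, `chrom`, `mature_start`,
#'   `mature_end`, `strand`.
#' @param libraries character vector of library (count column) names.
#' @param totals named numeric vector of total mapped reads per library
#'   (the RPM denominator).
#' @param max_shift maximum absolute start/end offset for a read to count
#'   toward the mature miRNA (inclusive).
#' @return matrix of RPM values, loci x libraries.
#' @export
quantify_mirna_rpm <- function(alignments, loci, libraries, totals,
                               max_shift = 2L) {
  stopifnot(all(libraries %in% names(totals)),
            all(libraries %in% names(alignments)))
  if (any(totals[libraries] <= 0)) {
    bad <- libraries[totals[libraries] <= 0][1]
    stop(sprintf("undefined RPM: library '%s' has zero mapped reads", bad),
         call. = FALSE)
  }
  counts <- matrix(0, nrow(loci), length(libraries),
                   dimnames = list(loci$locus_id, libraries))
  for (i in seq_len(nrow(loci))) {
    sel <- alignments$chrom == loci$chrom[i] &
      alignments$strand == loci$strand[i] &
      abs(alignments$start - loci$mature_start[i]) <= max_shift &
      abs(alignments$end - loci$mature_end[i]) <= max_shift
    if (any(sel)) {
      counts[i, ] <- colSums(alignments[sel, libraries, drop = FALSE])
    }
  }
  sweep(counts, 2, totals[libraries], "/") * 1e6
}

#' Quantify transcript expression in FPKM
#'
#' FPKM = count / (length in kb x total fragments in millions).
#'
#' @param counts matrix of fragment counts, transcripts x samples.
#' @param lengths named numeric vector of transcript lengths in nt.
#' @param totals named numeric vector of total fragments per sample.
#' @return matrix of FPKM values with the shape of `counts`.
#' @export
quantify_fpkm <- function(counts, lengths, totals) {
  stopifnot(nrow(counts) == length(lengths),
            ncol(counts) == length(totals))
  if (any(lengths <= 0)) stop("zero-length transcript", call. = FALSE)
  kb <- lengths / 1e3
  mil <- totals / 1e6
  sweep(sweep(counts, 1, kb, "/"), 2, mil, "/")
}

#' Average a sample-level matrix to tissue level
#'
#' @param mat entities x samples matrix.
#' @param tissue_of named (or positional) character vector giving the tissue
#'   of each sample column.
#' @param tissues required tissue set and output column order.
#' @return entities x tissues matrix of replicate means.
#' @export
average_by_tissue <- function(mat, tissue_of, tissues = TISSUES) {
  stopifnot(length(tissue_of) == ncol(mat))
  missing <- setdiff(tissues, tissue_of)
  if (length(missing)) {
    stop(sprintf("missing tissue(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- sapply(tissues, function(ts) {
    rowMeans(mat[, tissue_of == ts, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), tissues))
  out
}

#' Classify miRNA expression patterns from a tissue-level RPM matrix
#'
#' Classes partition the miRNA set: `housekeeping` (high in every tissue),
#' `tissue_specific` (high in exactly one tissue; its identity is reported
#' as `peak_tissue`), `low` (below `low_cut` everywhere), `intermediate`
#' (everything else).
#'
#' @param tissue_mat miRNAs x tissues RPM matrix.
#' @param high_cut RPM threshold for "high" (inclusive).
#' @param low_cut RPM threshold for "low" (strict).
#' @return data.frame with `mirna_id`, `class`, `peak_tissue`.
#' @export
classify_patterns <- function(tissue_mat, high_cut = 100, low_cut = 10) {
  n_high <- rowSums(tissue_mat >= high_cut)
  all_low <- rowSums(tissue_mat < low_cut) == ncol(tissue_mat)
  cls <- rep("intermediate", nrow(tissue_mat))
  cls[n_high == ncol(tissue_mat)] <- "housekeeping"
  cls[n_high == 1L & cls != "housekeeping"] <- "tissue_specific"
  cls[all_low & n_high == 0L] <- "low"
  peak <- rep(NA_character_, nrow(tissue_mat))
  ts <- cls == "tissue_specific"
  if (any(ts)) {
    peak[ts] <- colnames(tissue_mat)[apply(tissue_mat[ts, , drop = FALSE],
                                           1, which.max)]
  }
  data.frame(mirna_id = rownames(tissue_mat), class = cls,
             peak_tissue = peak, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target Ct of the gene of interest in the test sample.
#' @param ct_ref Ct of the reference gene in the test sample.
#' @param ct_target_cal Ct of the gene of interest in the calibrator.
#' @param ct_ref_cal Ct of the reference gene in the calibrator.
#' @return relative expression `2^-((ct_target - ct_ref) -
#'   (ct_target_cal - ct_ref_cal))`.
#' @export
ddct <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  stopifnot(is.finite(ct_target), is.finite(ct_ref),
            is.finite(ct_target_cal), is.finite(ct_ref_cal))
  2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))
}
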