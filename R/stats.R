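# Correlation and enrichment statistics.

#' Pearson correlation between miRNAs and their targets
#'
#' One record per requested pair, computed over tissue-averaged profiles
#' (both matrices must share the same tissue column order). Pairs with a
#' constant profile on either side have undefined r and are flagged.
#'
#' @param mirna_mat miRNAs x tissues matrix.
#' @param target_mat targets x tissues matrix.
#' @param pairs data.frame with `mirna_id`, `target_id`.
#' @return data.frame with `mirna_id`, `target_id`, `r`, `t_stat`, `p`,
#'   `n`, `defined`.
#' @export
correlate_pairs <- function(mirna_mat, target_mat, pairs) {
  if (!identical(colnames(mirna_mat), colnames(target_mat))) {
    stop("tissue ordering of the two matrices differs", call. = FALSE)
  }
  n <- ncol(mirna_mat)
  res <- data.frame(mirna_id = pairs$mirna_id, target_id = pairs$target_id,
                    r = NA_real_, t_stat = NA_real_, p = NA_real_,
                    n = n, defined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    x <- mirna_mat[pairs$mirna_id[i], ]
    y <- target_mat[pairs$target_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) next
    r <- cor(x, y)
    res$r[i] <- r
    res$defined[i] <- TRUE
    if (abs(r) < 1) {
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      res$t_stat[i] <- t_stat
      res$p[i] <- 2 * pt(-abs(t_stat), df = n - 2)
    } else {
      res$t_stat[i] <- sign(r) * Inf
      res$p[i] <- 0
    }
  }
  res
}

#' Fraction of pairs with negative correlation
#'
#' Undefined records (constant profiles) are excluded from the denominator.
#'
#' @param records output of [correlate_pairs()].
#' @return list with `fraction`, `n_negative`, `n_defined`.
#' @export
negative_fraction <- function(records) {
  ok <- records$defined
  if (!any(ok)) stop("no defined correlation records", call. = FALSE)
  n_neg <- sum(records$r[ok] < 0)
  list(fraction = n_neg / sum(ok), n_negative = n_neg, n_defined = sum(ok))
}

#' Hypergeometric (Fisher) term enrichment
#'
#' Upper-tail hypergeometric p per term:
#' p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n), with k the overlap of
#' the selection with the term, K the term size, n the selection size and N
#' the universe size. Terms with no overlap are omitted.
#'
#' @param selection character vector of selected genes (subset of universe).
#' @param term_genes named list mapping term id -> character vector of genes.
#' @param universe character vector of all genes.
#' @param adjust apply Benjamini-Hochberg adjustment?
#' @return data.frame with `term_id`, `k`, `K`, `n`, `N`, `p`, and `p_adj`
#'   when `adjust` is TRUE; sorted by p.
#' @export
enrich <- function(selection, term_genes, universe, adjust = TRUE) {
  selection <- unique(selection)
  universe <- unique(universe)
  extra <- setdiff(selection, universe)
  if (length(extra)) {
    stop(sprintf("selection not contained in universe: %s",
                 paste(head(extra, 5), collapse = ", ")), call. = FALSE)
  }
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(term_genes), function(term) {
    genes <- intersect(unique(term_genes[[term]]), universe)
    K <- length(genes)
    k <- length(intersect(genes, selection))
    if (k == 0L) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0))
    if (adjust) out$p_adj <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
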