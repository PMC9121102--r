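# Weighted co-expression modules.
#
# The procedure mirrors the standard weighted-network workflow: soft
# thresholding of the absolute Pearson correlation (unsigned network,
# a_ij = |cor|^beta with beta = 8 by default), topological overlap,
# average-linkage clustering of 1 - TOM with a static height cut, module
# eigengenes (first principal component, sign-oriented), module-trait
# correlations against one-hot tissue indicators, and kME hub ranking.
# The static cut replaces dynamic tree cutting; it is deterministic,
# dependency-free, and sufficient for recovering planted blocks.

#' Default co-expression settings
#'
#' @param beta soft power (default 8).
#' @param min_module_size smallest cluster kept as a module.
#' @param cut_height static cut height on the 1 - TOM dendrogram.
#' @param trait_r_cut minimum |r| for a module-trait association.
#' @param trait_p_cut maximum p for a module-trait association.
#' @param n_hubs hub genes reported per module.
#' @return list of settings.
#' @export
coexpress_config <- function(beta = 8, min_module_size = 5L,
                             cut_height = 0.9, trait_r_cut = 0.75,
                             trait_p_cut = 0.01, n_hubs = 9L) {
  stopifnot(beta >= 1, cut_height > 0, cut_height <= 1,
            trait_r_cut > 0, trait_r_cut <= 1)
  list(beta = beta, min_module_size = min_module_size,
       cut_height = cut_height, trait_r_cut = trait_r_cut,
       trait_p_cut = trait_p_cut, n_hubs = n_hubs)
}

#' Filter genes for network construction
#'
#' Removes rows with zero variance or with more than `max_missing` missing
#' samples.
#'
#' @param mat genes x samples matrix (may contain NA).
#' @param max_missing maximum tolerated missing fraction (strict).
#' @return list with `mat` (filtered) and `removed` (data.frame of gene id
#'   and reason).
#' @export
filter_genes <- function(mat, max_missing = 0.10) {
  miss_frac <- rowMeans(is.na(mat))
  v <- apply(mat, 1, function(x) var(x, na.rm = TRUE))
  zero_var <- !is.na(v) & v == 0
  too_missing <- miss_frac > max_missing
  drop <- zero_var | too_missing | is.na(v)
  removed <- data.frame(
    gene = rownames(mat)[drop],
    reason = ifelse(too_missing[drop], "missing_fraction", "zero_variance"),
    stringsAsFactors = FALSE)
  kept <- mat[!drop, , drop = FALSE]
  if (!nrow(kept)) stop("all genes removed by filtering", call. = FALSE)
  list(mat = kept, removed = removed)
}

#' Soft-threshold adjacency
#'
#' @param mat genes x samples matrix.
#' @param beta soft power.
#' @return genes x genes adjacency `|cor|^beta` with unit diagonal.
#' @export
adjacency <- function(mat, beta = 8) {
  stopifnot(ncol(mat) >= 4)
  a <- abs(cor(t(mat)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i the connectivity excluding the diagonal; TOM_ii = 1.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return TOM matrix of the same shape.
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  shared <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' Clusters are obtained with a static cut at `cut_height`; clusters below
#' `min_module_size` are pooled into the unassigned module `"grey"`.
#' Module labels are `"M1"`, `"M2"`, ... ordered by decreasing size.
#'
#' @param tom TOM matrix.
#' @param config settings from [coexpress_config()].
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom, config = coexpress_config()) {
  genes <- rownames(tom)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = config$cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$min_module_size]
  lab <- rep("grey", length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) {
      lab[raw == as.integer(keep[i])] <- paste0("M", i)
    }
  }
  names(lab) <- genes
  lab
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression submatrix, sign-oriented to correlate positively
#' with the module's mean standardized profile. Single-gene modules return
#' the standardized gene profile. The `"grey"` pool gets no eigengene.
#'
#' @param mat genes x samples matrix.
#' @param assignment gene -> module vector from [detect_modules()].
#' @return modules x samples matrix of eigengenes.
#' @export
module_eigengene <- function(mat, assignment) {
  mods <- setdiff(sort(unique(assignment)), "grey")
  eg <- matrix(NA_real_, length(mods), ncol(mat),
               dimnames = list(mods, colnames(mat)))
  for (mod in mods) {
    sub <- mat[names(assignment)[assignment == mod], , drop = FALSE]
    z <- t(scale(t(sub)))
    if (nrow(z) == 1L) {
      e <- as.numeric(z)
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    ref <- colMeans(z)
    if (sd(ref) > 0 && cor(e, ref) < 0) e <- -e
    eg[mod, ] <- e
  }
  eg
}

#' Module-trait correlation table
#'
#' Correlates each module eigengene with one-hot tissue indicators over
#' samples; significance from the Pearson t-test.
#'
#' @param eigengenes modules x samples matrix.
#' @param tissue_of tissue label of each sample column.
#' @param config settings from [coexpress_config()].
#' @param tissues tissue set to test.
#' @return data.frame with `module`, `tissue`, `r`, `p`, `retained`.
#' @export
module_trait <- function(eigengenes, tissue_of,
                         config = coexpress_config(),
                         tissues = TISSUES) {
  stopifnot(length(tissue_of) == ncol(eigengenes))
  rows <- list()
  for (mod in rownames(eigengenes)) {
    for (ts in tissues) {
      ind <- as.numeric(tissue_of == ts)
      ct <- cor.test(eigengenes[mod, ], ind)
      r <- unname(ct$estimate)
      p <- ct$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, tissue = ts, r = r, p = p,
        retained = abs(r) >= config$trait_r_cut & p < config$trait_p_cut,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank hub genes by eigengene connectivity (kME)
#'
#' kME is the Pearson correlation of a gene's profile with its own module
#' eigengene; the top `n_hubs` genes per module are returned, ties broken
#' by gene id.
#'
#' @param mat genes x samples matrix.
#' @param eigengenes modules x samples matrix.
#' @param assignment gene -> module vector.
#' @param n_hubs hubs per module.
#' @return data.frame with `module`, `gene`, `kme`, `rank`.
#' @export
kme_hubs <- function(mat, eigengenes, assignment, n_hubs = 9L) {
  rows <- list()
  for (mod in rownames(eigengenes)) {
    genes <- names(assignment)[assignment == mod]
    kme <- vapply(genes, function(g) cor(mat[g, ], eigengenes[mod, ]),
                  numeric(1))
    ord <- order(-kme, genes)
    if (length(genes) < n_hubs) {
      warning(sprintf("module %s has %d genes (< n_hubs = %d); returning all",
                      mod, length(genes), n_hubs))
    }
    top <- ord[seq_len(min(n_hubs, length(genes)))]
    rows[[length(rows) + 1L]] <- data.frame(
      module = mod, gene = genes[top], kme = kme[top],
      rank = seq_along(top), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trace the regulatory miRNAs of a module
#'
#' @param module_genes character vector of gene/transcript ids in the module.
#' @param interactions interaction table with `mirna_id`, `transcript_id`.
#' @return list with `edges` (interactions restricted to the module) and
#'   `degree` (named miRNA -> number of module targets, decreasing).
#' @export
trace_module_mirnas <- function(module_genes, interactions) {
  edges <- interactions[interactions$transcript_id %in% module_genes, ,
                        drop = FALSE]
  rownames(edges) <- NULL
  deg <- sort(table(edges$mirna_id), decreasing = TRUE)
  list(edges = edges, degree = setNames(as.integer(deg), names(deg)))
}
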