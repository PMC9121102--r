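# Promoter scanning and the TF -> miRNA -> target network.
#
# TF binding is predicted by scanning 2,000-nt promoters with position
# weight matrices. Scores are log2 odds against a 0-order background,
# quantized to a fixed grid of 1e-4 bits so that the score distribution
# under the background (and hence every p-value) is computed exactly by
# dynamic programming over per-column score distributions. Typed edges:
# TMI (TF -> miRNA), MTI (miRNA -> target), TTI (TF -> target); cascades
# are TMI-MTI chains and feed-forward loops are cascades whose TF also
# hits the same target.

PWM_SCORE_SCALE <- 1e4

#' Extract promoter sequences upstream of features
#'
#' On the + strand the promoter is `[start - upstream, start)`; on the -
#' strand it is `[end, end + upstream)` reverse-complemented. Promoters are
#' truncated at chromosome edges and the realized length recorded.
#'
#' @param features data.frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param genome named character vector of chromosome sequences.
#' @param upstream promoter length in nt.
#' @return data.frame with `id`, `chrom`, `start`, `end`, `strand`,
#'   `length`, `seq`.
#' @export
extract_promoters <- function(features, genome, upstream = 2000L) {
  if (any(!features$strand %in% c("+", "-"))) {
    stop("feature without strand", call. = FALSE)
  }
  n <- nrow(features)
  out <- features[, c("id", "chrom", "strand")]
  out$start <- out$end <- integer(n)
  out$seq <- character(n)
  for (i in seq_len(n)) {
    chrom_seq <- genome[[features$chrom[i]]]
    clen <- nchar(chrom_seq)
    if (features$strand[i] == "+") {
      s <- max(0L, features$start[i] - upstream)
      e <- features$start[i]
      sq <- substring(chrom_seq, s + 1L, e)
    } else {
      s <- features$end[i]
      e <- min(clen, features$end[i] + upstream)
      sq <- revcomp(substring(chrom_seq, s + 1L, e))
    }
    out$start[i] <- s; out$end[i] <- e; out$seq[i] <- sq
  }
  out$length <- out$end - out$start
  out[, c("id", "chrom", "start", "end", "strand", "length", "seq")]
}

#' Read position weight matrices
#'
#' Supports the JASPAR-style tab format (`>id name` header followed by four
#' `A [ ... ]` rows) and the MEME minimal format (`MOTIF` blocks with a
#' letter-probability matrix). Count matrices are converted to column
#' probabilities.
#'
#' @param path motif file.
#' @return named list of PWMs; each a list with `motif_id`, `tf_family`,
#'   `mat` (4 x L probability matrix, rows A/C/G/T).
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  pwms <- list()
  if (any(grepl("^MEME version", lines))) {
    idx <- grep("^MOTIF\\b", lines)
    for (i in seq_along(idx)) {
      hdr <- strsplit(lines[idx[i]], "\\s+")[[1]]
      id <- hdr[2]
      fam <- if (length(hdr) >= 3) hdr[3] else id
      j <- idx[i] + 1L
      while (j <= length(lines) && !grepl("^letter-probability", lines[j])) {
        j <- j + 1L
      }
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- t(vapply(strsplit(rows, "\\s+"),
                      function(x) as.numeric(x[nzchar(x)]), numeric(4)))
      pwms[[id]] <- list(motif_id = id, tf_family = fam,
                         mat = .pwm_normalize(t(mat)))
    }
  } else {
    idx <- grep("^>", lines)
    for (i in seq_along(idx)) {
      hdr <- strsplit(sub("^>", "", lines[idx[i]]), "\\s+")[[1]]
      id <- hdr[1]
      fam <- if (length(hdr) >= 2) hdr[2] else id
      rows <- lines[idx[i] + 1:4]
      base <- sub("^([ACGT]).*", "\\1", rows)
      vals <- lapply(rows, function(r) {
        as.numeric(strsplit(gsub("[][]", " ",
                                 sub("^[ACGT]\\s*", "", r)), "\\s+")[[1]] |>
                     (\(x) x[nzchar(x)])())
      })
      mat <- do.call(rbind, vals)
      rownames(mat) <- base
      mat <- mat[DNA_BASES, , drop = FALSE]
      pwms[[id]] <- list(motif_id = id, tf_family = fam,
                         mat = .pwm_normalize(mat))
    }
  }
  pwms
}

.pwm_normalize <- function(mat, pseudocount = 1e-3) {
  stopifnot(nrow(mat) == 4)
  rownames(mat) <- DNA_BASES
  if (ncol(mat) < 4) stop("PWM must have length >= 4", call. = FALSE)
  mat <- sweep(mat, 2, colSums(mat), "/")
  if (any(mat == 0)) {
    mat <- mat + pseudocount
    mat <- sweep(mat, 2, colSums(mat), "/")
  }
  bad <- abs(colSums(mat) - 1) > 1e-6
  if (any(bad)) stop("PWM columns must sum to 1", call. = FALSE)
  mat
}

# integer log-odds score matrix (units of 1e-4 bits)
.pwm_int_scores <- function(pwm_mat, background = rep(0.25, 4)) {
  lo <- log2(sweep(pwm_mat, 1, background, "/"))
  storage.mode(lo) <- "double"
  round(lo * PWM_SCORE_SCALE)
}

# Exact distribution of the integer window score under the 0-order
# background; returns the upper-tail function.
.pwm_tail <- function(int_mat, background = rep(0.25, 4)) {
  lo <- apply(int_mat, 2, min)
  hi <- apply(int_mat, 2, max)
  offset <- sum(lo)
  width <- sum(hi - lo) + 1L
  probs <- c(1, numeric(width - 1L))
  at <- 1L
  for (j in seq_len(ncol(int_mat))) {
    nxt <- numeric(width)
    for (b in 1:4) {
      sh <- int_mat[b, j] - lo[j]
      idx <- seq_len(width - sh)
      nxt[idx + sh] <- nxt[idx + sh] + probs[idx] * background[b]
    }
    probs <- nxt
  }
  tail_p <- rev(cumsum(rev(probs)))
  function(score) {
    i <- score - offset + 1L
    if (i <= 0L) return(1)
    if (i > width) return(0)
    tail_p[i]
  }
}

#' Scan promoter sequences with PWMs
#'
#' Both strands are scanned; a window is a hit when the exact p-value of
#' its log-odds score under the background is at most `p_cut`.
#'
#' @param promoters data.frame from [extract_promoters()] (needs `id`,
#'   `seq`) or a named character vector.
#' @param pwms list of PWMs from [read_pwms()].
#' @param p_cut score p-value threshold (default 1e-4).
#' @param background base frequencies (A, C, G, T).
#' @return data.frame with `promoter_id`, `motif_id`, `offset` (0-based on
#'   the forward promoter sequence), `strand`, `score` (bits), `p_value`.
#' @export
scan_motifs <- function(promoters, pwms, p_cut = 1e-4,
                        background = rep(0.25, 4)) {
  if (is.data.frame(promoters)) {
    seqs <- setNames(promoters$seq, promoters$id)
  } else {
    seqs <- promoters
  }
  rows <- list()
  for (pwm in pwms) {
    int_mat <- .pwm_int_scores(pwm$mat, background)
    tailf <- .pwm_tail(int_mat, background)
    L <- ncol(int_mat)
    for (pid in names(seqs)) {
      fwd <- seqs[[pid]]
      n <- nchar(fwd)
      if (n < L) next
      for (strand in c("+", "-")) {
        s <- if (strand == "+") fwd else revcomp(fwd)
        code <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
        n_win <- n - L + 1L
        tot <- numeric(n_win)
        off <- seq_len(n_win)
        for (j in seq_len(L)) {
          tot <- tot + int_mat[, j][code[off + j - 1L]]
        }
        pv <- vapply(tot, tailf, numeric(1))
        hit <- which(pv <= p_cut)
        if (!length(hit)) next
        fwd_off <- if (strand == "+") hit - 1L else n - L - (hit - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          promoter_id = pid, motif_id = pwm$motif_id, offset = fwd_off,
          strand = strand, score = tot[hit] / PWM_SCORE_SCALE,
          p_value = pv[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(promoter_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build typed regulatory edge sets
#'
#' TMI edges come from motif hits on pre-miRNA promoters, TTI edges from
#' hits on target-gene promoters, MTI edges from the interaction table.
#' Duplicate (source, target) pairs collapse to one edge with an evidence
#' count; TTI self-edges (TF regulating itself) are dropped.
#'
#' @param mirna_hits motif hits on miRNA promoters ([scan_motifs()] output;
#'   `promoter_id` is the miRNA/locus id).
#' @param gene_hits motif hits on gene promoters (`promoter_id` is the gene
#'   id).
#' @param interactions interaction table with `mirna_id`, `transcript_id`
#'   (already restricted to the overall or overlap dataset by the caller).
#' @param tf_map data.frame with `motif_id`, `tf_id` mapping motifs to the
#'   TF genes carrying them.
#' @param known_genes optional character vector; TFs outside it are flagged
#'   `external_tf` with a warning.
#' @return list with data.frames `tmi` (`tf_id`, `mirna_id`, `n_evidence`),
#'   `mti` (`mirna_id`, `target_id`), `tti` (`tf_id`, `target_id`,
#'   `n_evidence`).
#' @export
build_edges <- function(mirna_hits, gene_hits, interactions, tf_map,
                        known_genes = NULL) {
  expand <- function(hits, target_col) {
    if (!nrow(hits)) {
      return(data.frame(tf_id = character(0), target = character(0),
                        n_evidence = integer(0)))
    }
    m <- merge(hits, tf_map, by = "motif_id")
    if (!nrow(m)) {
      return(data.frame(tf_id = character(0), target = character(0),
                        n_evidence = integer(0)))
    }
    agg <- stats::aggregate(list(n_evidence = m$offset),
                            by = list(tf_id = m$tf_id,
                                      target = m$promoter_id),
                            FUN = length)
    agg
  }
  tmi <- expand(mirna_hits)
  names(tmi)[names(tmi) == "target"] <- "mirna_id"
  tti <- expand(gene_hits)
  names(tti)[names(tti) == "target"] <- "target_id"
  tti <- tti[tti$tf_id != tti$target_id, , drop = FALSE]
  mti <- unique(data.frame(mirna_id = interactions$mirna_id,
                           target_id = interactions$transcript_id,
                           stringsAsFactors = FALSE))
  if (!is.null(known_genes)) {
    ext <- setdiff(unique(c(tmi$tf_id, tti$tf_id)), known_genes)
    if (length(ext)) {
      warning(sprintf("%d TF(s) absent from the gene set: %s", length(ext),
                      paste(head(ext, 3), collapse = ", ")))
    }
    tmi$external_tf <- !(tmi$tf_id %in% known_genes)
    tti$external_tf <- !(tti$tf_id %in% known_genes)
  }
  rownames(tmi) <- rownames(tti) <- rownames(mti) <- NULL
  list(tmi = tmi, mti = mti, tti = tti)
}

#' Enumerate cascade and feed-forward-loop motifs
#'
#' Cascades are (TF, miRNA, gene) triples with TMI(tf, mirna) and
#' MTI(mirna, gene); FFLs are cascades whose (tf, gene) pair is also a TTI
#' edge. Edge sets are deduplicated before enumeration.
#'
#' @param edges edge sets from [build_edges()] (list with `tmi`, `mti`,
#'   `tti`).
#' @return list with `cascades`, `ffls` (data.frames `tf_id`, `mirna_id`,
#'   `target_id`) and `counts` (named vector: n_tmi, n_mti, n_tti,
#'   n_cascades, n_ffls).
#' @export
enumerate_motifs <- function(edges) {
  tmi <- unique(edges$tmi[, c("tf_id", "mirna_id")])
  mti <- unique(edges$mti[, c("mirna_id", "target_id")])
  tti <- unique(edges$tti[, c("tf_id", "target_id")])
  cascades <- merge(tmi, mti, by = "mirna_id")
  cascades <- cascades[, c("tf_id", "mirna_id", "target_id")]
  if (nrow(cascades)) {
    cascades <- cascades[order(cascades$tf_id, cascades$mirna_id,
                               cascades$target_id), , drop = FALSE]
    key_c <- paste(cascades$tf_id, cascades$target_id, sep = "\r")
    key_t <- paste(tti$tf_id, tti$target_id, sep = "\r")
    ffls <- cascades[key_c %in% key_t, , drop = FALSE]
  } else {
    ffls <- cascades
  }
  rownames(cascades) <- rownames(ffls) <- NULL
  counts <- c(n_tmi = nrow(tmi), n_mti = nrow(mti), n_tti = nrow(tti),
              n_cascades = nrow(cascades), n_ffls = nrow(ffls))
  stopifnot(counts["n_ffls"] <= counts["n_cascades"])
  list(cascades = cascades, ffls = ffls, counts = counts)
}

#' Export the regulatory network
#'
#' Writes a SIF edge list (`source TYPE target`), a node-attribute TSV
#' (`node`, `kind`), and a GraphML file that round-trips through igraph.
#'
#' @param edges edge sets from [build_edges()].
#' @param prefix output path prefix; files `<prefix>.sif`,
#'   `<prefix>.nodes.tsv`, `<prefix>.graphml` are written.
#' @return invisibly, the igraph object.
#' @export
export_network <- function(edges, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  tmi <- unique(edges$tmi[, c("tf_id", "mirna_id")])
  mti <- unique(edges$mti[, c("mirna_id", "target_id")])
  tti <- unique(edges$tti[, c("tf_id", "target_id")])
  el <- rbind(
    if (nrow(tmi)) data.frame(source = tmi$tf_id, type = "TMI",
                              target = tmi$mirna_id),
    if (nrow(mti)) data.frame(source = mti$mirna_id, type = "MTI",
                              target = mti$target_id),
    if (nrow(tti)) data.frame(source = tti$tf_id, type = "TTI",
                              target = tti$target_id))
  if (is.null(el)) {
    el <- data.frame(source = character(0), type = character(0),
                     target = character(0))
  }
  writeLines(sprintf("%s\t%s\t%s", el$source, el$type, el$target),
             paste0(prefix, ".sif"))
  kind <- c(setNames(rep("TF", length(unique(c(tmi$tf_id, tti$tf_id)))),
                     unique(c(tmi$tf_id, tti$tf_id))),
            setNames(rep("miRNA", length(unique(c(tmi$mirna_id,
                                                  mti$mirna_id)))),
                     unique(c(tmi$mirna_id, mti$mirna_id))),
            setNames(rep("target", length(unique(c(mti$target_id,
                                                   tti$target_id)))),
                     unique(c(mti$target_id, tti$target_id))))
  kind <- kind[!duplicated(names(kind))]
  write_tsv(data.frame(node = names(kind), kind = unname(kind)),
            paste0(prefix, ".nodes.tsv"))
  g <- igraph::graph_from_data_frame(
    el[, c("source", "target", "type")], directed = TRUE,
    vertices = data.frame(name = names(kind), kind = unname(kind)))
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(g)
}
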