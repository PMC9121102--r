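# Secondary-structure prediction by maximum base pairing.
#
# The internal folder is a Nussinov-style dynamic program: it maximizes the
# number of {G:C, A:U, G:U} pairs in a nested (pseudoknot-free) structure
# with a minimum hairpin loop of 3 unpaired nucleotides. It is not a
# thermodynamic model; the backend is pluggable so that externally computed
# dot-bracket structures (e.g. from an MFE folder) can be supplied instead.

.pairable_matrix <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["G", "C"] <- m["C", "G"] <- TRUE   # G:C
  m["A", "T"] <- m["T", "A"] <- TRUE   # A:U
  m["G", "T"] <- m["T", "G"] <- TRUE   # G:U wobble
  m
})

.wobble_matrix <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["G", "T"] <- m["T", "G"] <- TRUE
  m
})

#' Fold an RNA/DNA sequence by maximum base pairing
#'
#' Computes a nested secondary structure maximizing the number of
#' \{G:C, A:U, G:U\} base pairs, with a minimum hairpin loop of
#' `min_loop` unpaired nucleotides (Nussinov recursion with traceback).
#' Supplying `precomputed` bypasses the internal folder.
#'
#' @param sequence a single sequence (RNA or DNA alphabet).
#' @param min_loop minimum number of unpaired nucleotides enclosed by a pair.
#' @param precomputed optional dot-bracket string to use instead of folding;
#'   it is validated against the sequence length.
#' @return list with `structure` (dot-bracket), `n_pairs`, and `ptable`
#'   (integer vector; `ptable[i]` is the 1-based partner of position i, or 0).
#' @export
fold <- function(sequence, min_loop = 3L, precomputed = NULL) {
  stopifnot(length(sequence) == 1L)
  sequence <- normalize_seq(sequence, what = "fold() input")
  n <- nchar(sequence)
  if (!is.null(precomputed)) {
    if (nchar(precomputed) != n) {
      stop("precomputed structure length does not match sequence length",
           call. = FALSE)
    }
    pt <- pair_table(precomputed)
    return(list(structure = precomputed,
                n_pairs = as.integer(sum(pt > 0) %/% 2L), ptable = pt))
  }
  code <- match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
  if (n < 2L) {
    return(list(structure = strrep(".", n), n_pairs = 0L,
                ptable = integer(n)))
  }
  canp <- .pairable_matrix[cbind(rep(code, each = n), rep(code, n))]
  canp <- matrix(canp, n, n)  # canp[j, i] == pairable(code[j], code[i])

  dp <- matrix(0L, n, n)
  for (span in seq_len(n - 1L)) {
    i <- seq_len(n - span)
    j <- i + span
    # unpaired ends
    best <- pmax(dp[cbind(i + 1L, j)], dp[cbind(i, j - 1L)])
    if (span > min_loop) {
      paired <- dp[cbind(i + 1L, j - 1L)] + 1L
      ok <- canp[cbind(i, j)]
      best <- ifelse(ok, pmax(best, paired), best)
    }
    dp[cbind(i, j)] <- best
    # bifurcation: k-split, vectorized over k for each i
    if (span >= 2L) {
      for (ii in i) {
        jj <- ii + span
        k <- seq.int(ii, jj - 1L)
        split_best <- max(dp[ii, k] + dp[cbind(k + 1L, rep(jj, span))])
        if (split_best > dp[ii, jj]) dp[ii, jj] <- split_best
      }
    }
  }

  pt <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i < j) {
      v <- dp[i, j]
      if (v == 0L) break
      if (j - i > min_loop && canp[i, j] && v == dp[i + 1L, j - 1L] + 1L) {
        pt[i] <- j; pt[j] <- i
        i <- i + 1L; j <- j - 1L
      } else if (v == dp[i + 1L, j]) {
        i <- i + 1L
      } else if (v == dp[i, j - 1L]) {
        j <- j - 1L
      } else {
        k <- i
        while (k < j - 1L && dp[i, k] + dp[k + 1L, j] != v) k <- k + 1L
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        j <- k
      }
    }
  }
  structure_str <- rep(".", n)
  structure_str[pt > seq_len(n)] <- "("
  structure_str[pt > 0 & pt < seq_len(n)] <- ")"
  list(structure = paste(structure_str, collapse = ""),
       n_pairs = sum(pt > 0) %/% 2L, ptable = pt)
}

#' Convert a dot-bracket string to a pair table
#'
#' @param structure dot-bracket string (balanced).
#' @return integer vector of 1-based partners (0 for unpaired).
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' in dot-bracket string", bad[1]),
         call. = FALSE)
  }
  n <- length(ch)
  pt <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string", call. = FALSE)
  pt
}
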