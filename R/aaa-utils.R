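#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test median na.omit p.adjust phyper prcomp
#'   quantile rbinom rlnorm rnbinom rnorm runif sd setNames var pt dbinom
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end); GFF3 is
# converted to/from 1-based inclusive only at read/write time.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed from a master seed and a label
#'
#' Each generated output file draws from its own RNG stream whose seed is a
#' stable hash of the master seed and a file-level label, so that any single
#' file is reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stable_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  # avalanche rounds: labels differing in one trailing character must not
  # yield adjacent seeds (adjacent RNG seeds give correlated streams)
  for (z in 1:3) {
    h <- (h * 48271 + 11) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Reverse-complement nucleotide sequences
#'
#' Works on plain character vectors in the DNA alphabet (U is accepted and
#' treated as T).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Normalize a sequence to the uppercase DNA alphabet
#'
#' U is rewritten to T; any other non-ACGT character raises an error naming
#' the offending character.
#'
#' @param x character vector.
#' @param what label used in error messages.
#' @return normalized character vector.
#' @export
normalize_seq <- function(x, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1], regexpr("[^ACGT]", x[bad][1]))
    stop(sprintf("invalid character '%s' in %s", ch, what), call. = FALSE)
  }
  x
}

# number of mismatches between two equal-length strings (ungapped)
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (a == b) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
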