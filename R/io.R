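# Sequence file input/output.
#
# FASTA goes through Biostrings; FASTQ records are parsed directly from the
# 4-line layout so that malformed records can be reported with their line
# number (the clean-read contract), and written with a constant dummy
# quality as the generator emits pre-trimmed reads.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @param normalize convert to uppercase DNA (U -> T)?
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, normalize = TRUE) {
  set <- Biostrings::readBStringSet(path)
  x <- as.character(set)
  names(x) <- sub("\\s.*$", "", names(set))
  if (normalize) x <- normalize_seq(x, what = basename(path))
  x
}

#' Read full FASTA headers (token plus attributes)
#'
#' Returns a data frame with the sequence name and the remainder of the
#' header line, used for metadata-carrying catalogues.
#' @param path FASTA file.
#' @return data.frame with columns `name`, `desc`.
#' @export
read_fasta_headers <- function(path) {
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  data.frame(name = sub("\\s.*$", "", full),
             desc = sub("^\\S+\\s*", "", full),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal strict reader for the 4-line FASTQ layout (Phred+33, qualities
#' ignored). A malformed record raises an error naming the offending line.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, n), call. = FALSE)
  }
  if (n == 0L) return(data.frame(id = character(0), seq = character(0)))
  at <- seq(1L, n, by = 4L)
  bad_head <- !startsWith(lines[at], "@")
  if (any(bad_head)) {
    stop(sprintf("malformed FASTQ '%s': expected '@' header at line %d",
                 path, at[bad_head][1]), call. = FALSE)
  }
  bad_plus <- !startsWith(lines[at + 2L], "+")
  if (any(bad_plus)) {
    stop(sprintf("malformed FASTQ '%s': expected '+' separator at line %d",
                 path, at[bad_plus][1] + 2L), call. = FALSE)
  }
  seqs <- lines[at + 1L]
  bad_len <- nchar(seqs) != nchar(lines[at + 3L])
  if (any(bad_len)) {
    stop(sprintf(
      "malformed FASTQ '%s': sequence/quality length mismatch at line %d",
      path, at[bad_len][1] + 1L), call. = FALSE)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[at])),
             seq = seqs, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ with a constant dummy quality
#'
#' @param ids read identifiers.
#' @param seqs read sequences.
#' @param path output file.
#' @export
write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  out <- character(4L * length(ids))
  if (length(ids)) {
    out[seq(1, length(out), 4)] <- paste0("@", ids)
    out[seq(2, length(out), 4)] <- seqs
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Write gene/transcript features to GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention on write.
#'
#' @param features data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `type`, `id`, and optionally `parent`.
#' @param path output file.
#' @param source source column value.
#' @export
write_gff3 <- function(features, path, source = "mircascade") {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  attrs <- paste0("ID=", features$id)
  if (!is.null(features$parent)) {
    has_parent <- !is.na(features$parent) & features$parent != ""
    attrs[has_parent] <- paste0(attrs[has_parent], ";Parent=",
                                features$parent[has_parent])
  }
  if (!is.null(features$name)) {
    attrs <- paste0(attrs, ";Name=", features$name)
  }
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, source, features$type,
                   features$start + 1L, features$end, features$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a GFF3 file into internal coordinates
#'
#' @param path GFF3 file.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, `id`, `parent`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), id = character(0),
                      parent = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) {
    stop(sprintf("malformed GFF3 '%s': expected 9 columns in row %d",
                 path, bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  attr_field <- function(a, key) {
    hit <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    out <- rep(NA_character_, length(a))
    found <- lengths(regmatches(a, gregexpr(paste0("(^|;)", key, "="), a))) > 0
    out[found] <- sub(paste0("^(;)?", key, "="), "",
                      sub("^;", "", unlist(hit)))
    out
  }
  data.frame(chrom = m[, 1], start = as.integer(m[, 4]) - 1L,
             end = as.integer(m[, 5]), strand = m[, 7], type = m[, 3],
             id = attr_field(m[, 9], "ID"),
             parent = attr_field(m[, 9], "Parent"),
             stringsAsFactors = FALSE)
}
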