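#' Read a (soft-masked) FASTA file
#'
#' Reads FASTA into a named character vector, preserving case so that
#' soft-masked (lowercase) bases survive the round trip. Gzipped files are
#' handled transparently. Record ids are the first whitespace-delimited token
#' of each header.
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @return named character vector of sequences, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(c(e1 = "ACGTacgt"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record: ", ids[Biostrings::width(x) == 0L][1L],
         call. = FALSE)
  stats::setNames(as.character(x), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named", call. = FALSE)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Fraction of masked bases in a sequence
#'
#' Soft-masked (lowercase) bases and \code{N} both count as masked.
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector of masked fractions in \[0, 1\].
#' @export
masked_fraction <- function(seq) {
  vapply(seq, function(s) {
    v <- utf8ToInt(s)
    if (length(v) == 0L) return(NA_real_)
    sum((v >= 97L & v <= 122L) | v == 78L) / length(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a labelled enhancer sequence set
#'
#' An `enhancer_set` is a data.frame with one row per enhancer carrying its
#' genomic interval (0-based half-open), its group label (`Q`, `A` or `PAN`),
#' and its (possibly soft-masked) sequence.
#'
#' @param name unique enhancer ids.
#' @param chrom chromosome/contig names.
#' @param start,end 0-based half-open coordinates.
#' @param group group labels, each one of `Q`, `A`, `PAN`.
#' @param seq sequences; `nchar(seq)` must equal `end - start`.
#' @return a data.frame of class `enhancer_set` with an added
#'   `masked_fraction` column.
#' @export
enhancer_set <- function(name, chrom, start, end, group, seq) {
  n <- length(name)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(group) == n, length(seq) == n)
  start <- as.integer(start); end <- as.integer(end)
  if (anyDuplicated(name))
    stop("enhancer ids must be unique", call. = FALSE)
  if (any(start >= end))
    stop("start must be < end for: ",
         paste(name[start >= end], collapse = ", "), call. = FALSE)
  bad <- !(group %in% .GROUPS)
  if (any(bad))
    stop("unknown group label(s): ",
         paste(unique(group[bad]), collapse = ", "), call. = FALSE)
  if (any(nchar(seq) != end - start))
    stop("sequence length must equal end - start for: ",
         paste(name[nchar(seq) != end - start], collapse = ", "),
         call. = FALSE)
  out <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    start = start, end = end, group = as.character(group),
                    seq = as.character(seq),
                    masked_fraction = masked_fraction(seq),
                    stringsAsFactors = FALSE)
  class(out) <- c("enhancer_set", "data.frame")
  out
}

#' @export
print.enhancer_set <- function(x, ...) {
  cat(sprintf("enhancer_set: %d sequences (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  cat(sprintf("  lengths %d-%d bp, mean masked fraction %.3f\n",
              min(x$end - x$start), max(x$end - x$start),
              mean(x$masked_fraction)))
  invisible(x)
}

#' Extract interval sequences from a genome
#'
#' Pulls the sequence of each interval out of a named set of contig
#' sequences (as returned by [read_fasta()]), preserving case.
#'
#' @param genome named character vector of contig sequences.
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `group` (as returned by [read_bed()]).
#' @return an [enhancer_set()].
#' @export
extract_sequences <- function(genome, intervals) {
  miss <- setdiff(unique(intervals$chrom), names(genome))
  if (length(miss))
    stop("contigs absent from genome: ", paste(miss, collapse = ", "),
         call. = FALSE)
  too_long <- intervals$end > nchar(genome[intervals$chrom])
  if (any(too_long))
    stop("interval beyond contig end: ",
         paste(intervals$name[too_long], collapse = ", "), call. = FALSE)
  seq <- substring(genome[intervals$chrom], intervals$start + 1L,
                   intervals$end)
  enhancer_set(intervals$name, intervals$chrom, intervals$start,
               intervals$end, intervals$group, seq)
}

# Coerce an enhancer_set / named character vector to a named sequence vector.
as_seq_vector <- function(x) {
  if (inherits(x, "enhancer_set")) return(stats::setNames(x$seq, x$name))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected an enhancer_set or a named character vector", call. = FALSE)
}
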