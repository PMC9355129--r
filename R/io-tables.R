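#' Read enhancer intervals from a BED-like file
#'
#' Expects at least four tab-separated columns (`chrom`, `start`, `end`,
#' `name`); the group label (`Q`/`A`/`PAN`) is taken from `group_column`
#' (default column 5). Coordinates are 0-based half-open and kept verbatim.
#'
#' @param path path to the BED file (optionally gzipped).
#' @param group_column 1-based index of the column carrying the group label.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `group`.
#' @export
read_bed <- function(path, group_column = 5L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(x) < max(4L, group_column))
    stop("need at least ", max(4L, group_column), " columns, found ",
         ncol(x), call. = FALSE)
  start <- suppressWarnings(as.integer(x[[2L]]))
  end <- suppressWarnings(as.integer(x[[3L]]))
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinate on line ",
         which(is.na(start) | is.na(end))[1L], call. = FALSE)
  bad <- start >= end
  if (any(bad))
    stop("start >= end on line ", which(bad)[1L], call. = FALSE)
  group <- x[[group_column]]
  unk <- !(group %in% .GROUPS)
  if (any(unk))
    stop("unknown group label '", group[unk][1L], "' on line ",
         which(unk)[1L], call. = FALSE)
  if (anyDuplicated(x[[4L]]))
    stop("duplicate interval names", call. = FALSE)
  data.frame(chrom = x[[1L]], start = start, end = end, name = x[[4L]],
             group = group, stringsAsFactors = FALSE)
}

#' Write enhancer intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `name`, `group`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(
    intervals[, c("chrom", "start", "end", "name", "group")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read JASPAR-format position count matrices
#'
#' Parses the JASPAR (2016+) pfm text format: a header line `>ID name`
#' followed by four rows `A [ 1 2 ... ]`, `C [...]`, `G [...]`, `T [...]`
#' (bracket and base-letter decorations are optional).
#'
#' @param path path to the pfm text file (optionally gzipped).
#' @return list of position count matrices (see [pcm()]).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found", call. = FALSE)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1L]][1L]
    body <- lines[(starts[i] + 1L):(starts[i] + 4L)]
    if (starts[i] + 4L > length(lines) || any(grepl("^>", body)))
      stop("record ", id, ": expected 4 count rows", call. = FALSE)
    rows <- lapply(body, function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", l)
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
      if (anyNA(v)) stop("record ", id, ": non-numeric count", call. = FALSE)
      v
    })
    w <- lengths(rows)
    if (length(unique(w)) != 1L)
      stop("record ", id, ": row widths differ", call. = FALSE)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[i]] <- pcm(id, counts)
  }
  names(out) <- vapply(out, function(m) m$motif_id, character(1))
  out
}

#' Write position count matrices in JASPAR format
#'
#' @param pcms list of [pcm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pcms, path) {
  if (inherits(pcms, "pcm")) pcms <- list(pcms)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pcms) {
    writeLines(paste0(">", m$motif_id, " ", m$motif_id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read a gene table with differential-expression classes
#'
#' Expects a header-bearing TSV with columns `gene_id`, `direction`
#' (`+`/`-`), `pvalue`, and `enhancers` (semicolon-joined enhancer ids; may
#' be missing). A gene is classed `up` (`down`) when its p-value is below
#' `de_p_threshold` and its direction is `+` (`-`), otherwise `ns`.
#'
#' @param path path to the TSV (optionally gzipped).
#' @param de_p_threshold p-value cut separating differential from
#'   non-significant genes; the default mirrors the p < 0.01 rule used for
#'   the NSPC expression data.
#' @return data.frame with columns `gene_id`, `direction`, `pvalue`,
#'   `de_class`, and a list column `enhancer_ids`.
#' @export
read_gene_table <- function(path, de_p_threshold = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  need <- c("gene_id", "direction", "pvalue")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  p <- as.numeric(x$pvalue)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!"enhancers" %in% names(x)) {
    warning("no 'enhancers' column; all genes get empty enhancer lists")
    enh <- replicate(nrow(x), character(0), simplify = FALSE)
  } else {
    enh <- lapply(strsplit(ifelse(is.na(x$enhancers), "", x$enhancers), ";"),
                  function(v) v[nzchar(v)])
  }
  de_class <- ifelse(p < de_p_threshold,
                     ifelse(x$direction == "+", "up", "down"), "ns")
  out <- data.frame(gene_id = x$gene_id, direction = x$direction,
                    pvalue = p, de_class = de_class,
                    stringsAsFactors = FALSE)
  out$enhancer_ids <- enh
  out
}
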