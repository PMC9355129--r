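# PWM construction, best-hit scanning, IUPAC matching, motif comparison.

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

#' Reverse complement
#'
#' Handles the full IUPAC alphabet and preserves case, so soft-masked
#' sequence stays soft-masked.
#'
#' @param x character vector of DNA/IUPAC strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  y <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
              "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(y, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Position count matrix
#'
#' @param motif_id motif identifier.
#' @param counts 4 x w numeric matrix of nonnegative counts, rows A, C, G, T.
#' @return object of class `pcm`.
#' @export
pcm <- function(motif_id, counts) {
  .stop_scalar(motif_id, "motif_id")
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("counts must have 4 rows (A, C, G, T)", call. = FALSE)
  if (ncol(counts) < 4L)
    stop("motif width must be >= 4", call. = FALSE)
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (any(colSums(counts) <= 0))
    stop("every column must have positive total count", call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, counts = counts,
                 width = ncol(counts)),
            class = "pcm")
}

#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("pcm %s (width %d), consensus %s\n", x$motif_id, x$width,
              consensus(x)))
  print(round(x$counts, 2))
  invisible(x)
}

#' Consensus string of a count or weight matrix
#'
#' Column-wise argmax base; ties resolved in A < C < G < T order.
#'
#' @param x a [pcm()] or [counts_to_pwm()] object.
#' @return single consensus string.
#' @export
consensus <- function(x) {
  m <- if (inherits(x, "pwm")) x$log_odds else x$counts
  paste(c("A", "C", "G", "T")[apply(m, 2, which.max)], collapse = "")
}

#' Build a log-odds position weight matrix from counts
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (column total + pseudocount)`; log-odds are `log2(probability /
#' background)`, so a column with equal counts under a uniform background
#' scores exactly 0. The attainable score range (sum of column maxima /
#' minima) is stored for min-max rescaling of hit scores.
#'
#' @param x a [pcm()].
#' @param pseudocount positive smoothing mass, distributed across bases in
#'   proportion to the background.
#' @param background base composition (A, C, G, T), strictly positive,
#'   summing to 1.
#' @return object of class `pwm` with elements `log_odds`, `probs`,
#'   `min_score`, `max_score`.
#' @export
#' @examples
#' m <- pcm("ex", matrix(c(10, 0, 0, 0), 4, 6,
#'          dimnames = list(c("A", "C", "G", "T"), NULL)))
#' counts_to_pwm(m)$log_odds[, 1]
counts_to_pwm <- function(x, pseudocount = 1, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pcm"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0", call. = FALSE)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 strictly positive probabilities",
         call. = FALSE)
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1", call. = FALSE)
  counts <- x$counts
  tot <- colSums(counts)
  probs <- sweep(counts + pseudocount * background, 2, tot + pseudocount,
                 `/`)
  log_odds <- log2(probs / background)
  dimnames(log_odds) <- dimnames(probs) <- dimnames(counts)
  structure(list(motif_id = x$motif_id, log_odds = log_odds, probs = probs,
                 background = background, pseudocount = pseudocount,
                 width = ncol(counts),
                 min_score = sum(apply(log_odds, 2, min)),
                 max_score = sum(apply(log_odds, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (width %d, bits), consensus %s\n", x$motif_id,
              x$width, consensus(x)))
  cat(sprintf("  score range [%.3f, %.3f]\n", x$min_score, x$max_score))
  invisible(x)
}

# Score every valid placement of a log-odds vector on an encoded sequence.
# lov = as.vector(log_odds); placements touching a masked base score -Inf.
.scan_scores <- function(code, lov, w) {
  n <- length(code) - w + 1L
  sc <- numeric(n)
  bad <- integer(n)
  for (j in seq_len(w)) {
    b <- code[j:(j + n - 1L)]
    m <- b == 0L
    if (any(m)) {
      b[m] <- 1L
      bad <- bad + m
    }
    sc <- sc + lov[(j - 1L) * 4L + b]
  }
  if (any(bad > 0L)) sc[bad > 0L] <- -Inf
  sc
}

.rc_lov <- function(log_odds) as.vector(log_odds[4:1, ncol(log_odds):1])

#' Best-scoring motif placement in one sequence
#'
#' Scores every placement of the PWM on the given sequence (and its reverse
#' complement when `strands = "both"`) and returns only the maximally scoring
#' one. Placements touching a masked base (lowercase or `N`) are invalid.
#' Ties are broken by smallest offset, then by the plus strand. A sequence
#' whose every placement is masked yields the sentinel row with `valid =
#' FALSE` and `NA` coordinates.
#'
#' @param pwm a [counts_to_pwm()] object.
#' @param seq a single sequence string.
#' @param strands scan both strands (`"both"`, default) or only the plus
#'   strand (`"plus"`).
#' @param id sequence id recorded in the result.
#' @return one-row data.frame: `enhancer_id`, `motif_id`, `offset` (0-based),
#'   `strand`, `width`, `score` (bits), `relative_score` (min-max rescaled to
#'   \[0, 1\]), `valid`.
#' @export
scan_best_hit <- function(pwm, seq, strands = c("both", "plus"),
                          id = "seq") {
  stopifnot(inherits(pwm, "pwm"))
  strands <- match.arg(strands)
  .stop_scalar(seq, "seq")
  w <- pwm$width
  if (nchar(seq) < w)
    stop("sequence shorter than motif width", call. = FALSE)
  code <- encode_dna(seq)
  sp <- .scan_scores(code, as.vector(pwm$log_odds), w)
  best_off <- NA_integer_; best_strand <- NA_character_
  best <- max(sp)
  if (is.finite(best)) {
    best_off <- which(sp == best)[1L] - 1L
    best_strand <- "+"
  }
  if (strands == "both") {
    sm <- .scan_scores(code, .rc_lov(pwm$log_odds), w)
    bm <- max(sm)
    if (is.finite(bm) && (is.na(best_off) || bm > best ||
                          (bm == best && which(sm == bm)[1L] - 1L < best_off))) {
      best <- bm
      best_off <- which(sm == bm)[1L] - 1L
      best_strand <- "-"
    }
  }
  if (is.na(best_off)) {
    return(data.frame(enhancer_id = id, motif_id = pwm$motif_id,
                      offset = NA_integer_, strand = NA_character_,
                      width = w, score = NA_real_,
                      relative_score = NA_real_, valid = FALSE,
                      stringsAsFactors = FALSE))
  }
  rng <- pwm$max_score - pwm$min_score
  rel <- if (rng > 0) (best - pwm$min_score) / rng else 1
  data.frame(enhancer_id = id, motif_id = pwm$motif_id, offset = best_off,
             strand = best_strand, width = w, score = best,
             relative_score = rel, valid = TRUE, stringsAsFactors = FALSE)
}

#' Best hits of one PWM across a sequence set
#'
#' Vectorised driver for [scan_best_hit()]: one row per sequence.
#'
#' @param pwm a [counts_to_pwm()] object.
#' @param seqs an [enhancer_set()] or named character vector.
#' @param strands `"both"` or `"plus"`.
#' @return data.frame with the columns of [scan_best_hit()].
#' @export
scan_sequences <- function(pwm, seqs, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  v <- as_seq_vector(seqs)
  out <- vector("list", length(v))
  for (i in seq_along(v))
    out[[i]] <- scan_best_hit(pwm, v[[i]], strands, id = names(v)[i])
  do.call(rbind, out)
}

# Logical presence call per sequence: does the best valid hit reach the
# relative-score cut? Fast path used by the bootstrap machinery; agrees
# with scan_sequences() by construction (same .scan_scores core).
presence_calls <- function(pwm, seqs, threshold = 0.8,
                           strands = "both") {
  v <- as_seq_vector(seqs)
  lov <- as.vector(pwm$log_odds)
  rcv <- .rc_lov(pwm$log_odds)
  w <- pwm$width
  cut <- pwm$min_score + threshold * (pwm$max_score - pwm$min_score)
  vapply(v, function(s) {
    if (nchar(s) < w)
      stop("sequence shorter than motif width", call. = FALSE)
    code <- encode_dna(s)
    best <- max(.scan_scores(code, lov, w))
    if (strands == "both")
      best <- max(best, max(.scan_scores(code, rcv, w)))
    is.finite(best) && best >= cut
  }, logical(1), USE.NAMES = FALSE)
}

iupac_to_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  bad <- !(chars %in% names(IUPAC))
  if (any(bad))
    stop("illegal IUPAC code: ", paste(unique(chars[bad]), collapse = ", "),
         call. = FALSE)
  paste(vapply(chars, function(ch) {
    b <- IUPAC[[ch]]
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Find all matches of an IUPAC pattern
#'
#' Exact degenerate matching; masked (lowercase) bases and `N` never match.
#' Minus-strand matches are reported by the 0-based start of the matching
#' window on the given (plus) strand.
#'
#' @param pattern IUPAC string, e.g. `"CTTTGWW"`.
#' @param seq a single sequence string.
#' @param strands `"both"` or `"plus"`.
#' @return data.frame with columns `offset` (0-based) and `strand`, sorted
#'   by offset then strand.
#' @export
#' @examples
#' match_iupac("CTTTGWW", "ACTTTGTTA", strands = "plus")
match_iupac <- function(pattern, seq, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  .stop_scalar(seq, "seq")
  find <- function(rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  off <- find(iupac_to_regex(pattern))
  out <- data.frame(offset = off, strand = rep("+", length(off)),
                    stringsAsFactors = FALSE)
  if (strands == "both") {
    offm <- find(iupac_to_regex(revcomp(pattern)))
    # palindromic patterns: don't double-report the same window
    offm <- if (identical(revcomp(pattern), pattern)) integer(0) else offm
    out <- rbind(out, data.frame(offset = offm,
                                 strand = rep("-", length(offm)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Compare two count matrices by column correlation
#'
#' Slides the target over the query in both orientations (as-is and
#' reverse-complemented) and scores each alignment by the mean per-column
#' Pearson correlation of column frequency vectors over the overlap; a
#' column with zero variance (e.g. uniform) contributes correlation 0.
#' Ties are broken by smaller `|offset|`, then by the `same` orientation.
#'
#' @param query,target [pcm()] objects.
#' @param min_overlap minimum number of overlapping columns (>= 4).
#' @return object of class `motif_match`: `query_id`, `target_id`, `offset`
#'   (signed shift of target column 1 relative to query column 1),
#'   `orientation` (`same`/`revcomp`), `similarity`, `overlap`.
#' @export
compare_motifs <- function(query, target, min_overlap = 4L) {
  stopifnot(inherits(query, "pcm"), inherits(target, "pcm"))
  if (min_overlap < 4L) stop("min_overlap must be >= 4", call. = FALSE)
  wq <- query$width; wt <- target$width
  if (wq < min_overlap || wt < min_overlap)
    stop("motif narrower than min_overlap", call. = FALSE)
  fq <- sweep(query$counts, 2, colSums(query$counts), `/`)
  ft0 <- sweep(target$counts, 2, colSums(target$counts), `/`)
  col_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  best <- NULL
  for (orient in c("same", "revcomp")) {
    ft <- if (orient == "same") ft0 else ft0[4:1, wt:1, drop = FALSE]
    for (d in seq(-(wt - min_overlap), wq - min_overlap)) {
      qi <- max(1L, 1L + d):min(wq, wt + d)
      ti <- qi - d
      sim <- mean(vapply(seq_along(qi), function(k)
        col_cor(fq[, qi[k]], ft[, ti[k]]), numeric(1)))
      cand <- list(query_id = query$motif_id, target_id = target$motif_id,
                   offset = d, orientation = orient, similarity = sim,
                   overlap = length(qi))
      if (is.null(best) || sim > best$similarity + 1e-12 ||
          (abs(sim - best$similarity) <= 1e-12 &&
           (abs(d) < abs(best$offset) ||
            (abs(d) == abs(best$offset) && orient == "same" &&
             best$orientation == "revcomp"))))
        best <- cand
    }
  }
  structure(best, class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("%s ~ %s: similarity %.3f (%s, offset %+d, overlap %d)\n",
              x$query_id, x$target_id, x$similarity, x$orientation,
              x$offset, x$overlap))
  invisible(x)
}

#' Bundled synthetic motif library
#'
#' A small JASPAR-format library of synthetic count matrices whose consensi
#' contain the consensus words reported for LEF1/TCF (CTTTGT within the WRE
#' CTTTGWW), NFIX (TTGGCA), SOX2, ASCL1 and ASCL2 (CAGCTG E-box cores).
#' These are constructed stand-ins, not matrices downloaded from JASPAR.
#'
#' @return named list of [pcm()] objects.
#' @export
default_motif_library <- function() {
  read_jaspar(system.file("extdata", "synthetic_motif_library.jaspar",
                          package = "enhmotif", mustWork = TRUE))
}

#' Write motif hits as BED6
#'
#' The BED score column is `round(1000 * relative_score)`.
#'
#' @param hits data.frame from [scan_sequences()] with valid hits.
#' @param intervals data.frame mapping `name` to `chrom` and `start`, used
#'   to lift sequence-relative offsets to genomic coordinates; if `NULL`,
#'   offsets are written relative to each sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, intervals = NULL) {
  h <- hits[hits$valid, , drop = FALSE]
  chrom <- h$enhancer_id
  start <- h$offset
  if (!is.null(intervals)) {
    i <- match(h$enhancer_id, intervals$name)
    chrom <- intervals$chrom[i]
    start <- intervals$start[i] + h$offset
  }
  utils::write.table(
    data.frame(chrom, start, start + h$width, h$motif_id,
               round(1000 * h$relative_score), h$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
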