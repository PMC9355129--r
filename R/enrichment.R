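# Flank controls, bootstrap enrichment tests, positional bias.

#' Length-matched flanking control sequences
#'
#' For each enhancer interval, takes the two immediately adjacent regions of
#' the same length (upstream and downstream) from the supplied genome.
#' Controls inherit the enhancer's group. A flank running off its contig is
#' dropped; a flank overlapping any enhancer of the input set is dropped;
#' both events are reported via `message()`.
#'
#' @param intervals data.frame of enhancer intervals (`chrom`, `start`,
#'   `end`, `name`, `group`).
#' @param genome named character vector of contig sequences.
#' @return an [enhancer_set()] of controls named `<name>_L` / `<name>_R`.
#' @export
make_flank_controls <- function(intervals, genome) {
  len <- intervals$end - intervals$start
  cand <- rbind(
    data.frame(chrom = intervals$chrom, start = intervals$start - len,
               end = intervals$start, name = paste0(intervals$name, "_L"),
               group = intervals$group, stringsAsFactors = FALSE),
    data.frame(chrom = intervals$chrom, start = intervals$end,
               end = intervals$end + len,
               name = paste0(intervals$name, "_R"),
               group = intervals$group, stringsAsFactors = FALSE))
  clen <- nchar(genome[cand$chrom])
  off_contig <- cand$start < 0L | cand$end > clen | is.na(clen)
  if (any(off_contig))
    message(sum(off_contig), " flank(s) dropped: outside contig bounds")
  cand <- cand[!off_contig, , drop = FALSE]
  overlaps_enh <- vapply(seq_len(nrow(cand)), function(i) {
    same <- intervals$chrom == cand$chrom[i]
    any(same & intervals$start < cand$end[i] & intervals$end > cand$start[i])
  }, logical(1))
  if (any(overlaps_enh))
    message(sum(overlaps_enh), " flank(s) dropped: overlap an enhancer")
  cand <- cand[!overlaps_enh, , drop = FALSE]
  extract_sequences(genome, cand)
}

#' Bootstrap test of motif enrichment in enhancers versus controls
#'
#' The observed statistic is the difference in motif presence fractions
#' (enhancers minus controls), where a sequence is motif-positive when its
#' best hit reaches `threshold` on the min-max relative-score scale. The
#' null distribution is built by drawing, `B` times, one enhancer-sized and
#' one control-sized resample (both with replacement from the control pool)
#' and recomputing the difference; the p-value is the +1-smoothed upper tail
#' `(1 + #{null >= observed}) / (B + 1)`.
#'
#' @param pwm a [counts_to_pwm()] object.
#' @param enhancers,controls [enhancer_set()]s or named character vectors.
#' @param threshold relative-score presence cut in (0, 1]; 0.8 mirrors the
#'   80 percent-of-maximum convention of common PWM scanners.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed; results are bit-reproducible given seed and input
#'   order (inputs are resampled in the order given).
#' @param strands passed to the scanner.
#' @param group label recorded in the result.
#' @return object of class `enrichment_result`.
#' @export
bootstrap_enrichment <- function(pwm, enhancers, controls, threshold = 0.8,
                                 B = 1000L, seed = 1L,
                                 strands = "both", group = "pooled") {
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  pos <- presence_calls(pwm, enhancers, threshold, strands)
  ctl <- presence_calls(pwm, controls, threshold, strands)
  if (!length(pos) || !length(ctl))
    stop("both sequence sets must be non-empty", call. = FALSE)
  obs <- mean(pos) - mean(ctl)
  n <- length(pos); m <- length(ctl)
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b)
      mean(sample(ctl, n, replace = TRUE)) -
        mean(sample(ctl, m, replace = TRUE)), numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (B + 1)
  structure(list(motif_id = pwm$motif_id, group = group, statistic = obs,
                 frac_enhancer = mean(pos), frac_control = mean(ctl),
                 n_pos = n, n_ctrl = m, B = as.integer(B),
                 bootstrap_p = p, threshold = threshold,
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: presence %.3f (n=%d) vs %.3f (n=%d); diff %+.3f, bootstrap p = %.4g (B=%d)\n",
    x$motif_id, x$group, x$frac_enhancer, x$n_pos, x$frac_control, x$n_ctrl,
    x$statistic, x$bootstrap_p, x$B))
  invisible(x)
}

#' Pairwise bootstrap comparison of motif presence between groups
#'
#' For each ordered pair of groups, tests whether the first group's motif
#' presence fraction exceeds the second's. The null pools the two groups'
#' presence calls and draws group-sized resamples with replacement.
#'
#' @param pwm a [counts_to_pwm()] object.
#' @param groups named list of [enhancer_set()]s / named character vectors.
#' @param threshold,B,seed,strands as in [bootstrap_enrichment()].
#' @return data.frame, one row per ordered group pair, with presence
#'   fractions, the difference statistic, and the bootstrap p-value.
#' @export
group_differential_enrichment <- function(pwm, groups, threshold = 0.8,
                                          B = 1000L, seed = 1L,
                                          strands = "both") {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- vapply(groups, function(g)
    length(as_seq_vector(g)), integer(1))
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  if (any(sizes < 20L))
    warning("group(s) smaller than 20 sequences: low power")
  calls <- lapply(groups, presence_calls, pwm = pwm, threshold = threshold,
                  strands = strands)
  pairs <- expand.grid(g1 = names(groups), g2 = names(groups),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$g1 != pairs$g2, , drop = FALSE]
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- calls[[pairs$g1[i]]]; b <- calls[[pairs$g2[i]]]
    obs <- mean(a) - mean(b)
    pool <- c(a, b)
    null <- with_seed(substream(seed, paste0(pairs$g1[i], ">", pairs$g2[i])),
      vapply(seq_len(B), function(k)
        mean(sample(pool, length(a), replace = TRUE)) -
          mean(sample(pool, length(b), replace = TRUE)), numeric(1)))
    data.frame(motif_id = pwm$motif_id, group1 = pairs$g1[i],
               group2 = pairs$g2[i], frac1 = mean(a), frac2 = mean(b),
               statistic = obs,
               bootstrap_p = (1 + sum(null >= obs)) / (B + 1),
               B = as.integer(B), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Test for central positional bias of motif hits
#'
#' Compares the share of hits whose midpoint falls in the central window of
#' their sequence against the uniform expectation, with an exact binomial
#' upper-tail p-value.
#'
#' @param hits data.frame from [scan_sequences()] (valid rows are used);
#'   needs `enhancer_id`, `offset`, `width`.
#' @param lengths named integer vector of sequence lengths.
#' @param central_window_fraction width of the central window as a fraction
#'   of sequence length, in (0, 1).
#' @return list of class `positional_bias`: `central_fraction`,
#'   `expected_fraction`, `n_hits`, `p`.
#' @export
positional_bias <- function(hits, lengths, central_window_fraction = 0.5) {
  if (central_window_fraction <= 0 || central_window_fraction >= 1)
    stop("central_window_fraction must lie in (0, 1)", call. = FALSE)
  h <- hits[hits$valid & !is.na(hits$offset), , drop = FALSE]
  if (!nrow(h)) stop("no hits", call. = FALSE)
  len <- lengths[h$enhancer_id]
  if (anyNA(len)) stop("missing sequence length(s)", call. = FALSE)
  rel_mid <- (h$offset + h$width / 2) / len
  lo <- 0.5 - central_window_fraction / 2
  hi <- 0.5 + central_window_fraction / 2
  k <- sum(rel_mid >= lo & rel_mid < hi)
  n <- nrow(h)
  structure(list(motif_id = h$motif_id[1L],
                 central_fraction = k / n,
                 expected_fraction = central_window_fraction,
                 n_hits = n,
                 p = stats::pbinom(k - 1, n, central_window_fraction,
                                   lower.tail = FALSE)),
            class = "positional_bias")
}

#' @export
print.positional_bias <- function(x, ...) {
  cat(sprintf(
    "%s: central fraction %.3f (expected %.3f, n=%d), binomial p = %.4g\n",
    x$motif_id, x$central_fraction, x$expected_fraction, x$n_hits, x$p))
  invisible(x)
}
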