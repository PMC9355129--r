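# Anchor-flank window extraction and DREME-style exact-word discovery.

#' Extract fixed-width windows flanking anchor motif matches
#'
#' Finds every plus-strand occurrence of the anchor pattern and takes the
#' `half_width` bases immediately left and right of it (anchor excluded),
#' truncated at sequence ends; zero-length windows are dropped. Masked bases
#' are carried through as-is (word counting never matches them).
#'
#' @param seqs an [enhancer_set()] or named character vector.
#' @param anchor IUPAC anchor pattern; the default is the CTTTGT core
#'   recognised by LEF1/TCF factors.
#' @param half_width window width on each side of the anchor, in bp.
#' @return data.frame of class `flank_windows` (`enhancer_id`,
#'   `anchor_offset`, `side`, `seq`) with attributes `anchor` and
#'   `half_width`.
#' @export
extract_flanks <- function(seqs, anchor = "CTTTGT", half_width = 15L) {
  v <- as_seq_vector(seqs)
  out <- list()
  for (i in seq_along(v)) {
    s <- v[[i]]
    occ <- match_iupac(anchor, s, strands = "plus")
    if (!nrow(occ)) next
    L <- nchar(s)
    alen <- nchar(anchor)
    for (o in occ$offset) {
      left <- substr(s, max(0L, o - half_width) + 1L, o)
      right <- substr(s, o + alen + 1L, min(L, o + alen + half_width))
      if (nzchar(left))
        out[[length(out) + 1L]] <- data.frame(
          enhancer_id = names(v)[i], anchor_offset = o, side = "left",
          seq = left, stringsAsFactors = FALSE)
      if (nzchar(right))
        out[[length(out) + 1L]] <- data.frame(
          enhancer_id = names(v)[i], anchor_offset = o, side = "right",
          seq = right, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no anchor occurrences found")
    res <- data.frame(enhancer_id = character(0),
                      anchor_offset = integer(0), side = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  } else res <- do.call(rbind, out)
  attr(res, "anchor") <- anchor
  attr(res, "half_width") <- as.integer(half_width)
  class(res) <- c("flank_windows", "data.frame")
  res
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: each output sequence is a uniform random
#' permutation of the input's dinucleotide multiset (a random Eulerian walk
#' on the transition multigraph), so first-order composition is preserved
#' exactly. Case-sensitive, so masked letters stay masked.
#'
#' @param seqs character vector of sequences.
#' @param seed RNG seed.
#' @return character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seqs, seed = 1L) {
  shuffle1 <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    n <- length(ch)
    if (n <= 3L) return(s)
    verts <- unique(ch)
    edges <- split(ch[-1L], factor(ch[-n], levels = verts))
    last_v <- ch[n]
    # choose a random "last out-edge" per vertex forming an arborescence
    # into the final vertex, then shuffle the remaining out-edges
    repeat {
      last_edge <- vapply(verts, function(v) {
        if (v == last_v || !length(edges[[v]])) NA_character_
        else sample(edges[[v]], 1L)
      }, character(1))
      ok <- TRUE
      for (v in verts) {
        if (v == last_v || !length(edges[[v]])) next
        seen <- character(0); cur <- v
        while (cur != last_v) {
          if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    lists <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (!length(e)) return(character(0))
      if (!is.na(last_edge[[v]])) {
        k <- match(last_edge[[v]], e)
        e <- e[-k]
      }
      e <- if (length(e) > 1L) sample(e) else e
      c(e, if (!is.na(last_edge[[v]])) last_edge[[v]])
    })
    names(lists) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    for (i in 2:n) {
      nxt <- lists[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  }
  with_seed(seed, vapply(seqs, shuffle1, character(1), USE.NAMES = FALSE))
}

# Distinct words of lengths k_min..k_max in one window, collapsed to the
# lexicographically smaller of word/reverse-complement; runs through masked
# or N bases are skipped.
.window_words <- function(seq, k_min, k_max) {
  L <- nchar(seq)
  if (L < k_min) return(character(0))
  words <- character(0)
  for (k in k_min:min(k_max, L)) {
    sub <- substring(seq, 1:(L - k + 1L), k:L)
    sub <- sub[grepl("^[ACGT]+$", sub)]
    if (!length(sub)) next
    rc <- revcomp(sub)
    words <- c(words, ifelse(sub <= rc, sub, rc))
  }
  unique(words)
}

#' Discover words enriched in positive versus negative windows
#'
#' A desk-scale analogue of DREME's discriminative motif discovery: every
#' exact word of length `k_min`..`k_max` occurring in the positive windows
#' (word and reverse complement collapsed) is scored by a one-sided Fisher
#' exact test of per-window presence in positive versus negative windows;
#' the E-value is the p-value times the number of distinct candidate words
#' examined. The best word is reported, positive windows containing it are
#' removed, and the search repeats until the E-value threshold or
#' `max_motifs` is reached. Ranking is deterministic (E-value, then
#' lexicographic).
#'
#' Exact-word counting fragments a single planted motif into nested words
#' (a word and its subwords) whose p-values differ only through background
#' noise, so the raw ranking can surface a subword of the true motif. As a
#' deterministic analogue of the generalization step of regular-expression
#' discovery tools, the selected word is therefore promoted to the most
#' specific significant candidate that contains it (up to reverse
#' complement) and still accounts for at least `subsume_frac` of its
#' positive windows: any window carrying the longer word necessarily
#' carries the shorter one, so a coverage near 1 means the short word is
#' just a fragment of the long one, while genuine independent short-word
#' signal keeps coverage low and blocks the promotion.
#'
#' @param pos positive windows: a [extract_flanks()] result or character
#'   vector of window sequences.
#' @param neg negative windows; if `NULL`, a seeded dinucleotide shuffle of
#'   the positive windows is used.
#' @param k_min,k_max word lengths to consider (4..8).
#' @param e_threshold report words with E-value at or below this.
#' @param max_motifs maximum number of words reported.
#' @param subsume_frac minimum fraction of the selected word's positive
#'   windows a longer containing word must cover to replace it.
#' @param seed seed for the shuffled negative set.
#' @return data.frame of class `word_motifs`: `word`, `width`, `pos_count`,
#'   `pos_total`, `neg_count`, `neg_total`, `p`, `e_value`. Attribute
#'   `n_candidates` records the number of distinct words examined.
#' @export
discover_words <- function(pos, neg = NULL, k_min = 4L, k_max = 8L,
                           e_threshold = 0.05, max_motifs = 10L,
                           subsume_frac = 0.9, seed = 1L) {
  if (k_min < 4L || k_max > 8L || k_min > k_max)
    stop("need 4 <= k_min <= k_max <= 8", call. = FALSE)
  pos_seq <- if (is.data.frame(pos)) pos$seq else as.character(pos)
  if (!length(pos_seq)) stop("positive set is empty", call. = FALSE)
  neg_seq <- if (is.null(neg)) dinucleotide_shuffle(pos_seq, seed = seed)
             else if (is.data.frame(neg)) neg$seq else as.character(neg)
  if (!length(neg_seq)) stop("negative set is empty", call. = FALSE)
  pos_sets <- lapply(pos_seq, .window_words, k_min = k_min, k_max = k_max)
  neg_sets <- lapply(neg_seq, .window_words, k_min = k_min, k_max = k_max)
  if (!any(lengths(pos_sets)))
    stop("all positive windows shorter than k_min", call. = FALSE)
  candidates <- unique(unlist(pos_sets))
  n_cand <- length(candidates)
  neg_tab <- table(factor(unlist(neg_sets), levels = candidates))
  n2 <- length(neg_sets)
  found <- list()
  active <- rep(TRUE, length(pos_sets))
  repeat {
    n1 <- sum(active)
    if (!n1 || length(found) >= max_motifs) break
    pos_tab <- table(factor(unlist(pos_sets[active]), levels = candidates))
    a <- as.integer(pos_tab)
    b <- as.integer(neg_tab)
    p <- stats::phyper(a - 1L, a + b, n1 + n2 - a - b, n1,
                       lower.tail = FALSE)
    e <- p * n_cand
    ord <- order(e, candidates)
    best <- ord[1L]
    if (e[best] > e_threshold) break
    # promote to the most specific significant word this one fragments
    repeat {
      w <- candidates[best]
      longer <- which(nchar(candidates) > nchar(w) & e <= e_threshold &
                        (grepl(w, candidates, fixed = TRUE) |
                           grepl(revcomp(w), candidates, fixed = TRUE)) &
                        a >= subsume_frac * a[best])
      longer <- setdiff(longer, best)
      if (!length(longer)) break
      best <- longer[order(p[longer], candidates[longer])][1L]
    }
    w <- candidates[best]
    found[[length(found) + 1L]] <- data.frame(
      word = w, width = nchar(w), pos_count = a[best], pos_total = n1,
      neg_count = b[best], neg_total = n2, p = p[best],
      e_value = e[best], stringsAsFactors = FALSE)
    has_w <- vapply(pos_sets, function(s) w %in% s, logical(1))
    active <- active & !has_w
  }
  res <- if (length(found)) do.call(rbind, found) else
    data.frame(word = character(0), width = integer(0),
               pos_count = integer(0), pos_total = integer(0),
               neg_count = integer(0), neg_total = integer(0),
               p = numeric(0), e_value = numeric(0),
               stringsAsFactors = FALSE)
  attr(res, "n_candidates") <- n_cand
  class(res) <- c("word_motifs", "data.frame")
  res
}

#' Convert an IUPAC word to a degenerate count matrix
#'
#' Each matched base gets weight 1 (so `W` weights A and T equally); `N`
#' spreads weight 1 uniformly over the four bases.
#'
#' @param word IUPAC string.
#' @return a [pcm()] with `motif_id = word`.
#' @export
word_to_pcm <- function(word) {
  chars <- strsplit(word, "")[[1L]]
  counts <- vapply(chars, function(ch) {
    b <- IUPAC[[ch]]
    if (is.null(b)) stop("illegal IUPAC code: ", ch, call. = FALSE)
    if (identical(ch, "N")) return(rep(0.25, 4))
    as.numeric(c("A", "C", "G", "T") %in% b)
  }, numeric(4))
  pcm(word, counts)
}

#' Match discovered words against a motif library
#'
#' Converts each word to a degenerate count matrix ([word_to_pcm()]) and
#' reports its best library match by [compare_motifs()]. Words shorter than
#' `min_overlap` are skipped with a message.
#'
#' @param words a [discover_words()] result or character vector of words.
#' @param library named list of [pcm()] objects.
#' @param min_overlap minimum aligned columns.
#' @return data.frame: `word`, `target_id`, `offset`, `orientation`,
#'   `similarity`, `overlap`.
#' @export
words_to_known_motifs <- function(words, library, min_overlap = 4L) {
  if (!length(library)) stop("library is empty", call. = FALSE)
  wvec <- if (is.data.frame(words)) words$word else as.character(words)
  short <- nchar(wvec) < min_overlap
  if (any(short)) {
    message(sum(short), " word(s) shorter than min_overlap skipped")
    wvec <- wvec[!short]
  }
  out <- lapply(wvec, function(w) {
    q <- word_to_pcm(w)
    matches <- lapply(library, compare_motifs, query = q,
                      min_overlap = min_overlap)
    sims <- vapply(matches, function(m) m$similarity, numeric(1))
    best <- matches[[which.max(sims)]]
    data.frame(word = w, target_id = best$target_id, offset = best$offset,
               orientation = best$orientation, similarity = best$similarity,
               overlap = best$overlap, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
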