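# Independent oracles and small random-instance generators used across the
# suite. These deliberately avoid the package's vectorised code paths:
# everything here is naive character-by-character work.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len, masked_runs = 0) {
  s <- paste(sample(BASES, len, replace = TRUE), collapse = "")
  if (masked_runs > 0) {
    for (i in seq_len(masked_runs)) {
      k <- sample(2:5, 1)
      if (len <= k) next
      at <- sample(len - k, 1)
      substr(s, at, at + k - 1) <- tolower(substr(s, at, at + k - 1))
    }
  }
  s
}

random_pcm <- function(id = "rnd", width = sample(4:10, 1)) {
  counts <- matrix(sample(0:50, 4 * width, replace = TRUE), 4, width)
  # guarantee positive column sums
  counts[1, colSums(counts) == 0] <- 1
  rownames(counts) <- BASES
  pcm(id, counts)
}

# Character-by-character best-hit scan: loops over offsets and strands,
# scoring each placement base by base from the log-odds matrix.
naive_scan <- function(pwm, seq, strands = "both") {
  w <- pwm$width
  chars <- strsplit(seq, "")[[1]]
  n <- nchar(seq) - w + 1
  best <- NULL
  strand_set <- if (strands == "both") c("+", "-") else "+"
  for (strand in strand_set) {
    lo <- if (strand == "+") pwm$log_odds else
      pwm$log_odds[4:1, w:1, drop = FALSE]
    for (o in seq_len(n)) {
      win <- chars[o:(o + w - 1)]
      if (any(!win %in% BASES)) next  # masked or N
      sc <- 0
      for (j in seq_len(w)) sc <- sc + unname(lo[match(win[j], BASES), j])
      better <- !is.null(best) &&
        (sc > best$score ||
           (sc == best$score && o - 1 < best$offset) ||
           (sc == best$score && o - 1 == best$offset &&
              strand == "+" && best$strand == "-"))
      if (is.null(best) || better)
        best <- list(score = sc, offset = o - 1, strand = strand)
    }
  }
  best %||% list(score = NA, offset = NA, strand = NA)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Line-accumulating FASTA parser.
naive_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0); cur <- NULL
  for (l in lines) {
    if (startsWith(l, ">")) {
      ids <- c(ids, strsplit(sub("^>", "", l), "\\s+")[[1]][1])
      seqs <- c(seqs, ""); cur <- length(seqs)
    } else seqs[cur] <- paste0(seqs[cur], l)
  }
  stats::setNames(seqs, ids)
}

# Expand an IUPAC pattern into all concrete words it denotes.
iupac_expand <- function(pattern) {
  sets <- lapply(strsplit(pattern, "")[[1]], function(ch)
    switch(ch, A = "A", C = "C", G = "G", T = "T",
           R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
           W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
           B = c("C", "G", "T"), D = c("A", "G", "T"),
           H = c("A", "C", "T"), V = c("A", "C", "G"), N = BASES))
  apply(do.call(expand.grid, rev(sets)), 1,
        function(r) paste(rev(r), collapse = ""))
}

# Find all occurrences of any concrete word by sliding a window.
naive_iupac_match <- function(pattern, seq, strands = "both") {
  find_words <- function(words, k) {
    n <- nchar(seq) - k + 1
    if (n < 1) return(integer(0))
    wins <- substring(seq, 1:n, k:nchar(seq))
    which(wins %in% words) - 1L
  }
  k <- nchar(pattern)
  off <- find_words(iupac_expand(pattern), k)
  out <- data.frame(offset = off, strand = rep("+", length(off)),
                    stringsAsFactors = FALSE)
  if (strands == "both" && !identical(revcomp(pattern), pattern)) {
    offm <- find_words(iupac_expand(revcomp(pattern)), k)
    out <- rbind(out, data.frame(offset = offm,
                                 strand = rep("-", length(offm)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Exhaustive motif-comparison oracle: recomputes mean column correlation
# for every alignment with plain loops and cor().
naive_compare <- function(query, target, min_overlap = 4) {
  fq <- sweep(query$counts, 2, colSums(query$counts), `/`)
  ft0 <- sweep(target$counts, 2, colSums(target$counts), `/`)
  wq <- ncol(fq); wt <- ncol(ft0)
  best <- NULL
  for (orient in c("same", "revcomp")) {
    ft <- if (orient == "same") ft0 else ft0[4:1, wt:1, drop = FALSE]
    for (d in (-(wt - min_overlap)):(wq - min_overlap)) {
      qi <- max(1, 1 + d):min(wq, wt + d)
      sims <- numeric(0)
      for (k in seq_along(qi)) {
        a <- fq[, qi[k]]; b <- ft[, qi[k] - d]
        sims <- c(sims, if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b))
      }
      s <- mean(sims)
      if (is.null(best) || s > best$similarity + 1e-12 ||
          (abs(s - best$similarity) <= 1e-12 &&
             (abs(d) < abs(best$offset) ||
                (abs(d) == abs(best$offset) && orient == "same" &&
                   best$orientation == "revcomp"))))
        best <- list(offset = d, orientation = orient, similarity = s)
    }
  }
  best
}

# Count dinucleotides of a string (ordered pairs), for shuffle checks.
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# Plant a word into a background string at a given 0-based offset.
plant_word <- function(seq, word, offset0) {
  paste0(substr(seq, 1, offset0), word,
         substr(seq, offset0 + nchar(word) + 1, nchar(seq)))
}

# A small sharp test matrix whose consensus is the given word.
word_pcm_sharp <- function(word, id = word, major = 97) {
  chars <- strsplit(word, "")[[1]]
  counts <- vapply(chars, function(ch) {
    v <- rep(1, 4); v[match(ch, BASES)] <- major; v
  }, numeric(4))
  rownames(counts) <- BASES
  pcm(id, counts)
}
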