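# Linking motif presence in enhancers to differential-expression classes.

#' Assign each gene its nearest enhancer
#'
#' Distance is 0 when the TSS lies inside the interval, otherwise the gap
#' to the nearer interval edge. Ties are broken in favour of the
#' upstream enhancer (the one ending at or before the TSS), then the
#' smaller start coordinate.
#'
#' @param tss data.frame with columns `gene_id`, `chrom`, `position`.
#' @param enhancers data.frame of intervals (`chrom`, `start`, `end`,
#'   `name`, `group`).
#' @return data.frame `gene_id`, `enhancer`, `distance`; genes on a
#'   chromosome without enhancers get `NA` and a message.
#' @export
assign_nearest_enhancer <- function(tss, enhancers) {
  out <- data.frame(gene_id = tss$gene_id, enhancer = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tss))) {
    cand <- enhancers[enhancers$chrom == tss$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    pos <- tss$position[i]
    d <- ifelse(pos >= cand$start & pos < cand$end, 0L,
                ifelse(pos < cand$start, cand$start - pos,
                       pos - cand$end))
    upstream <- cand$end <= pos
    ord <- order(d, !upstream, cand$start)
    out$enhancer[i] <- cand$name[ord[1L]]
    out$distance[i] <- d[ord[1L]]
  }
  if (anyNA(out$enhancer))
    message(sum(is.na(out$enhancer)),
            " gene(s) unassigned: no enhancer on their chromosome")
  out
}

#' Build the 3x2 contingency table of DE class by motif presence
#'
#' Rows are `up`, `down`, `ns`; columns are `present`, `absent`. Genes
#' missing from `presence` count as motif-absent (reported via `message()`),
#' so the counts always partition the gene list.
#'
#' @param genes data.frame with `gene_id` and `de_class`
#'   (from [read_gene_table()] or [gen_de_table()]).
#' @param presence named logical vector of motif presence per gene.
#' @return 3x2 integer matrix of class `contingency_3x2`.
#' @export
build_contingency <- function(genes, presence) {
  if (!nrow(genes)) stop("empty gene list", call. = FALSE)
  pr <- presence[genes$gene_id]
  if (anyNA(pr)) {
    message(sum(is.na(pr)), " gene(s) without a presence call counted as ",
            "motif-absent")
    pr[is.na(pr)] <- FALSE
  }
  cls <- factor(genes$de_class, levels = c("up", "down", "ns"))
  if (anyNA(cls)) stop("de_class must be up/down/ns", call. = FALSE)
  tab <- table(cls, factor(ifelse(pr, "present", "absent"),
                           levels = c("present", "absent")))
  out <- matrix(as.integer(tab), 3, 2,
                dimnames = list(c("up", "down", "ns"),
                                c("present", "absent")))
  class(out) <- c("contingency_3x2", class(out))
  out
}

#' Pearson chi-squared test of a 3x2 table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with expectations from the
#' margins, 2 degrees of freedom, upper-tail p from the chi-squared
#' distribution, and no continuity correction. A zero margin is an error
#' (the test is undefined); any expected count below 5 sets the
#' `low_expected` flag.
#'
#' @param table a [build_contingency()] result (or any 3x2 count matrix).
#' @return list of class `contingency_test`: `chi2`, `df`, `p`, `observed`,
#'   `expected`, `low_expected`.
#' @export
chi_squared_test <- function(table) {
  O <- unclass(table)
  stopifnot(is.matrix(O), nrow(O) == 3L, ncol(O) == 2L)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero margin: chi-squared test undefined", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  structure(list(chi2 = chi2, df = 2L,
                 p = stats::pchisq(chi2, df = 2, lower.tail = FALSE),
                 observed = O, expected = E,
                 low_expected = any(E < 5)),
            class = "contingency_test")
}

#' @export
print.contingency_test <- function(x, ...) {
  cat(sprintf("3x2 chi-squared: X2 = %.4f, df = %d, p = %.4g%s\n",
              x$chi2, x$df, x$p,
              if (x$low_expected) " (expected count < 5)" else ""))
  print(x$observed)
  invisible(x)
}

#' Per-gene motif presence profiles across enhancer groups
#'
#' For each gene, records whether any linked enhancer of each group (`Q`,
#' `A`, `PAN`) carries the motif, and whether some single Q enhancer carries
#' both the motif and `second_motif` (the `dual` flag).
#'
#' @param genes data.frame with `gene_id` and list column `enhancer_ids`.
#' @param enhancer_groups named character vector: group per enhancer id.
#' @param presence named logical vector (or logical matrix with motifs as
#'   columns) of motif presence per enhancer.
#' @param motif motif id; column of `presence` when it is a matrix.
#' @param second_motif optional second motif id for the `dual` flag.
#' @return data.frame `gene_id`, `Q`, `A`, `PAN`, `dual`.
#' @export
gene_motif_profiles <- function(genes, enhancer_groups, presence,
                                motif = NULL, second_motif = NULL) {
  get_col <- function(m) {
    if (is.matrix(presence)) {
      if (!(m %in% colnames(presence)))
        stop("unknown motif id: ", m, call. = FALSE)
      presence[, m]
    } else presence
  }
  p1 <- get_col(motif %||% colnames(presence)[1L] %||% "motif")
  p2 <- if (!is.null(second_motif)) get_col(second_motif) else NULL
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ids <- genes$enhancer_ids[[i]]
    ids <- ids[ids %in% names(enhancer_groups)]
    grp <- enhancer_groups[ids]
    has <- function(g) any(grp == g & p1[ids], na.rm = TRUE)
    dual <- if (is.null(p2)) NA else
      any(grp == "Q" & p1[ids] & p2[ids], na.rm = TRUE)
    data.frame(gene_id = genes$gene_id[i], Q = has("Q"), A = has("A"),
               PAN = has("PAN"), dual = dual, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genes whose motif presence is exclusive to Q enhancers
#'
#' Selects genes with the motif in at least one Q enhancer and in no A or
#' PAN enhancer; with `require_dual`, additionally demands that one Q
#' enhancer carries both the motif and the second motif.
#'
#' @param profiles data.frame from [gene_motif_profiles()] (or the
#'   `profiles` element of [gen_de_table()]).
#' @param require_dual require the `dual` flag as well.
#' @return character vector of gene ids, sorted.
#' @export
exclusive_motif_genes <- function(profiles, require_dual = FALSE) {
  stopifnot(all(c("gene_id", "Q", "A", "PAN") %in% names(profiles)))
  keep <- profiles$Q & !profiles$A & !profiles$PAN
  if (require_dual) {
    if (!"dual" %in% names(profiles) || all(is.na(profiles$dual)))
      stop("profiles carry no dual-motif flag", call. = FALSE)
    keep <- keep & profiles$dual %in% TRUE
  }
  sort(profiles$gene_id[keep])
}
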