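# Seeded synthetic-data generators with machine-readable ground truth.

#' Synthetic dataset configuration
#'
#' Bundles every knob of the synthetic generators. All randomness flows from
#' `seed` through named substreams (background sequence, masking, motif
#' planting, co-motif planting, DE table, assays), so changing one stage's
#' parameters does not perturb another stage's draws.
#'
#' The defaults emulate the structure of a grouped enhancer atlas at desk
#' scale: three groups of 300-bp enhancers embedded mid-contig with
#' length-matched flanks, an anchor motif planted in all groups at equal
#' rate, a second motif enriched in Q, and a co-motif word planted within
#' `comotif$half_width` bp of the anchor in Q enhancers only.
#'
#' @param seed master RNG seed (mandatory).
#' @param n_per_group named integer vector, sequences per group.
#' @param length_bp enhancer length.
#' @param flank_bp contig flank length on each side (controls are
#'   length-matched, so keep `flank_bp >= length_bp`).
#' @param transition 4x4 dinucleotide transition matrix (rows/cols A,C,G,T,
#'   rows summing to 1) for the order-1 Markov background; the default is
#'   uniform.
#' @param spike data.frame with columns `group`, `motif_id`, `consensus`,
#'   `prob`: per-group planting probability of one motif instance.
#' @param comotif list: `word`, `prob` (conditional on a planted anchor),
#'   `groups`, `anchor_id`, `core` (the subword of the anchor consensus
#'   that flank extraction anchors on; offsets are measured from its
#'   edges), `half_width`.
#' @param masked_fraction fraction of each contig soft-masked as one
#'   contiguous lowercase run.
#' @param de list for [gen_de_table()]: `n_genes`, `class_props` (up, down,
#'   ns), `p_ns` (motif presence among ns genes), `or_up`, `or_down`
#'   (presence odds ratios vs ns), `profile` (list `p_Q`, `p_A`, `p_PAN`,
#'   `dual_given_Q`).
#' @param assays list for [gen_assay_data()]: `gel` (`n`, `psi`,
#'   `noise_cv`), `qpcr` (`n`, `fold`, `noise_sd`), `decay` (`n`, `t_half`,
#'   `timepoints`, `noise_cv`).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_per_group = c(Q = 300L, A = 300L, PAN = 300L),
                         length_bp = 300L,
                         flank_bp = length_bp,
                         transition = NULL,
                         spike = NULL,
                         comotif = list(word = "TTGGCA", prob = 0.6,
                                        groups = "Q",
                                        anchor_id = "LEF1_LIKE",
                                        core = "CTTTGT",
                                        half_width = 15L),
                         masked_fraction = 0.02,
                         de = list(n_genes = 600L,
                                   class_props = c(up = 0.2, down = 0.2,
                                                   ns = 0.6),
                                   p_ns = 0.3, or_up = 3, or_down = 1,
                                   profile = list(p_Q = 0.35, p_A = 0.2,
                                                  p_PAN = 0.2,
                                                  dual_given_Q = 0.8)),
                         assays = list(
                           gel = list(n = 12L, psi = 61, noise_cv = 0.05),
                           qpcr = list(n = 8L, fold = 8, noise_sd = 0.1),
                           decay = list(n = 4L, t_half = 3.3,
                                        timepoints = c(0, 1, 2, 4, 6, 8),
                                        noise_cv = 0.05))) {
  if (missing(seed) && is.null(seed)) stop("seed is mandatory")
  if (is.null(transition)) transition <- matrix(0.25, 4, 4)
  stopifnot(all(dim(transition) == c(4, 4)),
            all(abs(rowSums(transition) - 1) < 1e-9))
  if (is.null(spike))
    spike <- data.frame(
      group = c("Q", "A", "PAN", "Q", "A", "PAN"),
      motif_id = rep(c("LEF1_LIKE", "NFIX_LIKE"), each = 3),
      consensus = rep(c("ACTTTGTT", "TTGGCACA"), each = 3),
      prob = c(0.4, 0.4, 0.4, 0.3, 0.05, 0.05),
      stringsAsFactors = FALSE)
  stopifnot(all(spike$prob >= 0 & spike$prob <= 1),
            all(spike$group %in% .GROUPS))
  if (!is.null(names(n_per_group)))
    stopifnot(all(names(n_per_group) %in% .GROUPS))
  else names(n_per_group) <- .GROUPS[seq_along(n_per_group)]
  stopifnot(masked_fraction >= 0, masked_fraction < 1,
            comotif$prob >= 0, comotif$prob <= 1)
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 length_bp = as.integer(length_bp),
                 flank_bp = as.integer(flank_bp),
                 transition = transition, spike = spike, comotif = comotif,
                 masked_fraction = masked_fraction, de = de,
                 assays = assays),
            class = "synth_config")
}

#' Read a synthetic configuration from YAML
#'
#' Keys mirror the arguments of [synth_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a [synth_config()].
#' @export
synth_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$spike)) y$spike <- as.data.frame(y$spike)
  if (!is.null(y$n_per_group)) y$n_per_group <- unlist(y$n_per_group)
  if (!is.null(y$transition))
    y$transition <- matrix(unlist(y$transition), 4, 4, byrow = TRUE)
  do.call(synth_config, y)
}

# n sequences of length len from an order-1 Markov chain (uniform start),
# generated column-by-column across all sequences at once.
.markov_seqs <- function(n, len, transition) {
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(transition, 1, cumsum))
  m <- matrix(0L, n, len)
  m[, 1L] <- sample.int(4L, n, replace = TRUE)
  if (len > 1L) for (j in 2:len) {
    u <- stats::runif(n)
    cur <- m[, j - 1L]
    m[, j] <- 1L + (u > cum[cbind(cur, 1L)]) + (u > cum[cbind(cur, 2L)]) +
      (u > cum[cbind(cur, 3L)])
  }
  apply(m, 1L, function(r) paste(bases[r], collapse = ""))
}

.mask_run <- function(seq, frac) {
  L <- nchar(seq)
  k <- round(frac * L)
  if (k < 1L) return(seq)
  at <- sample.int(L - k + 1L, 1L)
  paste0(substr(seq, 1L, at - 1L),
         tolower(substr(seq, at, at + k - 1L)),
         substr(seq, at + k, L))
}

.plant <- function(seq, word, offset0) {
  paste0(substr(seq, 1L, offset0), word,
         substr(seq, offset0 + nchar(word) + 1L, nchar(seq)))
}

#' Generate a grouped synthetic enhancer dataset
#'
#' Produces, per group, `n` enhancers of `length_bp` embedded mid-contig
#' (so length-matched flanking controls exist on both sides), drawn from
#' the order-1 Markov background, with one contiguous soft-masked run per
#' contig. With each configured spike probability, one motif consensus is
#' planted at a uniform random offset inside the enhancer on the plus
#' strand; with the configured conditional probability, the co-motif word
#' is planted within `half_width` bp of the planted anchor (left or right,
#' uniform gap). Planting overwrites background (and any mask) so every
#' planted instance is real; the ground-truth table records all of them.
#'
#' @param config a [synth_config()].
#' @return list: `genome` (named contig sequences), `intervals` (BED-style
#'   data.frame), `sequences` ([enhancer_set()]), `truth` (data.frame:
#'   `name`, `group`, `motif_id`, `kind` = spike/comotif, `word`, `offset`
#'   within the enhancer, `strand`).
#' @export
gen_enhancer_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  L <- config$length_bp
  FL <- config$flank_bp
  clen <- L + 2L * FL
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  name <- sprintf("%s_%04d", groups, unlist(lapply(config$n_per_group,
                                                   seq_len)))
  for (s in c(config$spike$consensus, config$comotif$word))
    if (nchar(s) > L) stop("motif longer than enhancer: ", s, call. = FALSE)
  contigs <- with_seed(substream(config$seed, "background"),
                       .markov_seqs(n, clen, config$transition))
  if (config$masked_fraction > 0)
    contigs <- with_seed(substream(config$seed, "masking"),
                         vapply(contigs, .mask_run,
                                frac = config$masked_fraction, character(1),
                                USE.NAMES = FALSE))
  truth <- list()
  contigs <- with_seed(substream(config$seed, "planting"), {
    anchor_off <- rep(NA_integer_, n)  # enhancer-relative anchor offsets
    for (r in seq_len(nrow(config$spike))) {
      sp <- config$spike[r, ]
      idx <- which(groups == sp$group)
      hit <- idx[stats::runif(length(idx)) < sp$prob]
      w <- nchar(sp$consensus)
      for (i in hit) {
        off <- sample.int(L - w + 1L, 1L) - 1L
        contigs[i] <- .plant(contigs[i], sp$consensus, FL + off)
        if (sp$motif_id == config$comotif$anchor_id) anchor_off[i] <- off
        truth[[length(truth) + 1L]] <- data.frame(
          name = name[i], group = groups[i], motif_id = sp$motif_id,
          kind = "spike", word = sp$consensus, offset = off, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    cm <- config$comotif
    wlen <- nchar(cm$word)
    anchor_cons <- config$spike$consensus[
      config$spike$motif_id == cm$anchor_id][1L]
    # offsets are measured from the anchor core the flank extraction will
    # match on, so planted co-words always lie inside a flank window
    core <- cm$core %||% anchor_cons
    core_shift <- regexpr(core, anchor_cons, fixed = TRUE) - 1L
    if (core_shift < 0L) { core_shift <- 0L; core <- anchor_cons }
    for (i in which(!is.na(anchor_off) & groups %in% cm$groups)) {
      if (stats::runif(1) >= cm$prob) next
      side <- sample(c("left", "right"), 1L)
      gap <- sample.int(cm$half_width - wlen + 1L, 1L) - 1L
      off <- if (side == "right")
        anchor_off[i] + core_shift + nchar(core) + gap
      else anchor_off[i] + core_shift - gap - wlen
      if (off < 0L || off + wlen > L) next  # truncated at enhancer edge
      contigs[i] <- .plant(contigs[i], cm$word, FL + off)
      truth[[length(truth) + 1L]] <- data.frame(
        name = name[i], group = groups[i], motif_id = cm$word,
        kind = "comotif", word = cm$word, offset = off, strand = "+",
        stringsAsFactors = FALSE)
    }
    contigs
  })
  genome <- stats::setNames(contigs, paste0("ctg_", name))
  intervals <- data.frame(chrom = paste0("ctg_", name), start = FL,
                          end = FL + L, name = name, group = groups,
                          stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(name = character(0), group = character(0),
               motif_id = character(0), kind = character(0),
               word = character(0), offset = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  list(genome = genome, intervals = intervals,
       sequences = extract_sequences(genome, intervals), truth = truth)
}

#' Generate a differential-expression gene table with known motif link
#'
#' DE classes are drawn from `de$class_props`; the motif-presence indicator
#' used for the contingency test is drawn per class so that the presence
#' odds ratio of `up` (and `down`) versus `ns` equals `or_up` (`or_down`).
#' Independently, per-group presence profiles (`Q`, `A`, `PAN`) and a
#' dual-motif flag are drawn from `de$profile`, giving a ground-truth
#' exclusive-Q gene list.
#'
#' @param config a [synth_config()].
#' @return list: `genes` (data.frame `gene_id`, `direction`, `pvalue`,
#'   `de_class`), `presence` (named logical), `profiles` (data.frame
#'   `gene_id`, `Q`, `A`, `PAN`, `dual`), `truth` (list with realised class
#'   counts, per-class presence counts, and the exclusive / exclusive-dual
#'   gene id vectors).
#' @export
gen_de_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  de <- config$de
  if (de$n_genes < 100L) stop("n_genes must be >= 100", call. = FALSE)
  if (de$p_ns <= 0 || de$p_ns >= 1)
    stop("p_ns must lie in (0, 1); feasible presence probabilities need ",
         "0 < p_ns < 1", call. = FALSE)
  odds <- function(p) p / (1 - p)
  p_up <- de$or_up * odds(de$p_ns) / (1 + de$or_up * odds(de$p_ns))
  p_down <- de$or_down * odds(de$p_ns) / (1 + de$or_down * odds(de$p_ns))
  with_seed(substream(config$seed, "de"), {
    cls <- sample(c("up", "down", "ns"), de$n_genes, replace = TRUE,
                  prob = de$class_props)
    gene_id <- sprintf("g%05d", seq_len(de$n_genes))
    pvalue <- ifelse(cls == "ns", stats::runif(de$n_genes, 0.01, 1),
                     stats::runif(de$n_genes, 0, 0.01))
    direction <- ifelse(cls == "down", "-",
                        ifelse(cls == "up", "+",
                               sample(c("+", "-"), de$n_genes, TRUE)))
    p_class <- c(up = p_up, down = p_down, ns = de$p_ns)[cls]
    present <- stats::runif(de$n_genes) < p_class
    pr <- de$profile
    Q <- stats::runif(de$n_genes) < pr$p_Q
    A <- stats::runif(de$n_genes) < pr$p_A
    PAN <- stats::runif(de$n_genes) < pr$p_PAN
    dual <- Q & (stats::runif(de$n_genes) < pr$dual_given_Q)
    genes <- data.frame(gene_id = gene_id, direction = direction,
                        pvalue = pvalue, de_class = cls,
                        stringsAsFactors = FALSE)
    profiles <- data.frame(gene_id = gene_id, Q = Q, A = A, PAN = PAN,
                           dual = dual, stringsAsFactors = FALSE)
    list(genes = genes,
         presence = stats::setNames(present, gene_id),
         profiles = profiles,
         truth = list(
           class_counts = table(factor(cls, c("up", "down", "ns"))),
           presence_prob = c(up = p_up, down = p_down, ns = de$p_ns),
           presence_by_class = tapply(present,
                                      factor(cls, c("up", "down", "ns")),
                                      sum),
           exclusive_genes = sort(gene_id[Q & !A & !PAN]),
           exclusive_dual_genes = sort(gene_id[Q & !A & !PAN & dual])))
  })
}

#' Generate noisy assay tables with known truth
#'
#' Gel band intensities around a true percent retention with multiplicative
#' lognormal noise; qPCR Ct quadruples around a true fold change with
#' additive Gaussian Ct noise; cycloheximide-chase decay series around a
#' true half-life with multiplicative lognormal noise. Zero-noise settings
#' reproduce the truth exactly.
#'
#' @param config a [synth_config()].
#' @return list: `gel`, `qpcr`, `decay` data.frames and `truth` (list
#'   `psi`, `fold`, `t_half`).
#' @export
gen_assay_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  a <- config$assays
  stopifnot(a$gel$noise_cv >= 0, a$qpcr$noise_sd >= 0,
            a$decay$noise_cv >= 0)
  if (!length(a$decay$timepoints)) stop("zero timepoints", call. = FALSE)
  with_seed(substream(config$seed, "assays"), {
    lnoise <- function(n, cv) if (cv == 0) rep(1, n) else
      exp(stats::rnorm(n, 0, cv))
    gel <- data.frame(
      sample_id = sprintf("lane%02d", seq_len(a$gel$n)),
      intensity_FL = 1000 * (a$gel$psi / 100) * lnoise(a$gel$n,
                                                       a$gel$noise_cv),
      intensity_dE6 = 1000 * (1 - a$gel$psi / 100) * lnoise(a$gel$n,
                                                            a$gel$noise_cv),
      stringsAsFactors = FALSE)
    ct_ref <- 20; ct_ref_cal <- 20; ct_target_cal <- 26
    qn <- a$qpcr$n
    qpcr <- data.frame(
      sample_id = sprintf("s%02d", seq_len(qn)),
      ct_target = ct_target_cal - log2(a$qpcr$fold) +
        stats::rnorm(qn, 0, a$qpcr$noise_sd),
      ct_reference = ct_ref + stats::rnorm(qn, 0, a$qpcr$noise_sd),
      ct_target_cal = ct_target_cal + stats::rnorm(qn, 0, a$qpcr$noise_sd),
      ct_reference_cal = ct_ref_cal + stats::rnorm(qn, 0, a$qpcr$noise_sd),
      stringsAsFactors = FALSE)
    tp <- a$decay$timepoints
    decay <- do.call(rbind, lapply(seq_len(a$decay$n), function(i)
      data.frame(sample_id = sprintf("series%02d", i), time_h = tp,
                 intensity = exp(-log(2) / a$decay$t_half * tp) *
                   lnoise(length(tp), a$decay$noise_cv),
                 stringsAsFactors = FALSE)))
    list(gel = gel, qpcr = qpcr, decay = decay,
         truth = list(psi = a$gel$psi, fold = a$qpcr$fold,
                      t_half = a$decay$t_half))
  })
}
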