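# End-to-end orchestration: scan -> enrich -> flank-discover -> link -> report.

#' Run the full motif-enrichment analysis
#'
#' Orchestrates every stage on a synthetic dataset generated from `config`
#' (or on user-supplied `data` of the same shape): per-group bootstrap
#' enrichment of each library motif in enhancers versus length-matched
#' flanking controls; pairwise group-differential enrichment; positional
#' bias of the anchor motif; word discovery in anchor flanks of Q versus A
#' enhancers with library matching; the DE-class-by-motif-presence
#' contingency test; exclusive-Q and dual-motif gene sets; and the assay
#' quantifications. Results carry a provenance block sufficient to
#' reproduce the run.
#'
#' @param config a [synth_config()]; its seed drives every stage.
#' @param motif_library named list of [pcm()]s
#'   (default [default_motif_library()]).
#' @param data optional precomputed input list with elements `genome`,
#'   `intervals`, `sequences` (as from [gen_enhancer_dataset()]); when
#'   `NULL`, synthetic data are generated from `config`.
#' @param anchor IUPAC anchor pattern for flank extraction.
#' @param half_width flank window width (bp per side).
#' @param threshold relative-score presence cut.
#' @param B bootstrap replicates.
#' @param outdir if non-`NULL`, write TSV/JSON outputs there.
#' @param verbose stage-level messages.
#' @return list of class `pipeline_report` with elements `enrichment`,
#'   `group_differential`, `positional_bias`, `words`, `word_matches`,
#'   `contingency`, `gene_sets`, `assays`, `truth`, `provenance`.
#' @export
run_pipeline <- function(config = synth_config(), data = NULL,
                         motif_library = default_motif_library(),
                         anchor = "CTTTGT", half_width = 15L,
                         threshold = 0.8, B = 500L, outdir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[enhmotif] ", ...)
  stopifnot(inherits(config, "synth_config"))
  if (is.null(data)) {
    say("generating synthetic enhancer dataset (seed ", config$seed, ")")
    data <- gen_enhancer_dataset(config)
  }
  enh <- data$sequences
  say("building length-matched flanking controls")
  controls <- make_flank_controls(data$intervals, data$genome)
  pwms <- lapply(motif_library, counts_to_pwm)
  groups <- unique(enh$group)
  enh_by <- lapply(groups, function(g) enh[enh$group == g, ])
  ctl_by <- lapply(groups, function(g) controls[controls$group == g, ])
  names(enh_by) <- names(ctl_by) <- groups

  say("bootstrap enrichment: enhancers vs flanks (",
      length(pwms), " motifs x ", length(groups), " groups, B=", B, ")")
  enr <- list()
  for (m in names(pwms)) for (g in groups) {
    r <- bootstrap_enrichment(pwms[[m]], enh_by[[g]], ctl_by[[g]],
                              threshold = threshold, B = B,
                              seed = substream(config$seed,
                                               paste0("enr:", m, ":", g)),
                              group = g)
    enr[[length(enr) + 1L]] <- data.frame(
      motif_id = m, group = g, frac_enhancer = r$frac_enhancer,
      frac_control = r$frac_control, statistic = r$statistic,
      bootstrap_p = r$bootstrap_p, B = r$B, stringsAsFactors = FALSE)
  }
  enrichment <- do.call(rbind, enr)

  say("group-differential enrichment")
  gd <- do.call(rbind, lapply(names(pwms), function(m)
    group_differential_enrichment(pwms[[m]], enh_by, threshold = threshold,
                                  B = B,
                                  seed = substream(config$seed,
                                                   paste0("gd:", m)))))

  say("positional bias of the anchor motif")
  anchor_id <- config$comotif$anchor_id
  lengths <- stats::setNames(enh$end - enh$start, enh$name)
  pb <- lapply(groups, function(g) {
    hits <- scan_sequences(pwms[[anchor_id]], enh_by[[g]])
    hits <- hits[hits$valid & hits$relative_score >= threshold, ,
                 drop = FALSE]
    if (!nrow(hits)) return(NULL)
    r <- positional_bias(hits, lengths)
    data.frame(motif_id = anchor_id, group = g,
               central_fraction = r$central_fraction,
               expected_fraction = r$expected_fraction, n_hits = r$n_hits,
               p = r$p, stringsAsFactors = FALSE)
  })
  pb <- do.call(rbind, pb)

  say("flank word discovery (anchor ", anchor, ", +/-", half_width, " bp)")
  fl_q <- extract_flanks(enh_by[["Q"]], anchor, half_width)
  fl_a <- if ("A" %in% groups)
    extract_flanks(enh_by[["A"]], anchor, half_width) else NULL
  if (!is.null(fl_a) && !nrow(fl_a)) fl_a <- NULL
  words <- discover_words(fl_q, fl_a,
                          seed = substream(config$seed, "shuffle"))
  word_matches <- if (nrow(words))
    words_to_known_motifs(words, motif_library) else NULL

  say("differential-expression link")
  de <- gen_de_table(config)
  ct <- build_contingency(de$genes, de$presence)
  ct_test <- chi_squared_test(ct)
  gene_sets <- list(
    exclusive_q = exclusive_motif_genes(de$profiles),
    exclusive_q_dual = exclusive_motif_genes(de$profiles,
                                             require_dual = TRUE))

  say("assay quantifications")
  ad <- gen_assay_data(config)
  psi <- percent_exon_retention(ad$gel$intensity_FL, ad$gel$intensity_dE6)
  fold <- ddct_fold_change(ad$qpcr$ct_target, ad$qpcr$ct_reference,
                           ad$qpcr$ct_target_cal, ad$qpcr$ct_reference_cal)
  hl <- vapply(split(ad$decay, ad$decay$sample_id), function(d)
    fit_half_life(d$time_h, d$intensity)$t_half, numeric(1))
  assays <- list(psi_mean = mean(psi), fold_mean = mean(fold),
                 t_half_mean = mean(hl), truth = ad$truth)

  report <- structure(list(
    enrichment = enrichment, group_differential = gd, positional_bias = pb,
    words = words, word_matches = word_matches,
    contingency = ct_test, gene_sets = gene_sets, assays = assays,
    truth = list(planting = data$truth, de = de$truth),
    provenance = list(seed = config$seed, config = config,
                      threshold = threshold, B = as.integer(B),
                      anchor = anchor, half_width = as.integer(half_width),
                      package_version = as.character(
                        utils::packageVersion("enhmotif")),
                      r_version = R.version.string)),
    class = "pipeline_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a pipeline report to disk
#'
#' Tables as TSV, the contingency result and provenance as JSON, gene sets
#' as one-column TSVs.
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) if (!is.null(x) && nrow(x))
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(report$enrichment, "enrichment.tsv")
  tsv(report$group_differential, "group_differential.tsv")
  tsv(report$positional_bias, "positional_bias.tsv")
  tsv(report$words, "discovered_words.tsv")
  tsv(report$word_matches, "word_matches.tsv")
  ct <- report$contingency
  jsonlite::write_json(
    list(observed = ct$observed, expected = ct$expected, chi2 = ct$chi2,
         df = ct$df, p = ct$p, low_expected = ct$low_expected),
    file.path(outdir, "contingency.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report$gene_sets$exclusive_q,
             file.path(outdir, "exclusive_q_genes.tsv"))
  writeLines(report$gene_sets$exclusive_q_dual,
             file.path(outdir, "exclusive_q_dual_genes.tsv"))
  prov <- report$provenance
  prov$config <- unclass(prov$config)
  prov$config$transition <- as.vector(prov$config$transition)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("enhmotif pipeline report (seed ", x$provenance$seed, ")\n\n",
      sep = "")
  cat("Enhancers vs flanks (bootstrap p by motif x group):\n")
  print(x$enrichment[, c("motif_id", "group", "statistic", "bootstrap_p")],
        row.names = FALSE)
  cat("\nGroup-differential (top rows):\n")
  gd <- x$group_differential[order(x$group_differential$bootstrap_p), ]
  print(utils::head(gd, 6), row.names = FALSE)
  if (!is.null(x$positional_bias)) {
    cat("\nPositional bias of the anchor motif:\n")
    print(x$positional_bias, row.names = FALSE)
  }
  cat("\nDiscovered flank words:\n")
  print(as.data.frame(x$words), row.names = FALSE)
  if (!is.null(x$word_matches)) {
    cat("\nBest library matches:\n")
    print(x$word_matches, row.names = FALSE)
  }
  cat("\n")
  print(x$contingency)
  cat(sprintf("\nGene sets: %d exclusive-Q, %d exclusive-Q dual-motif\n",
              length(x$gene_sets$exclusive_q),
              length(x$gene_sets$exclusive_q_dual)))
  cat(sprintf(
    "Assays: mean retention %.1f%%, mean fold %.2f, mean t1/2 %.2f h\n",
    x$assays$psi_mean, x$assays$fold_mean, x$assays$t_half_mean))
  invisible(x)
}
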