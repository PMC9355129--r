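test_that("generation is byte-identical for a fixed seed", {
  cfg <- synth_config(seed = 29, n_per_group = c(Q = 30, A = 30, PAN = 30),
                      length_bp = 120)
  d1 <- gen_enhancer_dataset(cfg)
  d2 <- gen_enhancer_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$truth, d2$truth)
  expect_identical(gen_de_table(cfg), gen_de_table(cfg))
  expect_identical(gen_assay_data(cfg), gen_assay_data(cfg))
})

test_that("substreams are independent: assay knobs do not move sequences", {
  cfg1 <- synth_config(seed = 31, n_per_group = c(Q = 20),
                       length_bp = 100)
  cfg2 <- cfg1
  cfg2$assays$decay$noise_cv <- 0.5
  expect_identical(gen_enhancer_dataset(cfg1)$genome,
                   gen_enhancer_dataset(cfg2)$genome)
  expect_identical(gen_de_table(cfg1)$genes, gen_de_table(cfg2)$genes)
})

test_that("planted anchor counts follow the configured binomial rate", {
  cfg <- synth_config(seed = 37, n_per_group = c(Q = 500),
                      length_bp = 150,
                      spike = data.frame(group = "Q",
                                         motif_id = "LEF1_LIKE",
                                         consensus = "ACTTTGTT",
                                         prob = 0.4,
                                         stringsAsFactors = FALSE),
                      comotif = list(word = "TTGGCA", prob = 0,
                                     groups = "Q",
                                     anchor_id = "LEF1_LIKE",
                                     half_width = 15))
  d <- gen_enhancer_dataset(cfg)
  k <- sum(d$truth$kind == "spike")
  expect_gte(k, qbinom(0.005, 500, 0.4))
  expect_lte(k, qbinom(0.995, 500, 0.4))
  # every recorded planting is really in the sequence
  seqs <- stats::setNames(d$sequences$seq, d$sequences$name)
  for (i in sample(nrow(d$truth), 25))
    expect_identical(
      toupper(substr(seqs[[d$truth$name[i]]], d$truth$offset[i] + 1,
                     d$truth$offset[i] + nchar(d$truth$word[i]))),
      d$truth$word[i])
})

test_that("unspiked sequences match a naive scan of the background", {
  cfg <- synth_config(seed = 41, n_per_group = c(Q = 50),
                      length_bp = 120,
                      spike = data.frame(group = "Q",
                                         motif_id = "LEF1_LIKE",
                                         consensus = "ACTTTGTT",
                                         prob = 0,
                                         stringsAsFactors = FALSE),
                      comotif = list(word = "TTGGCA", prob = 0,
                                     groups = "Q",
                                     anchor_id = "LEF1_LIKE",
                                     half_width = 15))
  d <- gen_enhancer_dataset(cfg)
  expect_equal(nrow(d$truth), 0)
  pw <- counts_to_pwm(default_motif_library()$LEF1_LIKE)
  calls <- presence_calls(pw, d$sequences, threshold = 0.8)
  oracle <- vapply(d$sequences$seq, function(s) {
    o <- naive_scan(pw, s)
    rel <- (o$score - pw$min_score) / (pw$max_score - pw$min_score)
    !is.na(o$score) && rel >= 0.8
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(calls, oracle)
})

test_that("DE classes and presence rates respect the configuration", {
  cfg <- synth_config(seed = 43)
  cfg$de$n_genes <- 1000L
  cfg$de$class_props <- c(up = 0.2, down = 0.2, ns = 0.6)
  de <- gen_de_table(cfg)
  cc <- c(de$truth$class_counts)
  for (cl in c("up", "down", "ns")) {
    p <- cfg$de$class_props[[cl]]
    expect_gte(cc[[cl]], qbinom(0.005, 1000, p))
    expect_lte(cc[[cl]], qbinom(0.995, 1000, p))
  }
  # configured odds ratio implies a higher presence rate among up genes
  expect_gt(de$truth$presence_prob[["up"]],
            de$truth$presence_prob[["ns"]])
  cfg$de$p_ns <- 1
  expect_error(gen_de_table(cfg), "p_ns")
})

test_that("noiseless assays reproduce their truth exactly", {
  cfg <- synth_config(seed = 47)
  cfg$assays$gel$noise_cv <- 0
  cfg$assays$qpcr$noise_sd <- 0
  cfg$assays$decay$noise_cv <- 0
  a <- gen_assay_data(cfg)
  expect_equal(percent_exon_retention(a$gel$intensity_FL[1],
                                      a$gel$intensity_dE6[1]),
               a$truth$psi, tolerance = 1e-9)
  expect_equal(ddct_fold_change(a$qpcr$ct_target[1],
                                a$qpcr$ct_reference[1],
                                a$qpcr$ct_target_cal[1],
                                a$qpcr$ct_reference_cal[1]),
               a$truth$fold, tolerance = 1e-9)
  s1 <- a$decay[a$decay$sample_id == "series01", ]
  expect_equal(fit_half_life(s1$time_h, s1$intensity)$t_half,
               a$truth$t_half, tolerance = 1e-9)
})

test_that("planting an oversized motif is rejected", {
  expect_error(
    gen_enhancer_dataset(
      synth_config(seed = 1, length_bp = 6,
                   spike = data.frame(group = "Q", motif_id = "x",
                                      consensus = "ACTTTGTT", prob = 1,
                                      stringsAsFactors = FALSE))),
    "longer than enhancer")
})
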