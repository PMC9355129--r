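test_that("flank controls are adjacent, length-matched and disjoint", {
  set.seed(61)
  genome <- c(c1 = random_seq(1000))
  iv <- data.frame(chrom = "c1", start = 100, end = 200, name = "e1",
                   group = "Q", stringsAsFactors = FALSE)
  fl <- make_flank_controls(iv, genome)
  expect_setequal(fl$name, c("e1_L", "e1_R"))
  expect_equal(fl$start[fl$name == "e1_L"], 0)
  expect_equal(fl$end[fl$name == "e1_L"], 100)
  expect_equal(fl$start[fl$name == "e1_R"], 200)
  expect_equal(fl$end[fl$name == "e1_R"], 300)
  expect_identical(unique(fl$group), "Q")

  # enhancer at the contig start: only the downstream flank survives
  iv0 <- data.frame(chrom = "c1", start = 0, end = 100, name = "e0",
                    group = "A", stringsAsFactors = FALSE)
  expect_message(fl0 <- make_flank_controls(iv0, genome), "outside contig")
  expect_identical(fl0$name, "e0_R")
})

test_that("flank controls never overlap any enhancer of the set", {
  set.seed(67)
  for (rep in 1:10) {
    genome <- c(c1 = random_seq(3000))
    starts <- sort(sample(seq(100, 2500, by = 50), 5))
    iv <- data.frame(chrom = "c1", start = starts,
                     end = starts + sample(40:120, 5, TRUE),
                     name = paste0("e", 1:5),
                     group = sample(c("Q", "A", "PAN"), 5, TRUE),
                     stringsAsFactors = FALSE)
    iv <- iv[iv$end <= 3000, ]
    fl <- suppressMessages(make_flank_controls(iv, genome))
    expect_equal(nchar(fl$seq), fl$end - fl$start)
    # length-matched to the parent enhancer
    parent <- sub("_[LR]$", "", fl$name)
    expect_equal(fl$end - fl$start,
                 (iv$end - iv$start)[match(parent, iv$name)])
    # interval-intersection oracle
    for (i in seq_len(nrow(fl)))
      for (j in seq_len(nrow(iv)))
        expect_false(fl$start[i] < iv$end[j] && fl$end[i] > iv$start[j])
  }
})

test_that("bootstrap p hits the analytic floor under total separation", {
  set.seed(71)
  pw <- counts_to_pwm(word_pcm_sharp("ACTTTGTT"))
  enh <- vapply(1:50, function(i)
    plant_word(random_seq(60), "ACTTTGTT", sample(0:52, 1)), character(1))
  names(enh) <- paste0("e", 1:50)
  ctl <- stats::setNames(rep(strrep("A", 60), 50), paste0("c", 1:50))
  r <- bootstrap_enrichment(pw, enh, ctl, B = 999, seed = 4)
  expect_equal(r$statistic, 1)
  expect_equal(r$bootstrap_p, 1 / 1000)
})

test_that("self-comparison yields a zero statistic and bounded p", {
  set.seed(73)
  pw <- counts_to_pwm(word_pcm_sharp("ACTTTGTT"))
  s <- stats::setNames(vapply(1:30, function(i) random_seq(60),
                              character(1)), paste0("s", 1:30))
  r <- bootstrap_enrichment(pw, s, s, B = 199, seed = 1)
  expect_equal(r$statistic, 0)
  expect_gte(r$bootstrap_p, 1 / 200)
  expect_lte(r$bootstrap_p, 1)
  expect_error(bootstrap_enrichment(pw, s, s, B = 50), "B must be")
})

test_that("bootstrap results are bit-reproducible for a fixed seed", {
  set.seed(79)
  pw <- counts_to_pwm(word_pcm_sharp("TTGGCACA"))
  enh <- stats::setNames(vapply(1:40, function(i) random_seq(80),
                                character(1)), paste0("e", 1:40))
  ctl <- stats::setNames(vapply(1:40, function(i) random_seq(80),
                                character(1)), paste0("c", 1:40))
  r1 <- bootstrap_enrichment(pw, enh, ctl, B = 199, seed = 42)
  r2 <- bootstrap_enrichment(pw, enh, ctl, B = 199, seed = 42)
  expect_identical(r1, r2)
})

test_that("stronger spiking never weakens enrichment (median p)", {
  pw <- counts_to_pwm(word_pcm_sharp("ACTTTGTT"))
  median_p <- function(rate) {
    ps <- vapply(1:5, function(run) {
      cfg <- synth_config(seed = 100 + run,
                         n_per_group = c(Q = 60),
                         length_bp = 150, flank_bp = 0,
                         spike = data.frame(group = "Q",
                                            motif_id = "LEF1_LIKE",
                                            consensus = "ACTTTGTT",
                                            prob = rate,
                                            stringsAsFactors = FALSE),
                         comotif = list(word = "TTGGCA", prob = 0,
                                        groups = "Q",
                                        anchor_id = "LEF1_LIKE",
                                        half_width = 15),
                         masked_fraction = 0)
      d <- gen_enhancer_dataset(cfg)
      cfg0 <- cfg; cfg0$spike$prob <- 0; cfg0$seed <- cfg$seed + 5000L
      d0 <- gen_enhancer_dataset(cfg0)
      bootstrap_enrichment(pw, d$sequences, d0$sequences, B = 199,
                           seed = run)$bootstrap_p
    }, numeric(1))
    stats::median(ps)
  }
  p_weak <- median_p(0.1)
  p_strong <- median_p(0.5)
  expect_lte(p_strong, p_weak)
})

test_that("group comparison of a set with itself is exactly null", {
  set.seed(83)
  pw <- counts_to_pwm(word_pcm_sharp("TTGGCACA"))
  s <- stats::setNames(vapply(1:30, function(i) random_seq(60),
                              character(1)), paste0("s", 1:30))
  res <- suppressWarnings(
    group_differential_enrichment(pw, list(g1 = s, g2 = s), B = 100,
                                  seed = 2))
  expect_true(all(res$statistic == 0))
  expect_error(group_differential_enrichment(pw, list(a = s)), "two groups")
})

test_that("positional bias: extreme central concentration and errors", {
  hits <- data.frame(enhancer_id = paste0("e", 1:100), motif_id = "m",
                     offset = 46, width = 8, valid = TRUE,
                     stringsAsFactors = FALSE)
  lens <- stats::setNames(rep(100, 100), paste0("e", 1:100))
  r <- positional_bias(hits, lens, central_window_fraction = 0.5)
  expect_equal(r$central_fraction, 1)
  expect_equal(r$p, 0.5^100)
  expect_error(positional_bias(hits, lens, central_window_fraction = 1),
               "central_window_fraction")
  expect_error(positional_bias(hits[0, ], lens), "no hits")
})

test_that("positional bias is calibrated for uniformly placed hits", {
  set.seed(87)
  rejections <- 0
  for (i in 1:200) {
    # point hits with uniformly distributed midpoints
    off <- sample(0:99, 60, replace = TRUE)
    hits <- data.frame(enhancer_id = paste0("e", 1:60), motif_id = "m",
                       offset = off, width = 0, valid = TRUE,
                       stringsAsFactors = FALSE)
    lens <- stats::setNames(rep(100, 60), paste0("e", 1:60))
    if (positional_bias(hits, lens)$p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 200, 0.005)
  expect_lte(rejections / 200, 0.11)
})
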