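test_that("nearest-enhancer assignment: containment, ties, oracle", {
  enh <- data.frame(chrom = "chr1", start = c(100, 300), end = c(200, 400),
                    name = c("eA", "eB"), group = c("Q", "A"),
                    stringsAsFactors = FALSE)
  tss <- data.frame(gene_id = "g1", chrom = "chr1", position = 150,
                    stringsAsFactors = FALSE)
  a <- assign_nearest_enhancer(tss, enh)
  expect_identical(a$enhancer, "eA")
  expect_equal(a$distance, 0)

  # exactly equidistant: the upstream enhancer wins
  tss2 <- data.frame(gene_id = "g2", chrom = "chr1", position = 250,
                     stringsAsFactors = FALSE)
  a2 <- assign_nearest_enhancer(tss2, enh)
  expect_identical(a2$enhancer, "eA")

  expect_message(
    a3 <- assign_nearest_enhancer(
      data.frame(gene_id = "g3", chrom = "chrX", position = 5),
      enh),
    "unassigned")
  expect_true(is.na(a3$enhancer))

  # brute-force all-pairs oracle on random layouts
  set.seed(113)
  for (rep in 1:100) {
    ne <- sample(2:6, 1)
    starts <- sort(sample(seq(0, 5000, 10), ne))
    enh <- data.frame(chrom = "chr1", start = starts,
                      end = starts + sample(20:200, ne, TRUE),
                      name = paste0("e", seq_len(ne)),
                      group = "Q", stringsAsFactors = FALSE)
    pos <- sample(0:5500, 1)
    got <- assign_nearest_enhancer(
      data.frame(gene_id = "g", chrom = "chr1", position = pos), enh)
    d <- vapply(seq_len(ne), function(j) {
      if (pos >= enh$start[j] && pos < enh$end[j]) 0
      else if (pos < enh$start[j]) enh$start[j] - pos
      else pos - enh$end[j]
    }, numeric(1))
    expect_equal(got$distance, min(d))
    # the chosen enhancer attains the minimum
    expect_true(d[match(got$enhancer, enh$name)] == min(d))
  }
})

test_that("contingency tables partition the gene list", {
  genes <- data.frame(gene_id = paste0("g", 1:10),
                      de_class = rep("ns", 10), stringsAsFactors = FALSE)
  pres <- stats::setNames(rep(TRUE, 10), genes$gene_id)
  tab <- build_contingency(genes, pres)
  expect_equal(unclass(tab),
               matrix(c(0L, 0L, 10L, 0L, 0L, 0L), 3, 2,
                      dimnames = list(c("up", "down", "ns"),
                                      c("present", "absent"))))

  # order invariance
  genes2 <- data.frame(gene_id = paste0("g", 1:30),
                       de_class = sample(c("up", "down", "ns"), 30, TRUE),
                       stringsAsFactors = FALSE)
  pres2 <- stats::setNames(sample(c(TRUE, FALSE), 30, TRUE),
                           genes2$gene_id)
  t1 <- build_contingency(genes2, pres2)
  t2 <- build_contingency(genes2[sample(30), ], pres2)
  expect_identical(t1, t2)
  expect_equal(sum(t1), 30)
  expect_error(build_contingency(genes2[0, ], pres2), "empty")
})

test_that("contingency counts agree with the generator's bookkeeping", {
  cfg <- synth_config(seed = 19)
  de <- gen_de_table(cfg)
  tab <- build_contingency(de$genes, de$presence)
  expect_equal(rowSums(tab), c(de$truth$class_counts),
               ignore_attr = TRUE)
  expect_equal(tab[, "present"], c(de$truth$presence_by_class),
               ignore_attr = TRUE)
})

test_that("chi-squared matches the closed form and a reference", {
  # proportional rows: independence exactly
  t0 <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2)
  r0 <- chi_squared_test(t0)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  tab <- matrix(c(25L, 10L, 15L, 75L, 90L, 285L), 3, 2)
  r <- chi_squared_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$chi2, sum((tab - E)^2 / E))
  expect_equal(r$df, 2L)
  # doubling every count doubles the statistic exactly
  expect_equal(chi_squared_test(tab * 2L)$chi2, 2 * r$chi2)

  set.seed(127)
  for (i in 1:100) {
    tt <- matrix(rpois(6, 40) + 1L, 3, 2)
    mine <- chi_squared_test(tt)
    ref <- suppressWarnings(stats::chisq.test(tt, correct = FALSE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_error(chi_squared_test(matrix(c(0L, 0L, 0L, 5L, 5L, 5L), 3, 2)),
               "zero margin")
})

test_that("exclusive-Q gene sets follow the definition and the truth", {
  profiles <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    Q = c(TRUE, TRUE, FALSE, TRUE),
    A = c(FALSE, FALSE, FALSE, FALSE),
    PAN = c(TRUE, FALSE, FALSE, FALSE),
    dual = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  # motif in Q and PAN: excluded
  expect_identical(exclusive_motif_genes(profiles), c("g2", "g4"))
  expect_identical(exclusive_motif_genes(profiles, require_dual = TRUE),
                   "g2")

  cfg <- synth_config(seed = 23)
  de <- gen_de_table(cfg)
  expect_identical(exclusive_motif_genes(de$profiles),
                   de$truth$exclusive_genes)
  expect_identical(exclusive_motif_genes(de$profiles, require_dual = TRUE),
                   de$truth$exclusive_dual_genes)
})

test_that("profiles aggregate per-enhancer presence by group", {
  genes <- data.frame(gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  genes$enhancer_ids <- list(c("e1", "e2"), "e3")
  groups <- c(e1 = "Q", e2 = "A", e3 = "Q")
  pres <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), 3, 2,
                 dimnames = list(c("e1", "e2", "e3"), c("m1", "m2")))
  prof <- gene_motif_profiles(genes, groups, pres, motif = "m1",
                              second_motif = "m2")
  expect_identical(prof$Q, c(TRUE, TRUE))
  expect_identical(prof$A, c(FALSE, FALSE))
  # g1's Q enhancer e1 carries both motifs; g2's e3 has only m1
  expect_identical(prof$dual, c(TRUE, FALSE))
})
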