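test_that("gene classification applies fold and significance thresholds", {
  de <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    log2fc = c(-1.5, -3, 2.2, 0.5, -4),
    padj = c(0.01, 0.20, 0.001, 0.001, NA))
  cl <- classify_genes(de)
  expect_equal(cl$class, c("down", "none", "up", "none"))
  expect_equal(attr(cl, "n_missing_padj"), 1)
  ## the three classes partition the analysed genes
  expect_equal(sort(table(cl$class)[c("down", "none", "up")]),
               sort(table(cl$class)))

  cls <- list(
    s1 = classify_genes(tibble::tibble(gene = c("a", "b"),
                                       log2fc = c(-2, -2), padj = 0.01)),
    s2 = classify_genes(tibble::tibble(gene = c("a", "b"),
                                       log2fc = c(-2, 0), padj = 0.01)))
  expect_equal(class_intersection(cls)$down, "a")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- sprintf("g%02d", 1:10)
  targets <- universe[1:5]
  gene_set <- universe[1:4] # k = 4 of n = 4 drawn
  res <- enrich_hyper(targets, gene_set, universe)
  expect_equal(res$p_hyper, 5 / 210)
  expect_equal(res$p_hyper, bf_hyper_upper(4, 5, 10, 4))
  ## k = 0 and the saturated sample both give p = 1
  expect_equal(enrich_hyper(targets, universe[6:9], universe)$p_hyper, 1)
  expect_equal(enrich_hyper(targets, universe, universe)$p_hyper, 1)
  expect_error(enrich_hyper(targets, gene_set, character(0)), "empty")
})

test_that("permutation p-values are deterministic and degenerate correctly", {
  universe <- sprintf("g%02d", 1:30)
  targets <- universe[1:6]
  p1 <- enrich_perm(targets, universe[1:5], universe, n_perm = 200,
                    rng_seed = 5)
  p2 <- enrich_perm(targets, universe[1:5], universe, n_perm = 200,
                    rng_seed = 5)
  expect_identical(p1, p2)
  ## drawing the whole universe always reproduces the observed overlap
  expect_equal(enrich_perm(targets, universe, universe, n_perm = 50,
                           rng_seed = 1)$p_perm, 1)
  ## observed overlap 0 gives p = 1 under the >= rule
  expect_equal(enrich_perm(targets, universe[7:12], universe, n_perm = 50,
                           rng_seed = 1)$p_perm, 1)
  expect_error(enrich_perm(targets, universe, universe, set_size = 31),
               "larger than")
})

test_that("permutation and hypergeometric tails agree within Monte-Carlo error", {
  withr::local_seed(301)
  n_agree <- 0
  n_inst <- 15
  for (i in 1:n_inst) {
    N <- sample(40:120, 1)
    universe <- sprintf("u%03d", 1:N)
    targets <- sample(universe, sample(5:25, 1))
    gene_set <- sample(universe, sample(5:25, 1))
    hy <- enrich_hyper(targets, gene_set, universe)$p_hyper
    pm <- enrich_perm(targets, gene_set, universe, n_perm = 1000,
                      rng_seed = i)$p_perm
    tol <- 3 * sqrt(hy * (1 - hy) / 1000) + 2 / 1001
    if (abs(pm - hy) <= tol) n_agree <- n_agree + 1
  }
  expect_gte(n_agree, n_inst - 1)
})

test_that("multiple-testing adjustment matches the brute-force oracle", {
  expect_equal(adjust_pvalues(1e-4, "bonferroni", m = 100), 0.01)
  expect_equal(adjust_pvalues(0.3, "bonferroni"), 0.3)
  expect_equal(adjust_pvalues(0.3, "benjamini_hochberg"), 0.3)
  withr::local_seed(17)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_pvalues(p, "benjamini_hochberg"), bf_bh(p))
    expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, p * length(p)))
  }
  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")
})

test_that("word enrichment surfaces planted words and degenerates to 1", {
  withr::local_seed(53)
  word <- "CGTACT"
  genes <- sprintf("g%02d", 1:30)
  utr_seq <- vapply(1:30, function(i) rand_dna(150), character(1))
  ## scrub any chance occurrence, then plant the word in the first 8 genes
  utr_seq <- gsub(word, "CGTAGT", utr_seq, fixed = TRUE)
  utr_seq[1:8] <- paste0(substr(utr_seq[1:8], 1, 80), word,
                         substr(utr_seq[1:8], 87, 150))
  utrs <- tibble::tibble(gene = genes, utr_seq = utr_seq)
  tbl <- word_enrich(utrs, genes[1:8], genes, k = 6)
  expect_equal(tbl$word[1], word)
  expect_equal(tbl$rank[tbl$word == word], 1)

  all_one <- word_enrich(utrs, genes, genes, k = 6)
  expect_true(all(all_one$p_hyper == 1))
  expect_error(word_enrich(utrs, genes[1:3], genes, k = 9), "between 4 and 8")
  expect_error(word_enrich(utrs, genes[1:3], c(genes, "missing"), k = 6),
               "no UTR record")
})

test_that("clearance flagging requires down- but not up-enrichment", {
  enr <- tibble::tibble(
    mature_id = rep(c("m1", "m2", "m3"), each = 2),
    set_label = rep(c("down:s1", "up:s1"), 3),
    p_bonferroni = c(1e-6, 1, 1e-6, 1e-6, 1, 1))
  out <- rank_mirnas(enr, p_threshold = 0.001)
  expect_true(out$flagged[out$mature_id == "m1"])
  expect_false(out$flagged[out$mature_id == "m2"]) # up-enriched too
  expect_false(out$flagged[out$mature_id == "m3"]) # no targets anywhere
  ## raising the threshold can only grow the flagged set
  loose <- rank_mirnas(enr, p_threshold = 0.5)
  expect_true(all(out$flagged <= loose$flagged[match(out$mature_id,
                                                     loose$mature_id)]))
})
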