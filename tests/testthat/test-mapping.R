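test_that("exact substrings map uniquely with strand symmetry", {
  g <- toy_genome(seed = 1)
  read <- substr(g[["chr1"]], 101, 120) # offset 100, 0-based
  hits <- map_read(g, read, max_mismatches = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$chrom, "chr1")
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 100)
  expect_equal(hits$end, 120)
  expect_equal(hits$mismatches, 0)

  rc_hits <- map_read(g, revcomp(read), max_mismatches = 0)
  expect_equal(nrow(rc_hits), 1)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 100)
  expect_equal(rc_hits$end, 120)
})

test_that("only the best mismatch stratum is reported", {
  ## a perfect copy at one locus and a 1-mismatch copy at another
  withr::local_seed(5)
  read <- rand_dna(20)
  variant <- read
  substr(variant, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read, 10, 10))[1]
  g <- c(chr1 = paste0(rand_dna(50), read, rand_dna(50), variant, rand_dna(50)))
  hits <- map_read(g, read, max_mismatches = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$start, 50)
})

test_that("mapping agrees with the exhaustive sliding oracle", {
  withr::local_seed(23)
  for (rep in 1:5) {
    g <- c(chr1 = rand_dna(800), chr2 = rand_dna(600))
    ## reads: exact, mutated, reverse-complement, absent
    base <- substr(g[["chr2"]], 31, 52)
    mutated <- base
    substr(mutated, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(base, 7, 7))[1]
    for (read in list(base, mutated, revcomp(base), rand_dna(22))) {
      got <- as.data.frame(map_read(g, read, max_mismatches = 1))
      want <- bf_map(g, read, max_mm = 1)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, label = paste("rep", rep))
    }
  }
})

test_that("U is read as T and other characters are rejected", {
  g <- toy_genome(seed = 2)
  read_dna <- substr(g[["chr1"]], 201, 222)
  read_rna <- chartr("T", "U", read_dna)
  expect_identical(map_read(g, read_rna, 0), map_read(g, read_dna, 0))
  expect_error(map_read(g, "ACGTXACGTACGTACGTACGT"), "non-ACGTUN")
})

test_that("multi-mapping reads split fractionally and -m discards", {
  withr::local_seed(9)
  mat <- rand_dna(22)
  pad <- function() rand_dna(120)
  ## two identical hairpin copies -> every read hits both
  g2 <- c(chr1 = paste0(pad(), mat, pad(), mat, pad()))
  s1 <- 120; s2 <- 120 + 22 + 120
  loci2 <- rbind(
    toy_loci(hp_start = s1 - 10, hp_end = s1 + 32, m_start = s1, m_end = s1 + 22,
             id = "miR-a-3p", locus = "mir-a"),
    toy_loci(hp_start = s2 - 10, hp_end = s2 + 32, m_start = s2, m_end = s2 + 22,
             id = "miR-b-3p", locus = "mir-b"))
  counts <- quantify_library(tibble::tibble(seq = mat, count = 10),
                             g2, loci2)
  expect_equal(counts$count[counts$mature_id == "miR-a-3p"], 5)
  expect_equal(counts$count[counts$mature_id == "miR-b-3p"], 5)
  expect_equal(attr(counts, "mapped_total"), 10)

  ## six copies -> more hits than max_loci, read discarded
  g6 <- c(chr1 = paste0(pad(), paste(rep(paste0(mat, pad()), 6), collapse = "")))
  counts6 <- quantify_library(tibble::tibble(seq = mat, count = 10),
                              g6, loci2[0, ])
  expect_equal(attr(counts6, "discarded_multi"), 10)
  expect_equal(attr(counts6, "mapped_total"), 0)
})

test_that("exclusion intervals remove reads mapping into them", {
  g <- toy_genome(seed = 4)
  read <- substr(g[["chr1"]], 301, 322)
  loci <- toy_loci(hp_start = 290, hp_end = 360, m_start = 300, m_end = 322,
                   genome = g)
  lib <- tibble::tibble(seq = read, count = 8)
  kept <- quantify_library(lib, g, loci)
  expect_equal(sum(kept$count), 8)
  filtered <- quantify_library(
    lib, g, loci,
    exclude = tibble::tibble(chrom = "chr1", start = 250, end = 310))
  expect_equal(sum(filtered$count), 0)
  expect_equal(attr(filtered, "excluded"), 8)
  ## non-overlapping interval changes nothing
  untouched <- quantify_library(
    lib, g, loci,
    exclude = tibble::tibble(chrom = "chr2", start = 250, end = 310))
  expect_equal(sum(untouched$count), 8)
})

test_that("counting recovers the simulation truth when tails are off", {
  cfg <- small_sim_config(rng_seed = 77, tail_prob = 0)
  sim <- simulate_dataset(cfg)
  stage <- "oocyte"
  counts <- count_matrix(sim$libraries[stage], sim$genome, sim$loci)
  truth_counts <- tapply(sim$truth$reads[[stage]]$count,
                         sim$truth$reads[[stage]]$mature_id, sum)
  for (mid in names(truth_counts)) {
    expect_equal(counts[[stage]][counts$mature_id == mid],
                 unname(truth_counts[[mid]]), label = mid)
  }
  ## conservation: mapped total equals all miRNA reads (spikes don't map)
  expect_equal(attr(counts, "totals")[[stage]],
               sum(sim$truth$reads[[stage]]$count))
})

test_that("RPM normalization scales by library totals and flags zeros", {
  counts <- tibble::tibble(mature_id = c("a", "b"), lib1 = c(5, 0))
  out <- rpm(counts, totals = c(lib1 = 1e6))
  expect_equal(out$lib1, c(5, 0))
  ## scale invariance
  out2 <- rpm(dplyr::mutate(counts, lib1 = lib1 * 2), totals = c(lib1 = 2e6))
  expect_equal(out2$lib1, out$lib1)
  expect_error(rpm(counts, totals = c(lib1 = 0)), "zero genome-mapped")
  expect_error(rpm(counts), "totals")
})
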