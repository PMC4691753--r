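mk_loci <- function(starts, chrom = "chr1", len = 100) {
  tibble::tibble(
    locus_id = sprintf("mir-%02d", seq_along(starts)),
    chrom = chrom, strand = "+",
    hairpin_start = starts, hairpin_end = starts + len)
}

test_that("loci within the distance rule chain into clusters", {
  cl <- cluster_loci(mk_loci(c(0, 9000, 25000)))
  sizes <- split(cl$locus_id, cl$cluster_id)
  expect_equal(length(sizes), 2)
  expect_setequal(sizes[[which(lengths(sizes) == 2)]], c("mir-01", "mir-02"))
  ## gap is measured end-to-start: 9000 - 100 = 8900 <= 10000 joins,
  ## 25000 - 9100 = 15900 does not
  expect_equal(sort(unname(lengths(sizes))), c(1, 2))

  single <- cluster_loci(mk_loci(5000))
  expect_equal(nrow(single), 1)
  expect_equal(single$cluster_size, 1)

  two_chrom <- dplyr::bind_rows(mk_loci(0, chrom = "chr1"),
                                mk_loci(50, chrom = "chr2"))
  expect_equal(length(unique(cluster_loci(two_chrom)$cluster_id)), 2)
})

test_that("clustering partitions the loci and ignores input order", {
  withr::local_seed(8)
  starts <- sort(sample.int(2e5, 30))
  loci <- mk_loci(starts)
  a <- cluster_loci(loci)
  b <- cluster_loci(loci[sample.int(nrow(loci)), ])
  expect_equal(nrow(a), 30)
  expect_equal(anyDuplicated(a$locus_id), 0)
  ga <- split(sort(a$locus_id), a$cluster_id[order(a$locus_id)])
  gb <- split(sort(b$locus_id), b$cluster_id[order(b$locus_id)])
  expect_identical(unname(ga), unname(gb))
})

test_that("seeds are positions 2..k+1 of the mature sequence", {
  expect_equal(extract_seed("UAGUACGUUAUCGAUGGCAA", 6), "AGUACG")
  expect_equal(extract_seed("UAGUACGUUAUCGAUGGCAA", 7), "AGUACGU")
  expect_equal(extract_seed("UAAAGCU", 6), "AAAGCU")
  expect_error(extract_seed("UAAAGCU", 8), "too short")
  expect_error(extract_seed("UAAAGCUG", 5), "must be 6, 7 or 8")
})

test_that("seed families partition matures by exact seed identity", {
  matures <- tibble::tibble(
    mature_id = c("b", "a"),
    mature_seq = c("UAGUACGAAAAAAAAAAAAA", "CAGUACGCCCCCCCCCCCCC"))
  fam <- seed_families(matures, 6)
  expect_equal(nrow(fam), 1)
  expect_equal(fam$members[[1]], c("a", "b"))

  ## one mature per major seed family: seven families out
  major <- c("AGUACG", "AGUACA", "CACUGG", "AUCACA", "UAAAGC", "GACUAG",
             "AAUACU")
  tbl <- tibble::tibble(
    mature_id = sprintf("m%d", seq_along(major)),
    mature_seq = paste0("U", major, "UUACGGAUCCAUGGA"))
  fams <- seed_families(tbl, 6)
  expect_equal(nrow(fams), 7)
  expect_setequal(fams$seed, major)

  ## larger k refines but never merges
  withr::local_seed(19)
  rnd <- tibble::tibble(
    mature_id = sprintf("r%02d", 1:40),
    mature_seq = vapply(1:40, function(i) {
      paste0("U", sample(c("AGUACG", "UAAAGC", "CACUGG"), 1),
             rand_dna(14))
    }, character(1)))
  f6 <- seed_families(rnd, 6)
  f8 <- seed_families(rnd, 8)
  member_to_seed6 <- setNames(rep(f6$seed, lengths(f6$members)),
                              unlist(f6$members))
  for (j in seq_len(nrow(f8))) {
    parents <- unique(member_to_seed6[f8$members[[j]]])
    expect_length(parents, 1)
  }
})
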