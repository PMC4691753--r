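test_that("UTR merging deduplicates and spaces with N", {
  one <- tibble::tibble(gene = "g1", transcript = "t1", utr_seq = "ACGTACGT")
  expect_equal(merge_utrs(one)$utr_seq, "ACGTACGT")

  dup <- tibble::tibble(gene = "g1", transcript = c("t1", "t2"),
                        utr_seq = c("ACGTACGT", "ACGTACGT"))
  expect_equal(merge_utrs(dup)$utr_seq, "ACGTACGT")

  two <- tibble::tibble(gene = "g1", transcript = c("t1", "t2"),
                        utr_seq = c("ACGTACGT", "TTTTCCCC"))
  merged <- merge_utrs(two)$utr_seq
  expect_equal(merged, paste0("ACGTACGT", strrep("N", 8), "TTTTCCCC"))

  ## a site present only in the second transcript is still found
  mature <- "UAGUACGUUAUCGAUGGCAA"
  site_utr <- plant_sites(strrep("C", 40), mature, "7mer-A1", 12)
  both <- tibble::tibble(gene = "g2", transcript = c("t1", "t2"),
                         utr_seq = c(strrep("G", 30), site_utr))
  sites <- find_sites(tibble::tibble(mature_id = "m", mature_seq = mature),
                      merge_utrs(both))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$class, "7mer-A1")

  empty <- tibble::tibble(gene = c("g1", "g3"), transcript = c("t1", "t3"),
                          utr_seq = c("ACGT", ""))
  expect_warning(kept <- merge_utrs(empty), "g3")
  expect_equal(kept$gene, "g1")
})

test_that("canonical site classes follow the seed-match definitions", {
  mature <- "UAGUACGUU" # seed AGUACG, position 8 U
  ## revcomp(AGUACG) = CGTACT; with trailing A -> 7mer-A1
  utr <- tibble::tibble(gene = "g", utr_seq = "GGGGCGTACTAGGGG")
  sites <- find_sites(tibble::tibble(mature_id = "m", mature_seq = mature), utr)
  expect_equal(sites$class, "7mer-A1")
  expect_equal(sites$offset, 4)

  ## preceding A (complement of m8 = U) upgrades to 7mer-m8 / 8mer
  utr_m8 <- tibble::tibble(gene = "g", utr_seq = "GGGGACGTACTTGGGG")
  expect_equal(find_sites(tibble::tibble(mature_id = "m", mature_seq = mature),
                          utr_m8)$class, "7mer-m8")
  utr_8 <- tibble::tibble(gene = "g", utr_seq = "GGGGACGTACTAGGGG")
  s8 <- find_sites(tibble::tibble(mature_id = "m", mature_seq = mature), utr_8)
  expect_equal(s8$class, "8mer")
  expect_equal(s8$offset, 4)

  ## N never matches
  utr_n <- tibble::tibble(gene = "g", utr_seq = strrep("N", 50))
  expect_equal(nrow(find_sites(tibble::tibble(mature_id = "m",
                                              mature_seq = mature), utr_n)), 0)
})

test_that("site finding equals brute-force window enumeration", {
  withr::local_seed(71)
  matures <- tibble::tibble(
    mature_id = c("m1", "m2", "m3"),
    mature_seq = vapply(1:3, function(i) rand_dna(22), character(1)))
  utrs <- tibble::tibble(gene = sprintf("g%d", 1:4),
                         utr_seq = vapply(1:4, function(i) rand_dna(2000),
                                          character(1)))
  got <- find_sites(matures, utrs)
  for (mi in seq_len(nrow(matures))) {
    for (gi in seq_len(nrow(utrs))) {
      want <- bf_scan_sites(matures$mature_seq[mi], utrs$utr_seq[gi])
      sub <- got[got$mature_id == matures$mature_id[mi] &
                   got$gene == utrs$gene[gi], ]
      expect_equal(nrow(sub), nrow(want))
      if (nrow(want)) {
        expect_equal(sort(sub$offset), sort(want$offset))
        expect_equal(sub$class[order(sub$offset)],
                     want$class[order(want$offset)])
      }
    }
  }
})

test_that("gene-level targets respect the class threshold", {
  mature <- "UAGUACGUUAUCGAUGGCAA"
  matures <- tibble::tibble(mature_id = "m", mature_seq = mature)
  utr6 <- plant_sites(strrep("C", 60), mature, "6mer", 10)
  utrs <- tibble::tibble(gene = "g", utr_seq = utr6)
  expect_equal(nrow(predict_targets(matures, utrs, min_class = "8mer")), 0)
  expect_equal(nrow(predict_targets(matures, utrs, min_class = "6mer")), 1)
  ## a lone 6mer does not count under the default threshold
  expect_equal(nrow(predict_targets(matures, utrs)), 0)
  expect_error(predict_targets(matures, utrs, min_class = "9mer"), "min_class")

  ## seed-identical matures have identical seed-level target sets
  matures2 <- tibble::tibble(
    mature_id = c("p", "q"),
    mature_seq = c("UAGUACGUAAAAAAAAAAAA", "CAGUACGUCCCCCCCCCCCC"))
  utr_pair <- tibble::tibble(
    gene = "g", utr_seq = plant_sites(strrep("C", 60), matures2$mature_seq[1],
                                      "8mer", 20))
  tg <- predict_targets(matures2, utr_pair)
  expect_setequal(tg$mature_id, c("p", "q"))
  expect_equal(tg$best_class, c("8mer", "8mer"))
})

test_that("predicted pairs on simulated data equal the truth record", {
  sim <- sim_default()
  matures <- dplyr::select(sim$loci, mature_id, mature_seq)
  pairs <- predict_targets(matures, sim$utrs)
  expect_identical(sort(paste(pairs$mature_id, pairs$gene)),
                   sort(paste(sim$truth$pairs$mature_id,
                              sim$truth$pairs$gene)))
})
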