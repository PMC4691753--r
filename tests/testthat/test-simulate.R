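test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config(rng_seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$libraries, b$libraries)
  expect_identical(a$utrs, b$utrs)
  expect_identical(a$truth$pairs, b$truth$pairs)

  da <- withr::local_tempdir()
  db <- withr::local_tempdir()
  write_sim_dataset(a, da)
  write_sim_dataset(b, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f), warn = FALSE),
                     readLines(file.path(db, f), warn = FALSE),
                     label = paste("file", f))
  }
})

test_that("zero modification probability yields empty planted tails", {
  cfg <- small_sim_config(rng_seed = 3, tail_prob = 0)
  sim <- simulate_dataset(cfg)
  for (stage in names(sim$truth$reads)) {
    expect_true(all(nchar(sim$truth$reads[[stage]]$planted_tail) == 0))
  }
})

test_that("emitted reads are templated mature sequence plus the planted tail", {
  sim <- sim_default()
  tr <- sim$truth$reads[["e8_16h"]]
  loci <- sim$loci
  for (i in sample.int(nrow(tr), 50)) {
    a <- loci[loci$mature_id == tr$mature_id[i], ]
    templ <- substr(sim$genome[[a$chrom]], a$mature_start + 1,
                    tr$templated_end[i])
    expect_identical(tr$seq[i], paste0(templ, tr$planted_tail[i]))
  }
})

test_that("collapsed library counts reproduce the truth record exactly", {
  sim <- sim_default()
  for (stage in names(sim$libraries)) {
    tr <- sim$truth$reads[[stage]]
    spikes_in_lib <- sim$spikes[[paste0("count_", stage)]]
    lib_total <- sum(sim$libraries[[stage]]$count)
    expect_equal(lib_total, sum(tr$count) + sum(spikes_in_lib))
    agg <- tapply(tr$count, tr$seq, sum)
    lib <- sim$libraries[[stage]]
    mirna_rows <- lib$seq %in% names(agg)
    expect_equal(lib$count[mirna_rows],
                 as.vector(agg[lib$seq[mirna_rows]]))
  }
})

test_that("detectable-tail bookkeeping follows the genomic continuation", {
  sim <- sim_default()
  tr <- sim$truth$reads[["e8_16h"]]
  tailed <- tr[nchar(tr$planted_tail) > 0, ]
  first_match <- substr(tailed$planted_tail, 1, 1) ==
    substr(tailed$continuation, 1, 1)
  expect_identical(tailed$first_base_detectable, !first_match)
  ## a read flagged detectable under the first-base rule is detectable
  expect_true(all(tailed$detectable[tailed$first_base_detectable]))
  ## detectable fraction cannot exceed planted fraction
  rates <- sim$truth$detectable_rates
  expect_true(all(rates$detectable_modified <= rates$planted_modified))
})

test_that("planted site classes are recoverable by brute substring scan", {
  sim <- sim_default()
  plan <- sim$truth$plan
  for (i in sample.int(nrow(plan), 25)) {
    utr <- sim$utrs$utr_seq[sim$utrs$gene == plan$gene[i]]
    mat <- sim$loci$mature_seq[sim$loci$mature_id == plan$mature_id[i]]
    found <- bf_scan_sites(mat, utr)
    expect_true(plan$class[i] %in% found$class,
                label = paste(plan$mature_id[i], plan$gene[i], plan$class[i]))
  }
})

test_that("simulate_tail honours degenerate and stochastic models", {
  point2A <- tail_model(prob = 1, length_probs = c(0, 1, 0, 0, 0),
                        base_probs = matrix(rep(c(1, 0, 0, 0), 5), nrow = 5,
                                            byrow = TRUE,
                                            dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_identical(simulate_tail("UGAGGUAGU", point2A, rng_seed = 1),
                   "UGAGGUAGUAA")
  expect_identical(simulate_tail("UGAGGUAGU", tail_model(prob = 0), rng_seed = 1),
                   "UGAGGUAGU")

  n <- 10000
  reads <- simulate_tail("ACGTACGTACGT", tail_model(prob = 0.2), n = n,
                         rng_seed = 99)
  frac <- mean(nchar(reads) > 12)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("plant_sites substitutes in place and flags collisions", {
  utr <- strrep("C", 60)
  mature <- "UAGUACGUUAUCGAUGGCAA"
  planted <- plant_sites(utr, mature, "6mer", positions = 10)
  expect_equal(nchar(planted), nchar(utr))
  found <- bf_scan_sites(mature, planted)
  expect_equal(nrow(found), 1)
  expect_equal(found$offset, 10)

  ## planting nothing returns the input unchanged
  expect_identical(plant_sites(utr, mature, "8mer", integer(0)), utr)

  ## the 8mer site nests the lower classes definitionally: destroying the
  ## flanks one at a time downgrades the call
  p8 <- plant_sites(utr, mature, "8mer", positions = 20)
  expect_equal(bf_scan_sites(mature, p8)$class, "8mer")
  expect_error(plant_sites(p8, mature, "6mer", positions = 22),
               "collides")
  expect_error(plant_sites(utr, mature, "8mer", positions = 55), "fit")
})

test_that("invalid locus plans are rejected with diagnostics", {
  out_of_bounds <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(2000, 20000, 2000, 15000, 39990),
    n_members = c(2, 1, 1, 1, 1),
    spacing = c(3000, 0, 0, 0, 0))
  expect_error(simulate_dataset(small_sim_config(cluster_plan = out_of_bounds)),
               "outside")
  overlapping <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(2000, 2030, 2000, 15000, 30000),
    n_members = c(2, 1, 1, 1, 1),
    spacing = c(3000, 0, 0, 0, 0))
  expect_error(simulate_dataset(small_sim_config(cluster_plan = overlapping)),
               "overlap")
})
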