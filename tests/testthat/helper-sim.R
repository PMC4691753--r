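## Shared fixtures, built in code. The default simulation is computed once
## per test run and memoised; a scaled-down config keeps pipeline-level
## tests fast.

.fixture_env <- new.env(parent = emptyenv())

sim_default <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(sim_config())
  }
  .fixture_env$sim
}

small_sim_config <- function(rng_seed = 42, cluster_plan = NULL, ...) {
  if (is.null(cluster_plan)) {
    cluster_plan <- tibble::tibble(
      chrom = c("chr1", "chr1", "chr2", "chr2", "chr2"),
      start = c(2000, 20000, 2000, 15000, 30000),
      n_members = c(2, 1, 1, 1, 1),
      spacing = c(3000, 0, 0, 0, 0)
    )
  }
  sim_config(
    rng_seed = rng_seed,
    chrom_length = 40000,
    cluster_plan = cluster_plan,
    stages = c("oocyte", "e8_16h", "e16_24h"),
    clearance_loci = c(1, 2),
    reference_locus = 4,
    seed_plan = c("tca-miR-01-3p" = "AGUACGU", "tca-miR-02-3p" = "AGUACGU"),
    n_genes = 80,
    n_down = 15,
    n_up = 15,
    targets_per_clearance = 10,
    offtargets_per_clearance = 2,
    comparisons = c("e8_16h", "e16_24h"),
    ...
  )
}

## single-library configuration sized to ~10,000 reads for tail-recovery
## checks; expression flat so every mature contributes
tail_grid_config <- function(p, rng_seed) {
  sim_config(rng_seed = rng_seed,
             stages = "oocyte",
             comparisons = "oocyte",
             tail_prob = p,
             expression = matrix(800, nrow = 12, ncol = 1,
                                 dimnames = list(NULL, "oocyte")))
}

## memoised tail-calling runs over the planted modification grid
tail_grid_runs <- function() {
  if (is.null(.fixture_env$tail_grid)) {
    .fixture_env$tail_grid <- lapply(
      setNames(c(0.05, 0.2, 0.5), c("p05", "p20", "p50")),
      function(p) {
        sim <- simulate_dataset(tail_grid_config(p, rng_seed = 8012))
        calls <- call_tails(sim$libraries[["oocyte"]], sim$genome,
                            loci = sim$loci)
        list(sim = sim, calls = calls, summary = summarize_tails(calls))
      })
  }
  .fixture_env$tail_grid
}

## a 2-chromosome toy genome with a known 22-mer planted at chr1:100
toy_genome <- function(seed = 7, len = 2000) {
  withr::with_seed(seed, {
    g <- c(chr1 = rand_dna(len), chr2 = rand_dna(len))
    g
  })
}

## a minimal one-hairpin loci table around a planted mature
toy_loci <- function(chrom = "chr1", hp_start = 90, hp_end = 160,
                     m_start = 100, m_end = 122, id = "miR-x-3p",
                     locus = "mir-x", strand = "+", genome = NULL) {
  seq <- if (is.null(genome)) NA_character_ else {
    as_rna(substr(genome[[chrom]], m_start + 1, m_end))
  }
  tibble::tibble(locus_id = locus, mature_id = id, arm = "3p",
                 chrom = chrom, strand = strand,
                 hairpin_start = hp_start, hairpin_end = hp_end,
                 mature_start = m_start, mature_end = m_end,
                 mature_seq = seq)
}
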