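## Brute-force oracles, independent of the package's implementation paths.

## slide the read across every position and strand; report best stratum
bf_map <- function(genome, read, max_mm = 1) {
  read <- chartr("U", "T", toupper(read))
  w <- nchar(read)
  rb <- strsplit(read, "")[[1]]
  rc <- strsplit(mirtailor::revcomp(read), "")[[1]]
  hits <- list()
  for (chrom in names(genome)) {
    gb <- strsplit(genome[[chrom]], "")[[1]]
    n <- length(gb)
    if (n < w) next
    for (s in 1:(n - w + 1)) {
      seg <- gb[s:(s + w - 1)]
      mmf <- sum(seg != rb)
      if (mmf <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(
          chrom = chrom, strand = "+", start = s - 1L, end = s - 1L + w,
          mismatches = mmf)
      }
      mmr <- sum(seg != rc)
      if (mmr <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(
          chrom = chrom, strand = "-", start = s - 1L, end = s - 1L + w,
          mismatches = mmr)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[out$mismatches == min(out$mismatches), , drop = FALSE]
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

## rank-then-Pearson Spearman with average ranks
bf_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## step-up Benjamini-Hochberg: sort, p * m / i, cumulative min from the right
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## enumerate every window of a UTR against the four canonical patterns,
## resolving each seed-core occurrence to its highest class
bf_scan_sites <- function(mature_seq, utr) {
  m <- chartr("U", "T", toupper(mature_seq))
  seed6 <- substr(m, 2, 7); seed7 <- substr(m, 2, 8)
  core <- mirtailor::revcomp(seed6)
  m8c <- chartr("ACGT", "TGCA", substr(m, 8, 8))
  n <- nchar(utr)
  out <- list()
  for (s in 1:(n - 5)) {
    if (substr(utr, s, s + 5) != core) next
    before <- if (s > 1) substr(utr, s - 1, s - 1) else ""
    after <- if (s + 6 <= n) substr(utr, s + 6, s + 6) else ""
    has_m8 <- before == m8c
    has_a1 <- after == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    out[[length(out) + 1]] <- data.frame(
      class = cls, offset = if (has_m8) s - 2L else s - 1L)
  }
  if (length(out) == 0) return(data.frame(class = character(), offset = integer()))
  do.call(rbind, out)
}

## exact upper-tail hypergeometric by enumeration over k
bf_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## exact-match scan via vectorised window extraction (both strands)
scan_exact <- function(genome, pattern) {
  w <- nchar(pattern)
  pat_rc <- mirtailor::revcomp(pattern)
  hits <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]])
    if (n < w) next
    win <- substring(genome[[chrom]], 1:(n - w + 1), w:n)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pattern else pat_rc
      at <- which(win == p)
      if (length(at)) {
        hits[[length(hits) + 1]] <- data.frame(
          chrom = chrom, strand = strand, start = at - 1L, end = at - 1L + w)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  }
  do.call(rbind, hits)
}

## re-verify tail calls against the raw genome text at the reported locus:
## the templated prefix must equal the genomic substring, and the first
## tail base must differ from the genomic continuation; returns the number
## of violations
verify_tail_contract <- function(genome, tailed) {
  bad <- 0L
  for (i in seq_len(nrow(tailed))) {
    ct <- mirtailor::call_tail(genome, tailed$seq[i])
    h <- ct$hits[[1]][1, ]
    prefix <- substr(tailed$seq[i], 1, ct$prefix_len)
    if (h$strand == "+") {
      genomic <- substr(genome[[h$chrom]], h$start + 1, h$end)
      cont <- substr(genome[[h$chrom]], h$end + 1, h$end + 1)
    } else {
      genomic <- mirtailor::revcomp(substr(genome[[h$chrom]], h$start + 1, h$end))
      cont <- mirtailor::revcomp(substr(genome[[h$chrom]], h$start, h$start))
    }
    ok <- identical(ct$status, "tailed") &&
      identical(ct$tail, tailed$tail[i]) &&
      identical(genomic, prefix) &&
      substr(ct$tail, 1, 1) != cont
    if (!ok) bad <- bad + 1L
  }
  bad
}
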