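---
title: "Methods: tail calling, absolute quantification and clearance-microRNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tail calling, absolute quantification and clearance-microRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mirtailor implements the bespoke computations of a developmental small
RNA-seq study of the maternal-to-zygotic transition (MZT): detection of
nontemplated 3′-end additions on mature microRNAs, absolute quantification
of maternal microRNA content, genomic clustering and seed-family grouping of
microRNA loci, canonical 3′-UTR target prediction, and enrichment statistics
that flag the microRNAs driving maternal transcript clearance. This vignette
documents the models, the parameters that matter, the numerical choices, and
what the synthetic-data tests do and do not establish.

## Read mapping and counting

`map_read()` is an exhaustive substitution-only aligner over both strands of
every chromosome. It reports *all* hits in the best mismatch stratum: if any
0-mismatch hit exists, 1-mismatch hits are suppressed. This reproduces the
common small-RNA policy `bowtie -v 1 -a --best --strata -m 5`:

- `max_mismatches = 1` (exposed; 2 is used as a sensitivity variant in
  absolute quantification),
- reads hitting more than `max_loci = 5` genomic places are discarded,
- a retained read with *n* hits contributes `count/n` to each hit
  (`quantify_library()`), so fractional contributions of a read always sum
  to its collapsed count,
- expression is normalized as reads per million genome-mapped reads
  (`rpm()`); a zero-total library is an error naming the library, never a
  silent division.

Assignment of an alignment to a mature microRNA is not fully standardized in
the field; we use a 5′-anchor rule: the alignment's 5′ start must lie within
±3 nt of the annotated mature 5′ end (microRNA 5′ ends are homogeneous
because they define the seed), and the alignment must lie within the hairpin
extended by the same 3-nt slack. The slack on the hairpin boundary matters
because mature 3p arms commonly end exactly at the annotated hairpin end, and
reads carrying 1–2 nt of 3′ addition still align with one mismatch but would
otherwise be orphaned. The mapper is an exhaustive scan because correctness,
not throughput, is the goal at the package's scale (hundreds of kilobases);
Biostrings provides the string matching underneath.

Reads of 16 nt or shorter are excluded throughout, matching the global
read-length cutoff of adapter-trimmed small-RNA libraries.

## Nontemplated 3′-tail calling

`call_tail()` implements iterative 3′ trimming: if the full read maps with 0
mismatches it is *untailed*; otherwise trim 1 nt from the 3′ end and remap,
until either a perfect hit is found (a *tailed* call) or the remaining prefix
would drop below `min_prefix = 16` (*unmapped*). The templated prefix is
therefore the longest perfectly mapping prefix, and the tail is its
complement in the read.

Two consequences shape interpretation:

- An addition identical to the genomic continuation is invisible — the read
  simply maps full-length. Reported modification rates are conservative.
- A tail whose first base continues the template but whose second base does
  not is still detected, with the boundary shifted: the recovered tail is
  the suffix after the longest templated extension. The simulator's truth
  record stores exactly this maximal-prefix decomposition (alongside the
  simpler first-base detectability flag), so recovery tests compare like
  with like.

`summarize_tails()` reports count-weighted modified proportions (overall and
per mature), the tail-length histogram, and a 5-position × 4-nucleotide
composition matrix. Tails longer than 5 nt contribute only their first five
positions to the matrix; positions with no observations are flagged rather
than zero-filled. Per-microRNA proportions are weighted by collapsed counts
across all sequence variants of a mature; multi-mapping prefixes keep the
same 1/n fractional weighting as counting, so tailing and expression
bookkeeping agree.

## Absolute quantification

`absolute_quantify()` treats all microRNA reads as equimolar per read — read
count is the only abundance proxy a sequencing library offers — and scales by
a reference of known amount:

```
fmol_per_egg = total_miRNA_reads / reference_reads × reference_fmol / n_eggs
molecules    = fmol × 1e-15 × 6.02214076e23
```

Each spike-in yields its own estimate; the pipeline reports every estimate
and their spread rather than collapsing them silently. The endogenous
reference (an abundant microRNA whose cellular amount is known independently,
e.g. from qPCR) enters through the same formula.

The pipeline reports estimates under three totals: full-length mapping at 1
and at 2 mismatches (the sensitivity pair), and *tail-inclusive* totals in
which reads recovered by the trimming caller are added back. Tail-inclusive
totals are the least biased: multi-nucleotide tails prevent full-length
mapping, so mapping-only totals undercount microRNAs relative to tail-free
spike-ins by roughly the multi-nt tailing rate (~8–10% under the default
model). The endogenous-reference ratio is insensitive to this choice since
numerator and denominator lose the same fraction — the agreement of the two
references is therefore a meaningful internal consistency check, and it is
asserted in the test suite.

`stage_correlation()` computes Spearman correlations (average ranks on ties
— the standard definition) for all library pairs; constant libraries yield
`NA` with a warning naming the library, never a silent zero.

## Locus clustering and seed families

`cluster_loci()` chains hairpins on the same chromosome whose nearest
boundaries are at most `max_gap = 10000` bases apart (single linkage). The
10-kb rule is the conventional definition of a microRNA cluster; distance is
measured end-to-start because midpoint or start-start conventions give
different answers for long hairpins and the boundary convention is the most
conservative. Strand is ignored, matching how clusters are drawn in genome
maps. The result is a partition and is invariant to input order.

`extract_seed()` returns mature positions 2..k+1 (k = 6, 7 or 8);
`seed_families()` partitions matures by exact seed identity. Larger k
refines, never merges, smaller-k families — a property the tests assert.
Hairpin-level homology families (alignment- or covariance-model-based) are
out of scope; the seed is the determinant of canonical targeting and of the
downstream enrichment analysis.

## Canonical target prediction

For a mature with seed *s* = positions 2–7 and *m8* = position 8 (U ≡ T),
scanning the UTR 5′→3′:

| class   | target pattern                          |
|---------|-----------------------------------------|
| 6mer    | revcomp(s)                              |
| 7mer-A1 | revcomp(s) + "A"                        |
| 7mer-m8 | revcomp(s₂₋₈)                           |
| 8mer    | revcomp(s₂₋₈) + "A"                     |

Every canonical site contains the 6mer core, so `find_sites()` scans for the
core (overlapping occurrences included) and resolves each occurrence to its
highest class from the flanking bases (8mer > 7mer-m8 > 7mer-A1 > 6mer),
reporting each genomic occurrence once. `N` never matches. The site offset is
the 0-based position of the site string's 5′ end.

`predict_targets()` calls a gene a target given ≥1 site of class ≥
`min_class`. The default is `7mer-A1` — 7mers and 8mers are the conventional
"canonical" core, and lone 6mers are weak and noisy — with `6mer` mode
available; the threshold is recorded on the output since published canonical
implementations differ and rarely state it.

`merge_utrs()` concatenates distinct per-transcript UTRs of a gene with an
8-N spacer. UTR genome coordinates are not modelled, so interval union is
unavailable; the spacer prevents chimeric sites spanning transcript
boundaries (no site class is longer than 8 nt).

## Enrichment statistics

`classify_genes()` applies the symmetric rule: *down* if log2FC ≤
−log2(`fold_threshold`) with adjusted p < `alpha` (defaults 2 and 0.05),
*up* symmetric, otherwise *none* (including low-significance large-fold
genes). Genes lacking an adjusted p are excluded and counted. The universe
for all enrichment tests is genes with a UTR record **and** a DE record —
enrichment must condition on testable genes.

`enrich_hyper()` is the upper-tail hypergeometric P(X ≥ k) for k overlaps
between a microRNA's target set (intersected with the universe) and a gene
set. `enrich_perm()` draws size-matched gene sets without replacement
(`n_perm = 1000`) and applies the `(1 + #{perm ≥ obs}) / (n_perm + 1)`
pseudocount — standard practice that avoids zero p-values. Because the
permutation null *is* the hypergeometric law, the two agree within
Monte-Carlo error; the suite checks this on random instances. Bonferroni
correction uses family size = microRNAs × gene sets tested, recorded in the
output metadata since the appropriate family is an analysis choice.

`word_enrich()` is a set-based simplification of ranked word-landscape
(Sylamer-style) analysis: for each of the 4^k words (k = 6 by default,
4–8 allowed), a hypergeometric test of "gene's UTR contains the word" in the
gene set versus the universe, Bonferroni over 4^k. It is labelled
"sylamer-like"; it does not reproduce the ranked landscape, only the
predictor-free sanity check that seed-complementary words surface in
down-regulated UTRs.

`rank_mirnas()` flags clearance candidates: Bonferroni p < 0.001 in at least
one down-regulated set and not significant in any up-regulated set, and
attaches expression for expression-versus-enrichment plots.

## The synthetic study and its truth record

`sim_config()` fixes the study conditions; `simulate_dataset()` is
deterministic given `rng_seed`. Defaults:

- **Genome/loci:** 2 × 100 kb chromosomes, 12 hairpins (70 nt; 22-nt 5p/3p
  arms): a 3-hairpin cluster (3-kb spacing), a 2-hairpin cluster (9.2 kb,
  inside the 10-kb rule), 7 singletons spaced beyond it. Plus strand only;
  the mapper itself is strand-complete and tested on both.
- **Stages:** oocyte, 0–5 h, 8–16 h, 16–24 h, 24–48 h — the pre-ZT stages
  and the three embryo-versus-oocyte comparisons the clearance analysis
  uses. Expected 3p-arm counts: ~150–250 per constitutive locus, 600 for
  the endogenous reference, and 5 → 300–400 for the four clearance loci
  that switch on at 8–16 h; 5p arms at 5% of 3p. Counts are Poisson.
- **Seed families:** clearance 3p arms carry seeds AGUACG (×2, one shared
  family), AGUACA and CACUGG at positions 2–8, emulating convergent seed
  families among early zygotic microRNAs.
- **Tails:** per-read modification probability 0.2; lengths 1–5 with
  probabilities (0.55, 0.30, 0.10, 0.04, 0.01); composition
  adenosine-dominated (position 1: A = 0.95). These reproduce the
  qualitative picture of short, A-led additions. The truth stores each
  read's planted tail, its maximal-prefix detectable decomposition, and
  per-mature detectable rates.
- **Absolute content:** 0.2 fmol of microRNA per egg, 10 eggs per library.
  Sequencing depth is defined as expected reads per fmol, making spike-in
  counts (two spikes, 1 and 2 fmol) coherent with the planted content; the
  endogenous reference's true fmol is its expected read share times the
  total content. Spike sequences are verified absent from the genome.
- **Targeting/DE:** 250 genes with 400-nt UTRs; 40 down, 40 up, 170 none
  (identical classes across the three comparisons, so the intersection
  sets equal the planted classes); each clearance microRNA targets 25
  down-class genes plus 3 none-class off-targets (8mer/7mer-m8/7mer-A1
  mix); one non-clearance microRNA receives 12 uniformly placed targets as
  an unenriched control. Planted log2 fold changes and adjusted p-values
  respect the classification thresholds by construction.

Chance seed matches in random UTRs would blur the planted truth, so the
generator scrubs them by default (`scrub_chance_sites`): any 6mer core of
any simulated mature occurring outside a planted site is destroyed by a
single-base substitution, iterating until clean. Planting retries positions
so that no foreign core is created at a site boundary and the realized class
equals the requested class. Because rare collisions can survive (a foreign
core inside a planted site string cannot be scrubbed without destroying the
site), the truth's site and pair tables are derived by an independent
brute-force substring scan of the final UTRs — the truth records what was
actually emitted, and the planted plan is stored alongside.

**What the synthetic data does not emulate:** sequencing error, 5′-end
heterogeneity (templated 3′ variation exists behind a default-off
parameter), piRNA background, minus-strand loci, expression-dependent
biases, UTR base composition, or miRanda-style energy scoring. Passing tests
therefore establish the correctness of the algorithms under their stated
contracts, not field performance on real libraries.

## Problem sizes and numerical choices

The suite runs the default study (~2,200–3,700 reads per library), a
~10,000-read single-library grid over planted tailing rates
{0.05, 0.2, 0.5}, 1 Mb of random UTR for site-finder equivalence, 50 random
instances of permutation-versus-hypergeometric concordance at 1,000
permutations, and the end-to-end demo — sizes chosen so the full suite runs
in a few minutes on one CPU while keeping binomial standard errors tight
enough for 3-SE recovery checks. Monte-Carlo assertions use 3-SE tolerances
with the permutation pseudocount added; one 3-sigma excursion among 50
instances is tolerated as expected behaviour of an honest test. All
randomness flows from explicit seeds; enrichment permutation seeds are
derived per microRNA × gene set so results are order-independent.

Degenerate inputs are contracts, not corner cases: empty libraries give
all-zero columns, zero-total libraries and empty universes are errors naming
the offender, constant expression columns give flagged `NA` correlations,
all-empty merged UTRs exclude the gene with a diagnostic, and the tail
caller's three-way return (`untailed`/`tailed`/`unmapped`) has no error
branch.

## Known limitations

- The 1/n multi-map split is the simplest reading of multi-map correction;
  expectation-maximization re-assignment is out of scope.
- The mapper supports substitutions only (no indels, no quality scores) and
  emits no SAM; it is not meant for genome-scale data.
- Word enrichment is set-based, not a ranked landscape.
- The ±3-nt 5′-anchor assignment rule is a package decision; annotations
  with heterogeneous 5′ ends may need a wider anchor.
- DE tables are consumed, never computed; the package does not wrap a DE
  engine.
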