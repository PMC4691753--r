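# mirtailor

Tidy analysis of developmental small RNA-seq: nontemplated 3′-end tailing of
mature microRNAs, absolute microRNA quantification, microRNA locus clustering
and seed families, canonical 3′-UTR target prediction, and target-enrichment
statistics linking early zygotic microRNAs to maternal transcript clearance.

## The problem

During the maternal-to-zygotic transition (MZT), maternally deposited mRNAs
are cleared while the zygotic genome switches on. In insects, specific
microRNAs expressed immediately after zygotic genome activation drive part of
this clearance by pairing their seed region (mature positions 2–7/8) with
sites in maternal 3′ UTRs. Analysing this from small RNA-seq requires several
bespoke computations that general-purpose tools do not provide:

- **3′ tail calling.** Nontemplated nucleotides (mostly adenosines) are added
  to microRNA 3′ ends. A read carrying such a tail fails to map full-length;
  trimming one base at a time from the 3′ end and remapping until the prefix
  maps perfectly decomposes the read into a templated prefix and a
  nontemplated tail. Only additions that differ from the genomic sequence
  immediately downstream are observable, so estimates are conservative.
- **Absolute quantification.** Spiking synthetic 5′-phosphorylated
  oligonucleotides of known molar amount into a library of a counted number
  of eggs converts read counts to fmol per egg:
  `fmol/egg = total_miRNA_reads / reference_reads × reference_fmol / n_eggs`,
  and fmol to molecules via Avogadro's number. An abundant endogenous
  microRNA quantified independently serves as a second reference.
- **Counting policy.** Reads map with up to 1 mismatch, best stratum only;
  reads hitting more than 5 loci are discarded; retained multi-mappers
  contribute 1/n per locus; expression is reads per million genome-mapped.
- **Targeting and enrichment.** Canonical site classes (8mer > 7mer-m8 >
  7mer-A1 > 6mer) are scanned over merged per-gene 3′ UTRs; per-microRNA
  target sets are tested for enrichment in down-/up-/non-regulated gene
  classes by the hypergeometric upper tail and size-matched permutation
  (1000 draws), Bonferroni-corrected; a set-based 6-mer word-enrichment
  scan provides a predictor-free cross-check.

Everything is testable offline: a synthetic-data module generates a genome,
microRNA loci (with clusters and seed families), stage libraries with planted
tails, spike-ins, UTRs with planted sites, and DE tables, together with a
machine-readable truth record.

## Worked example

```r
library(mirtailor)

sim <- simulate_dataset(sim_config())   # deterministic toy study
sim
#> <mir_sim>
#>   genome: 2 chromosome(s), 200,000 bases
#>   loci: 12 hairpins (24 mature arms)
#>   libraries: oocyte, e0_5h, e8_16h, e16_24h, e24_48h
#>   genes: 250; planted target pairs: 148; clearance microRNAs: 4

res <- run_pipeline(sim)
res
#> <mir_pipeline>
#>   libraries: oocyte, e0_5h, e8_16h, e16_24h, e24_48h
#>   flagged clearance microRNAs: tca-miR-01-3p, tca-miR-02-3p, tca-miR-03-3p, tca-miR-06-3p
#>   recovery vs truth: 3/3 checks pass
```

The flagged set is exactly the four planted clearance microRNAs: those
switched on at 8–16 h whose targets were planted in the down-regulated gene
class. Absolute quantification of the oocyte library against the spike-ins
(tail-inclusive totals) recovers the planted content of 0.2 fmol of microRNA
per egg:

```r
dplyr::filter(res$absolute, totals == "tail_inclusive")
#>   reference        fmol_per_egg molecules_per_egg
#> 1 spike-in:spike1        0.199        119905604
#> 2 spike-in:spike2        0.199        119638791
#> 3 endogenous             0.202        121745635
```

i.e. ~1.2 × 10⁸ microRNA molecules per egg, with the spike-in and the
endogenous reference in agreement. Tail calling on the 8–16 h library
reports an 18% modified fraction with ~95% of tails 1–3 nt long and
position 1 dominated by adenosine (`glance(res$tails[["e8_16h"]])`,
`res$tails[["e8_16h"]]$composition`). `res$words` shows the 6-mer words
enriched in down-regulated UTRs; the reverse complements of the planted
family seeds (e.g. `CGTACT` for seed `AGUACG`) rank at the top.

Plots: `autoplot(res$tails[["e8_16h"]])`, `plot_tail_composition(...)`,
`autoplot(res$correlation)`, `plot_clearance(res$clearance)`.

A thin command-line wrapper over these functions ships in
`inst/scripts/mirtailor` (subcommands `simulate`, `map`, `tails`,
`quantify`, `catalog`, `targets`, `enrich`, `run-all`).

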