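# thelytools

Diagnosing the cytological mechanism of thelytokous parthenogenesis from
parent–offspring genetic markers.

In haplodiploid wasps, unfertilised eggs normally become haploid males
(arrhenotoky); in thelytokous lineages they become diploid females, and the
diploidy can be restored by several cytological routes — apomixis (clonal,
no meiosis) or automixis with central fusion, terminal fusion, gamete
duplication, or random fusion of meiotic products. Each route homozygoses a
heterozygous maternal locus at a characteristic expected rate *r*:

| mechanism          | *r*     |
|--------------------|---------|
| apomixis           | 0       |
| central fusion     | 0–1/3   |
| random fusion      | 1/3     |
| terminal fusion    | 1/3–1   |
| gamete duplication | 1       |

Given a brood of known parentage, the observed transition rate
*R* = N<sub>o</sub> / (N<sub>t</sub> + N<sub>o</sub>) (homozygous over
total offspring of heterozygous mothers) is tested against each *r* with a
two-sided Fisher exact test; for the ranged mechanisms the endpoint closest
to *R* is used. The package provides the full pipeline around this
statistic:

* `simulate_meiosis()` / `restore_diploidy()` / `simulate_pedigree()` — a
  chromatid-level simulator of meiosis and all five diploidy-restoration
  modes, parameterised by the per-locus probability *y* of second-division
  segregation;
* `expected_homozygosity()` with an independent exhaustive oracle
  `enumerate_homozygosity()` and Monte-Carlo check `mc_homozygosity()`;
* `transition_summary()` / `classify_mechanism()` / `clonal_consistency()`
  — inference from genotype tables;
* `polymorphism_report()` — marker statistics (allele counts, HO, unbiased
  HE, PIC);
* `scan_sequence()` / `scan_fasta()` — a microsatellite (SSR) scanner with
  perfect/compound/imperfect classification and a naive reference
  implementation as oracle;
* `karyotype_report()` — relative length, centromeric index and M/SM/A
  classification from chromosome arm measurements;
* seeded synthetic-data generators (`make_pedigree()`, `make_fasta()`,
  `make_karyotype_measurements()`) producing every input with known truth.

The `analysis/` directory contains numbered driver scripts that run the
stages in order (karyotype, SSR discovery, marker statistics, clonal-line
genotyping, simulation validation) and write their tables under `results/`.

## Worked example

The packaged fixture `clonal_line_genotypes.tsv` has the structure of a
clonal laboratory line: 8 heterozygous founder females and three
generations of 96, 63 and 60 daughters typed at four microsatellite loci.

```r
library(thelytools)

tab <- read_genotype_table(
  system.file("extdata", "clonal_line_genotypes.tsv", package = "thelytools")
)
summ <- do.call(rbind, lapply(gt_loci(tab), \(l) transition_summary(tab, l)))
summ
#>     locus  Nt No R n_excluded
#> 1 DWTH119 219  0 0          0
#> 2 DWTH366 219  0 0          0
#> 3 DWTH178 219  0 0          0
#> 4 DWTH340 219  0 0          0

res <- classify_mechanism(summ, alpha = 0.001)
subset(res$per_locus, locus == "DWTH119")[, c("mechanism", "r_used", "p_value", "verdict")]
#>            mechanism    r_used       p_value verdict
#> 1           apomixis 0.0000000  1.000000e+00      NS
#> 2 gamete_duplication 1.0000000 7.394976e-131     ***
#> 3      random_fusion 0.3333333  1.521942e-25     ***
#> 4     central_fusion 0.0000000  1.000000e+00      NS
#> 5    terminal_fusion 0.3333333  1.521942e-25     ***

res$overall
#> [1] "apomixis"       "central_fusion"
```

All 219 offspring of heterozygous mothers are heterozygous (*R* = 0 at
every locus), so gamete duplication, terminal fusion (tested at its nearest
endpoint *r* = 1/3) and random fusion are rejected at *p* < 0.001, while
apomixis and central fusion without recombination — the two mechanisms that
preserve heterozygosity — cannot be distinguished from marker data alone.
`clonal_consistency(tab)` reports 0 mismatching individuals (genotyping
error rate 0) across 227 × 4 calls.

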