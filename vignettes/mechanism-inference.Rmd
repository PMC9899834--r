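---
title: "Diagnosing the cytology of thelytoky from genetic markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing the cytology of thelytoky from genetic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thelytools)
```

## The problem

In haplodiploid Hymenoptera the usual reproductive mode is arrhenotoky:
haploid males from unfertilised eggs, diploid females from fertilised ones.
Some species instead reproduce by thelytoky — unfertilised eggs develop into
diploid females — and the diploidy of those daughters can be restored by
several distinct cytological routes:

* **apomixis** — meiosis is absent or mitosis-like; daughters are clones;
* **automixis** — meiosis completes and diploidy is restored by fusing two
  of its products: **central fusion** (products of opposite first-division
  poles), **terminal fusion** (sister products of one second-division
  spindle), **gamete duplication** (one haploid product doubles), or
  **random fusion** (two products fused without regard to pedigree).

The routes leave different genetic footprints. At a locus where the mother
is heterozygous `ab`, the probability `r` that a daughter is homozygous is

| mechanism          | expected `r`       |
|--------------------|--------------------|
| apomixis           | 0                  |
| central fusion     | 0 – 1/3            |
| random fusion      | 1/3                |
| terminal fusion    | 1/3 – 1            |
| gamete duplication | 1                  |

so the observed rate of transition to homozygosity `R = No / (Nt + No)`
over a brood of known parentage discriminates among them (up to the
intrinsic apomixis / central-fusion ambiguity when no recombination
separates centromere and marker). This package implements the full chain:
a chromatid-level simulator, the closed-form rates with an independent
enumeration oracle, exact tests of `R` against each `r`, marker statistics,
an SSR scanner for marker discovery, and karyotype classification.

## The meiosis model

A meiosis is modelled at the level of the four chromatid products. Loci
segregate independently (marker loci are assumed unlinked). The only free
parameter per locus is `y`, the probability of **second-division
segregation** (SDS): a crossover between centromere and locus in that
meiosis. With probability `1 - y` the two maternal alleles separate at the
first division (each pole's two sister chromatids carry the same allele);
with probability `y` both poles carry one copy of each allele and sisters
differ. Under random pairing of chromatids at most two of the four
chromatids can co-segregate in the informative way, so `y` is biologically
bounded by `2/3`; the package enforces `y ∈ [0, 2/3]` (a permissive mode
allows `y ∈ [0, 1]` for unit tests that force SDS). No published value
fixes `y` for any locus; it is exposed as a parameter and the published
range endpoints correspond to `y = 0` and `y = 2/3`.

Fusion is a cell-level event: the egg pronucleus is drawn uniformly among
the four products, terminal fusion uses its unique sister, central fusion
draws uniformly between the two opposite-pole products, and one pair of
nuclei supplies the alleles at every locus. The closed forms follow:
central fusion `y/2`, terminal fusion `1 - y`, gamete duplication 1,
apomixis 0.

**Random fusion** is implemented as a uniform draw of two distinct products
among the four final products. The phrase "fusion of two products of the
first meiotic division" admits another reading (fusion of the two
first-division nuclei), but that reading collapses onto central fusion;
only the uniform-pair reading yields the constant `r = 1/3` independent of
`y`, which is the value the field attaches to random fusion. The
`enumerate_homozygosity()` oracle — an exhaustive weighted enumeration over
segregation states, egg choices and admissible fusions, sharing no code
with the closed forms — confirms all five forms to machine precision, and
`mc_homozygosity()` confirms them stochastically.

## Inference

`transition_summary()` counts, per locus, the heterozygous (`Nt`) and
homozygous (`No`) diploid offspring of heterozygous mothers; offspring of
homozygous mothers carry no information about the transition and are
excluded with a warning. `exact_test_vs_expected()` compares the observed
split to the expected one with a two-sided Fisher exact test on
`[[No, Nt], [round(r N), N - round(r N)]]`; the expected count is rounded
half-up. How the original analysis built its 2x2 table is not stated
anywhere we could follow, so a binomial exact test of `No/N` against `p = r`
is provided as an option; the Fisher construction is the default because an
exact test of conformity between observed and expected frequencies is what
the published table reports. For the clonal data (`N = 219`, `No = 0`) the
two differ only in the tail mass, not in any verdict.

For the ranged mechanisms the test uses the endpoint of the theoretical
range closest to the observed `R` (central fusion: `R` clamped to
`[0, 1/3]`; terminal fusion: to `[1/3, 1]`), which is the conservative
convention the published table states. Verdicts use `alpha = 0.001`, so
they map onto the printed `***` / NS dichotomy; the same source also
mentions a 95% confidence level in passing, so `alpha` is exposed as a
parameter rather than hard-coded. The overall verdict is the set of
mechanisms not rejected at any locus; apomixis and central fusion at
`y = 0` are mutually unresolvable by design, and the validation asserts
them as a pair.

## Marker statistics

`polymorphism_report()` gives per-locus allele counts, observed
heterozygosity (`HO`, a diploid property — haploid males contribute one
gene copy to frequencies but are excluded from `HO`), expected
heterozygosity, and PIC. `HE` defaults to the small-sample unbiased
estimator `C/(C-1) (1 - Σ p_i²)` with `C` gene copies, the estimator the
standard marker software applies; the plain gene diversity is available
with `unbiased = FALSE`. `PIC = 1 - Σ p_i² - Σ_{i<j} 2 p_i² p_j²`. The raw
genotypes behind the published field panel are not deposited, so those
printed values serve as schema only; the statistics are validated against
closed forms and synthetic panels with known allele frequencies.

## SSR scanning

`scan_sequence()` reimplements microsatellite detection rather than
wrapping an external tool. Maximal tandem runs of 1–6 bp motifs are found
by shifted equality (`s[i] == s[i+k]` chains); a run whose motif is itself
a tandem of a shorter unit is reported at the shortest period, `N` breaks
runs, and minimum repeat counts default to 10/6/5/5/4/4 for mono- through
hexanucleotide motifs. Two runs of the same motif (up to cyclic rotation)
separated by an interruption of at most `max_interruption_bp` called bases
form one **imperfect** locus when their joint count meets the minimum;
chains of three or more interrupted runs are not treated as a single
imperfect locus. Reported loci separated by at most
`compound_max_spacer_bp` merge into a **compound** locus. The external
standard behind the published perfect/compound/imperfect counts does not
print its thresholds, so the defaults (interruption 3 bp, spacer 100 bp)
follow common practice for this class of scanner and are configurable;
the synthetic generator always plants loci consistent with whatever
configuration it is given. Motifs are reported as literal repeat units —
no canonicalisation across rotations or reverse complements — matching how
marker tables print them ("TG 12", not "AC 12"). Coordinates are 0-based
half-open throughout.

A deliberately naive `O(n k r)` scanner (`scan_sequence_naive()`) is kept
as an independent oracle; the suite asserts identity of the two on random
2-kb sequences and on every planted contig.

## Karyotype

`centromeric_index()` is `100 × short / (short + long)`;
`classify_chromosome()` uses the classical centromeric-index tradition —
metacentric at `CI ≥ 37.5`, submetacentric at `25 ≤ CI < 37.5`, acrocentric
below — with boundary values assigned to the higher class. The cited
classification guideline does not print its cut-offs; this convention
reproduces every published class label. Relative length is normalised per
cell before averaging (the printed standard deviations imply per-cell
normalisation), so `RL` means sum to 100 up to rounding and the statistic
is invariant to the measurement unit.

## Synthetic data

The generators define the study conditions the pipeline is validated under:

* `pedigree_spec()` defaults to the clonal laboratory design — 8 founder
  females of one four-locus heterozygous genotype, three generations of
  96/63/60 offspring;
* `fasta_plant_spec()` defaults to the published SSR composition — 636
  contigs with one locus each: 563 perfect (124/308/123/7/0/1 by motif
  length), 59 compound, 14 imperfect; background flanks (60 bp per side)
  are rejection-sampled against the scanner itself so the planted locus is
  the only detectable one (intentionally self-referential; the brute-force
  scanner cross-checks it);
* `make_karyotype_measurements()` jitters per-cell chromosome totals and
  centromeric indices around the published per-pair targets (15 cells,
  matching the reported larval sample).

What the generators do **not** emulate: genotyping noise and allele
dropout, linkage between markers, assembly artefacts, mutation
accumulation in clonal lineages, or real chromatin measurement error
structure. Passing tests therefore demonstrate the correctness of the
computations under the stated model, not robustness to every failure mode
of real data.

## Numerical choices and problem sizes

Expected counts are rounded half-up (ties away from zero) when building
Fisher tables; `R` is `NA`, flagged, when a locus has no eligible
offspring; degenerate pedigrees (a generation without females) raise an
explicit error. Validation uses 100 seeded replicates of 200-offspring
broods per mechanism for recovery (requiring the generating mechanism in
the NS-set in ≥ 95% of replicates) and n = 50,000 Monte-Carlo draws per
grid point against the closed forms (within 4 binomial standard errors);
these sizes give comfortable statistical resolution while keeping the
suite quick on a laptop.

## Limitations

Single-locus, single-chromosome recombination model (no chiasma
interference, no linkage); no triploidy or endosymbiont biology; no
read-level sequence simulation (contigs are generated directly); the
apomixis / central-fusion ambiguity at `y = 0` is intrinsic to marker data
and can only be broken cytologically.
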