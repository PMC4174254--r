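# unidem

Comparing maternal and paternal demographic histories from uniparental
sequence data.

The mitochondrial genome and the non-recombining portion of the Y
chromosome (NRY) are inherited through the female and male line
respectively, each as a single haploid locus without recombination.
Sequencing both in the same individuals makes it possible to ask, free
of SNP-ascertainment bias, whether female and male effective population
sizes (N_f, N_m) and between-population differentiation have differed
through human history. `unidem` implements the complete analysis path
for this comparison, for population geneticists working with
matched mtDNA/NRY (or any haploid, non-recombining) resequencing data:

* **Genotype QC** — haploid calling from PL genotype-likelihood triples
  (a call is `N` unless the favoured homozygote beats both the other
  homozygote and the impossible heterozygote by ≥30 PHRED units),
  multi-allelic site removal, majority-allele polarity.
* **Imputation** — sequential nearest-haplotype imputation that
  exploits complete linkage: complete sites seed a reference set,
  remaining sites are filled from the closest donor haplotype and join
  the reference, with a mask-and-revalidate accuracy protocol.
* **Homoplasy filter** — maximum-parsimony tree plus per-site two-state
  Fitch counts; sites with >2 changes, all on terminal branches, are
  removed as likely sequencing errors.
* **Statistics** — haplotype diversity, segregating sites, mean
  pairwise differences (mpd) with Tajima's variance, nucleotide
  diversity, Watterson's θ, Tajima's D, pairwise Φ<sub>ST</sub>,
  hierarchical AMOVA with permutation tests, mpd-ratio resampling, and
  Mantel tests against great-circle distances.
* **Simulation + ABC** — a fast structured-coalescent simulator (C++
  core) for a six-region serial-founder model with no post-divergence
  migration (times T1–T6, exponential within-branch growth), and ABC
  with rejection plus log-scale local-linear regression adjustment to
  estimate divergence times (stage 1, combined loci) and sex-specific
  effective sizes (stage 2, one locus each), validated on
  pseudo-observed datasets (R², bias, relative RMSE, coverage,
  factor-2).
* **Synthetic data** — a generator that emulates the full study design
  (511 males, 44 populations, 6 regions, realistic NRY missingness), so
  every stage is testable without any download.

## Worked example

The classic four-haplotype toy `{000, 001, 011, 111}` over a 6-bp
locus:

```r
library(unidem)
fx <- worked_fixture()
diversity_stats(fx$tajima4$matrix, L = 6)
#> # A tibble: 1 × 10
#>       n     H     S   mpd mpd_se    pi pi_se theta_s theta_s_site tajimas_d
#>   <int> <dbl> <int> <dbl>  <dbl> <dbl> <dbl>   <dbl>        <dbl>     <dbl>
#> 1     4     1     3  1.67   1.45 0.278 0.242    1.64        0.273     0.168
```

All six pairwise comparisons yield 10 differences, so mpd = 10/6; every
haplotype is unique (H = 1); θ_S = 3/(1 + 1/2 + 1/3) = 18/11; D is
mildly positive because mpd slightly exceeds θ_S.

A full synthetic study through imputation, diversity and AMOVA:

```r
study <- generate_study(study_config(), tempfile(), seed = 1)
imp <- impute_missing(study$nry_masked)
imp
#> <imputation_result> 19489 calls imputed (1 reference sites)

diversity_by(imp$matrix, study$metadata, by = "region",
             L = locus_spec("NRY")$length)
#>   group            n     H     S   mpd mpd_se        pi tajimas_d
#> 1 Africa          85 0.992   258 25.0   12.3  0.0000498    -1.76
#> 2 America         22 0.913    24  5.22   2.93 0.0000104    -0.782
#> 3 Central Asia   146 0.994   309 17.4    8.62 0.0000348    -2.24
#> 4 East Asia      162 0.996   634 29.7   14.4  0.0000592    -2.40
#> 5 Europe          79 0.973   144 19.2    9.51 0.0000383    -1.17
#> 6 Oceania         17 0.919    63 14.9    7.83 0.0000296    -0.854

amova(imp$matrix, study$metadata$population, study$metadata$region,
      n_perm = 100, seed = 2)
#> <amova_result> 3-level design
#>                           source  df    SSD    MSD  variance  percent
#>                     Among groups   5 4368.7 873.75 11.056591 49.83556
#>  Among populations within groups  38  425.5  11.20  0.006414  0.02891
#>               Within populations 467 5194.5  11.12 11.123143 50.13553
#>  statistic     value  p_value
#>     phi_st 0.4986447 0.009901
#>     phi_sc 0.0005763 0.445545
#>     phi_ct 0.4983556 0.009901
```

The negative Tajima's D values reflect the post-founding growth built
into the generating model; Φ<sub>SC</sub> ≈ 0 because synthetic
populations are labels within panmictic regions, so essentially all
among-sample variance sits between regions and within populations.

The end-to-end pipeline (QC → imputation → homoplasy filter →
statistics → optional ABC) is one call:

```r
res <- run_pipeline(list(seed = 1, run_abc = TRUE), "out/")
```

and writes TSV reports plus a JSON manifest (versions, seeds, timings)
under `out/`. A thin CLI over the same functions is in
`inst/scripts/unidem.R` (subcommands `synth`, `impute`, `stats`,
`pipeline`).

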