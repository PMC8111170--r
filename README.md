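# triohrr

Family-based candidate-gene association analysis with trio-derived
pseudo-controls, in R.

## The problem

Candidate-gene case–control studies of childhood neuropsychiatric disorders
often recruit affected children together with both biological parents.
Under the Haplotype-Relative-Risk (HRR) design, the pair of parental alleles
*not* transmitted to an affected child forms the genotype of a matched
"pseudo-control": a synthetic individual drawn from the same source
population, immune to population stratification under the null, that can be
pooled with unrelated community controls to raise power. `triohrr`
implements the full analysis pipeline around this idea for biallelic SNP
panels:

- **Genotype I/O and domain model** — PLINK text PED/MAP reading/writing,
  with dosages coded against a panel-wide minor allele; trio links inferred
  from parent-id columns.
- **SNP quality control** — minor-allele frequency, missingness, an exact
  Hardy–Weinberg equilibrium test (classic two-sided summation over
  heterozygote configurations), and the trio Mendel-error rate, all with
  strict exclusion inequalities.
- **Pseudo-control construction** — per marker,
  `pseudo = father + mother − child` on dosages, the allele-multiset
  identity for the non-transmitted pair; Mendel-inconsistent trio-markers
  become missing, never a crash.
- **Association** — allelic and dominant/recessive genotypic χ² tests
  (Pearson, no continuity correction) with cross-product odds ratios and
  Woolf 95% confidence intervals (Haldane +0.5 on zero cells),
  most-significant-model selection, multi-group homogeneity tests, and
  family-wise **max-T permutation** correction by case/control label
  swapping with genotype rows (hence LD) held fixed.
- **LD and tag SNPs** — two-locus haplotype frequencies by EM over the
  double-heterozygote phase ambiguity, r² and D′, and greedy r²-bin
  tag-SNP selection.
- **Gene-level combination** — the GATES extended-Simes procedure
  `p_gene = min_j m_e · p_(j) / m_e(j)` with the effective number of tests
  `m_e = m − Σ(λ_i − 1)·1[λ_i > 1]` taken from eigenvalues of the
  p-value correlation matrix.
- **Analytic power** — two-proportion normal approximation on allele counts
  for a per-allele odds ratio ψ acting on the control allele odds.
- **Synthetic cohorts** — a latent-Gaussian (AR1-within-block) haplotype
  simulator with a log-additive logistic disease model, supporting
  unrelated case/control sampling and affected-child-ascertained trios, so
  the whole pipeline is testable without access to individual-level data.

## Worked example

A 20-SNP SHANK2/SHANK3 panel studied in 541 clinical cases (298 ADHD, 134
ASD, 109 ADHD+ASD boys) against 488 controls (232 community controls plus
256 trio pseudo-controls) ships as per-group minor-allele frequencies in
`inst/extdata/shank_panel_maf.tsv`. Aggregated allele-count tables — and
from them the allelic odds ratios and p-values — are reconstructible from
frequencies and group sizes alone:

```r
library(triohrr)
tab <- read.delim(system.file("extdata", "shank_panel_maf.tsv",
                              package = "triohrr"))
row <- tab[tab$id == "rs7106631", ]
cases <- combine_allele_counts(
  allele_counts_from_maf(row$maf_adhd,     298),
  allele_counts_from_maf(row$maf_asd,      134),
  allele_counts_from_maf(row$maf_adhd_asd, 109))
controls <- combine_allele_counts(
  allele_counts_from_maf(row$maf_control,  232),
  allele_counts_from_maf(row$maf_pseudo,   256))
allelic_test(cases, controls, marker = "rs7106631")
#> rs7106631 allelic model: OR = 0.7202 (95% CI 0.6044-0.8581),
#>   chi2 = 13.51, p = 0.0002371
```

The odds ratio below 1 says each copy of the minor (T) allele lowers the
odds of being in the clinical sample by ~28%; the χ² p-value of 0.0002 is
the allelic association test on the 2×2 allele-count table. The analytic
power of this aggregated comparison, assuming a per-allele odds ratio of
1.5 at control MAF 0.4 and a 0.001 significance level:

```r
allelic_power(541, 488, p0 = 0.4, psi = 1.5, alpha = 0.001)
#> [1] 0.898    # ~90%
```

End-to-end synthetic runs (simulation → QC → pseudo-controls → association
→ permutation → LD → gene level) go through `run_pipeline()` with a YAML or
in-code configuration; see `?run_pipeline` and the methods vignette
(`vignettes/trio-pseudo-control-association.Rmd`). A thin command-line
front end with `simulate`, `qc`, `pseudo`, `assoc`, `perm`, `ld`, `tags`,
`gene`, `power` and `run` subcommands lives at `inst/cli/triohrr.R`.

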