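---
title: "Trio pseudo-controls and candidate-gene association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio pseudo-controls and candidate-gene association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triohrr)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, the defaults and why they are set where they are,
the numerical choices, and what the synthetic-data tests do and do not
establish about real data.

## Study design and domain model

The package targets candidate-gene studies of biallelic SNP panels in which
a clinical sample (possibly several diagnostic groups) is compared with
unrelated controls augmented by *pseudo-controls* built from affected-child
trios. A `cohort` couples a marker panel, an individual table and a dosage
matrix; dosages count copies of the panel minor allele. The minor allele is
fixed once for the whole dataset (at PED/MAP load time, from pooled allele
counts, ties resolved to the alphabetically smaller allele). Freezing the
orientation matters: per-group frequencies may then exceed 0.5, but every
odds ratio in every contrast refers to the same effect allele, so
protective effects (OR < 1) read consistently across tables.

Coordinates are 1-based GRCh37 base pairs carried as opaque metadata; the
package performs no liftover and supports only autosomal, biallelic,
unphased text PED/MAP data (binary PLINK files, VCF, multi-allelic sites
and X-chromosome dosage rules are out of scope).

## Pseudo-controls from trios

Under the Haplotype-Relative-Risk principle the two parental alleles not
transmitted to the affected child constitute a control genotype drawn from
the same source population. On minor-allele dosages the non-transmitted
pair is obtained without any phase bookkeeping:

$$g_{\text{pseudo}} = g_{\text{father}} + g_{\text{mother}} - g_{\text{child}},$$

the allele-multiset identity. We deliberately use this subtraction rather
than per-parent transmission phasing: the two formulations are
algebraically identical, but the subtraction has no ambiguous
double-heterozygote case and therefore needs no random tie-break, keeping
the construction deterministic. A trio-marker that is Mendel-inconsistent
or incompletely genotyped yields a missing pseudo-control genotype at that
marker only (the trio is not discarded wholesale); a warning totals the
masked inconsistencies. Downstream, pseudo-controls are ordinary unrelated
controls — the package does not implement matched (conditional) analyses
or the TDT.

## Quality control

Four per-marker filters, each a *strict* inequality so boundary values
pass: MAF below 5%, missing rate above 10%, exact Hardy–Weinberg p below
0.1%, trio Mendel-error rate above 5% (defaults of `qc_thresholds()`,
all configurable).

The HWE test is the classic exact formulation: conditional on the observed
allele counts, every heterozygote count of matching parity is enumerated,
and the probabilities not exceeding the observed configuration's are
summed. No mid-p variant is used, matching the convention of the standard
genetics toolchains. Probabilities are computed in log space and
normalised, so large samples are safe; a monomorphic marker returns p = 1
with a flag, since only one configuration exists.

Which sample HWE should be evaluated on is genuinely open in this design:
cases are ascertained, and pseudo-controls are synthetic genotypes on which
HWE is not meaningful. The package therefore tests community controls and
trio founders (parents) separately and fails a marker if *either* p falls
below threshold — the conservative reading. Missingness and MAF are
computed on all individuals; the Mendel rate over complete trios only,
incomplete trios leaving the denominator.

## Association tests

The allelic test is the Pearson χ² (1 df, no Yates continuity correction)
on the 2×2 minor/major allele-count table; the continuity correction is
deliberately off because the field's standard association software defaults
likewise, and corrected p-values would not match published allelic results.
The odds ratio is the cross product oriented to the minor allele with the
Woolf interval $\exp(\ln \widehat{OR} \pm 1.959964\sqrt{\sum 1/n_{ij}})$;
when a cell is zero, Haldane's +0.5 goes on every cell for the OR and CI
only (the χ² keeps the raw table). If a whole group is empty the result is
flagged undefined; if an effect category is absent from both groups there
is nothing to test, but a Haldane OR is still reported with the flag.
Genotypic models collapse genotype counts with respect to the minor allele
(dominant: carriers vs non-carriers; recessive: homozygous carriers vs the
rest) and reuse the same 2×2 machinery. "Most significant model" selection
takes the smallest p with exact ties resolved allelic > dominant >
recessive. Missing genotypes are handled complete-case per marker — the
filters bound the damage at 10%, and nothing in the published methodology
suggests imputation.

### Multiple-testing correction

Family-wise correction is max-T permutation: case/control labels are
permuted uniformly over all exchangeable units while genotype rows — and
hence the LD between markers — stay fixed; each permutation contributes the
maximum χ² over the marker set, and

$$p^{\text{adj}}_m = \frac{1 + \#\{b: \max_k T^{(b)}_k \ge T_m\}}{B + 1},$$

the add-one estimator that cannot return zero. Pseudo-controls are treated
as exchangeable with community controls under permutation; respecting trio
structure during permutation would be an alternative, but treating
pseudo-controls as genuine random controls is precisely the HRR premise,
and the unmatched analysis is what the rest of the pipeline implements. An
exhaustive mode enumerates all label assignments for small fixtures, which
is how the Monte-Carlo path is validated in the tests.

### Analytic power

Power for the allelic test uses the two-proportion normal approximation on
allele counts. A per-allele odds ratio $\psi$ acting on control allele odds
$p_0/(1-p_0)$ implies the case frequency
$p_1 = \psi p_0 / (1 - p_0 + \psi p_0)$; with allele totals $2n$ per group,

$$\text{power} = \Phi\!\left(\frac{|p_1-p_0| - z_{1-\alpha/2}\,SE_0}{SE_1}\right)
              + \Phi\!\left(\frac{-|p_1-p_0| - z_{1-\alpha/2}\,SE_0}{SE_1}\right),$$

with $SE_0$ the pooled null standard error and $SE_1$ the
alternative-hypothesis standard error of the frequency difference. Both
rejection tails are summed — the far tail is numerically zero for any
realistic design, but its inclusion makes the null case $\psi = 1$ return
exactly $\alpha$, which is the correct size of the two-sided test.

## Linkage disequilibrium and tag SNPs

Two-locus haplotype frequencies come from an EM algorithm over the
double-heterozygote phase ambiguity: all other genotype pairs resolve to
haplotype counts directly, and the expected split of double heterozygotes
between coupling and repulsion phases is iterated from a linkage-
equilibrium start until the largest frequency change drops below 1e-10 (or
1,000 iterations). The log-likelihood trace is exposed and asserted
non-decreasing in the tests. From frequencies, $D = f_{mm} - p_A p_B$,
$r^2 = D^2 / (p_A q_A p_B q_B)$ and $D' = |D|/D_{\max}$. We compute r² from
EM haplotype frequencies rather than as the composite correlation of
dosages, matching the convention of the standard LD-visualization tools;
monomorphic markers get r² = 0 with a flag. LD defaults to the control
sample, because case LD is distorted at associated markers.

Tag selection is greedy r²-binning: repeatedly take the unassigned marker
with the most unassigned neighbours above the threshold (strictly above
0.8 by default), bin it with those neighbours and make it the tag. The
underlying cluster principle does not fix a tie-break; we resolve ties by
smallest base-pair position so the output is a pure function of the input
matrix.

## Gene-level combination (GATES)

Per-SNP p-values within a gene are combined by the extended Simes
procedure. With p-values sorted ascending,

$$p_{\text{gene}} = \min_j \frac{m_e \, p_{(j)}}{m_e(j)},$$

where $m_e = m - \sum_i (\lambda_i - 1)\,1[\lambda_i > 1]$ is the effective
number of tests from the eigenvalues of the p-value correlation matrix and
$m_e(j)$ the same functional on the top-$j$ submatrix. The p-value
correlation is obtained from the genotype correlation through the
sixth-order polynomial published with the GATES method (Li, Gui, Kwan &
Sham 2011, *Am J Hum Genet* 88:283–293), recorded in one constant table in
the source. Two numerical choices: the polynomial evaluates to 0.9814 at
r = 1, so $|r| = 1$ is mapped to exactly 1 (p-values of two-sided tests on
duplicated — or coding-flipped — genotypes coincide exactly, and this
preserves the $m_e = 1 \Rightarrow p_{\text{gene}} = \min p$ limit); and
eigenvalues are floored at zero before the $m_e$ formula, because the
polynomial-mapped matrix can fall microscopically outside the PSD cone.
Genotype correlations are estimated on the control sample, consistent with
the LD module. Gene-level validation is property-based (limiting cases and
null calibration) rather than number-matching, since published gene-level
p-values are functions of the original genotypes.

## The synthetic-cohort generator

Haplotypes are drawn from a latent-Gaussian threshold model: within each
LD block the latent variables follow an AR(1) process with correlation
`within_block_rho`, blocks are independent, and a marker carries its minor
allele when the latent variable falls below `qnorm(maf)`. A copula of this
kind was chosen over coalescent simulation deliberately: it gives direct,
independent control of the two properties the pipeline actually consumes —
marginal allele frequencies and a banded r² structure — which is what the
EM-LD, tag-binning and GATES correlation handling need exercised. It does
not emulate recombination hotspots, allele-frequency/LD coupling, rare
variation, population structure or genotyping error, so passing tests
certify the statistical machinery, not robustness to those features of real
data. Note also that the binary r² implied by a latent correlation is
substantially below it (at MAF 0.5, $r_{\text{binary}} = \tfrac{2}{\pi}
\arcsin \rho$, so $\rho = 0.99$ yields r² ≈ 0.83); the tests check the
simulator against this threshold-model integral, not against $\rho^2$.

The disease model is logistic and log-additive across markers,
$\mathrm{logit}\,P(\text{affected}) = \mathrm{logit}(\pi_0) + \sum_m g_m
\ln \psi_m$, with baseline prevalence $\pi_0 = 0.05$ by default: low enough
that odds ratios approximate relative risks (the regime in which
"protective effect of ~28%" phrasing is meaningful), high enough that
rejection sampling of ascertained families stays cheap. Case/control
sampling rejects until the requested counts are met; trio simulation draws
parents from the pool, transmits one uniformly chosen haplotype from each,
and (optionally) resamples whole families until the child is affected —
which is what induces transmission distortion at associated markers, the
signal the HRR design exploits. Every stochastic operation takes an
explicit seed; one seed, one byte-identical dataset. The default panel
(`default_study_panel()`) mirrors the study scale the package is built
around: 13 + 7 SNPs in two blocks with MAFs between 0.25 and 0.52, and the
emulated cohort structure is 256 affected-child trios, clinical groups of
298/134/109, and 232 community controls.

## Pipeline orchestration

`run_pipeline()` executes load (files or simulation) → QC → pseudo-control
construction (trio parents then leave the analysis set) → per-contrast
allelic tests → genotypic models and best-model selection for SNPs
nominally significant (p < 0.05, configurable) on the *primary* contrast →
max-T permutation on the primary contrast → LD matrix → GATES per gene and
contrast. The primary contrast — by default the first declared, intended as
"all clinical vs all control" — drives permutation and model selection,
mirroring the aggregate-first analysis order. The configuration seed is set
once at the start; stage failures abort with a stage-named error and
partial output files are removed. Logs record per-stage record counts so
QC-to-analysis attrition is auditable.

## Test design and problem sizes

All expected values in the test suite are either hand-verifiable
arithmetic, outputs of independent oracles (brute-force enumeration of HWE
configurations and of label permutations, numeric integration of the
threshold model, true-phase haplotype counts), or published summary values
reconstructible from the shipped frequency table. Simulation-based checks
use sizes chosen to make the assertions sharp at reasonable cost: 2,000
replicates for calibration checks (binomial-SE bands), 20,000 trios for
frequency-matching properties (3-SE tolerances), 100 seeds for per-allele
OR recovery at 5,000+5,000 individuals, and 25 replicate pipeline runs at
the emulated study scale for the end-to-end null-calibration and
planted-effect checks. The gene-level null calibration uses 500 cases and
500 controls per replicate: at a few hundred individuals the per-SNP χ²
inputs are themselves measurably miscalibrated, which would confound a
check aimed at the combination procedure.

## Known limitations

- Only autosomal biallelic markers in text PED/MAP; no covariate
  adjustment, trend tests or exact (Fisher) association tests.
- Pseudo-controls are unmatched downstream; the matched conditional
  analysis that the trio design would also support is out of scope.
- The GATES genotype→p-value correlation polynomial is an approximation
  fitted for two-sided single-SNP tests; gene-level p-values inherit its
  error, and published gene-level numbers cannot be checked without the
  original genotypes.
- The simulator's LD is stationary within blocks and zero between them;
  real panels have irregular LD, and tag-binning behaviour on such panels
  is only exercised synthetically.
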