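---
title: "Selection versus drift in a two-species nested design: the methods behind qstfstkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection versus drift in a two-species nested design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstfstkit)
options(qstfstkit.verbose = FALSE)
```

## The scientific question

When a highly self-pollinating plant species diverges from its
mixed-mating sister species in flower size, nectar, pollen production and
herkogamy — the "selfing syndrome" — the divergence can be the product of
natural selection or simply of genetic drift in small, inbred
populations. `qstfstkit` implements the comparison that distinguishes the
two: quantitative-trait differentiation (Qst) measured in a common-garden
nested design is compared against neutral-marker differentiation (Fst)
from SNP genotypes. Under drift, Qst and Fst share the same expectation;
selection pushes the divergence of the selected trait above (or below)
the neutral envelope. The package covers the univariate comparison per
trait, a multivariate comparison of whole trait covariance matrices, and
a synthetic-data generator that reproduces the statistical structure of
the greenhouse-plus-RNA-seq design so that every stage can be validated
against a known truth.

The design the package expects is nested: two species, a set of wild
collection sites per species, up to a few maternal families
("accessions") per site, and a small number of selfed offspring per
accession grown and phenotyped in a common environment; one selfed
offspring per accession is genotyped at thousands of biallelic SNPs. The
accession is the replicated genetic unit throughout — it is what links
the phenotype table to the genotype matrix, and it is the unit that every
bootstrap resamples.

## Fst estimation

Two multi-locus estimators are provided, both ratio-of-averages so that
loci with little information do not dominate:

* **Weir–Cockerham**: per-locus variance components $a$ (among species),
  $b$ (among individuals within species) and $c$ (within individuals)
  from the 1984 two-level decomposition, combined as
  $\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)$. The components
  use observed per-species sample sizes and heterozygote counts, so
  missing genotypes simply reduce the per-locus $n$; the estimator
  accommodates arbitrary within-species inbreeding through the $c$
  component, which matters here because both species are partly or
  highly selfing.
* **Hudson**: $\sum_l N_l / \sum_l D_l$ with
  $N_l = (p_1-p_2)^2 - p_1(1-p_1)/(m_1-1) - p_2(1-p_2)/(m_2-1)$ and
  $D_l = p_1(1-p_2) + p_2(1-p_1)$, $m_j$ the number of called allele
  copies. It serves as a cross-check; the two estimators agree closely on
  all simulated data we generate.

Loci with more than one missing call (configurable through
`max_missing_calls`) are excluded before estimation, mirroring the hard
call-rate filter that upstream SNP calling pipelines apply. Negative
multi-locus estimates are reported as computed; clamping is left to
presentation.

Two **ascertainment rules** are exposed because Fst depends on which SNPs
enter: `"all"` keeps loci polymorphic in at least one species (biased
upward by variants fixed since divergence), `"shared"` keeps loci
polymorphic in both (biased downward by excluding fixed ancestral
variants). The shared set is a subset of the all set by construction, and
on simulations containing species-private fixed variants the all-SNP
estimate is the larger of the two, as expected.

Confidence intervals are percentile bootstrap over loci (default 1,000
replicates), because multi-locus Fst uncertainty is locus-driven; the
resampling unit is never the individual here. The CI algorithm behind the
published intervals is not recoverable from the text of typical reports,
so bootstrap-over-loci — the convention of the hierfstat ecosystem — is
the package's documented choice.

## Qst estimation

Trait divergence is screened with a three-level nested ANOVA (species /
site-in-species / accession-in-site / residual) on per-individual means,
with species tested against the site-in-species stratum (or the accession
stratum when sites provide no degrees of freedom). p values across the
trait family receive a Benjamini–Hochberg correction in one call.
Relative divergence, $|m_1-m_2|/\max(m_1,m_2)$, is reported as a
unit-free descriptive measure.

For Qst itself sites are ignored — the designs this package targets have
too few accessions per site to resolve within-species structure — and a
two-level ANOVA (species / accession / residual) yields method-of-moments
variance components via the Sokal–Rohlf unbalanced-design coefficients:

$$\mathrm{E[MS_W]} = \sigma^2_e,\quad
\mathrm{E[MS_A]} = \sigma^2_e + k_\mathrm{rep}\,\sigma^2_\mathrm{BetwAcc},\quad
\mathrm{E[MS_B]} = \sigma^2_e + k_\mathrm{rep,b}\,\sigma^2_\mathrm{BetwAcc}
 + k_\mathrm{acc}\,\sigma^2_\mathrm{BetwSp}.$$

Method of moments replaces the REML fits used by point-and-click
statistical suites: it is closed-form, dependency-free, coincides with
REML in balanced designs (which these nearly are — two replicates per
accession), and makes the parametric bootstrap below transparent, since
the same expected-mean-square algebra drives both. Negative moment
estimates are clamped to zero with the raw value retained.

The reported statistic is the conservative variant

$$Q_{st}^{*} = \frac{\sigma^2_\mathrm{BetwSp}}
{\sigma^2_\mathrm{BetwSp} + 2\,\sigma^2_\mathrm{BetwAcc}}.$$

Because offspring are selfed, the between-accession component estimates
the total genetic variance $V_G$ (in the highly selfing species) or
something between $V_A$ and $V_G$ (in the mixed mater). Since
$\sigma^2_\mathrm{BetwAcc} \ge V_A$, $Q_{st}^{*}$ underestimates the true
$Q_{st}$ and the selection test errs on the side of caution.

Phenotype derivations used upstream of the ANOVA are implemented exactly
as the field measures them: capillary nectar volume $V = 2\mu l \cdot
h/32$mm, the quadratic sucrose calibration
$\mathrm{mg/ml} = 0.0524 w^2 + 9.6554 w + 1.3904$ applied to
refractometer w/w readings with a $(\mathrm{nectar}+2.5)/\mathrm{nectar}$
dilution correction (the undiluted and corrected readings are averaged),
pollen per ovule as aliquot count $\times 5/4$, and per-individual means
over repeated flowers with the early-growth summary
`internode_sum` added for multivariate work. Pollen per ovule is
log-transformed before ANOVA by default; all other traits enter
untransformed, and the transform set is a per-trait configuration.

## The univariate Qst–Fst tests

**Standard bootstrap.** Accessions are resampled with replacement within
each species; one draw drives both tables — the phenotype rows of the
chosen accessions (repeats kept as distinct pseudo-accessions) and the
genotyped offspring of those accessions (entering Fst with their draw
multiplicity). $Q_{st}^{*}$, Fst, and $D = Q_{st}^{*} - F_{st}$ are
recomputed per replicate and $p$ is the proportion of $D \le 0$. When
phenotyped and genotyped accession sets do not overlap exactly (the
designs allow a few phenotyped-only accessions), the joint draw uses the
union of identifiers; a flag switches to independent per-table resampling
for datasets with entirely disjoint identifiers. Resamples that collapse
a species below two distinct accessions are redrawn and logged. By
default the raw proportion is reported (a zero is printed as the
`1/n_boot` floor only when `p_floor = TRUE`).

**Parametric bootstrap.** The neutral distribution of $D$ is simulated
from the drift expectation
$\sigma^2_\mathrm{BetwSp} \approx 2\bar F_{st} V_A/(1-\bar F_{st})$: each
iteration resamples Fst by bootstrapping loci, sets the neutral
between-species variance from that draw, and generates the three nested
mean squares from chi-square distributions scaled by their expectations
($\chi^2_1$ at the species stratum — the single degree of freedom that
dominates the test's low power with two groups — and the observed
degrees of freedom elsewhere), then reassembles a simulated
$Q_{st}^{*}$. $V_A$ is taken as the observed between-accession component
divided by the dam-offspring relatedness, 1 for selfed offspring, so
$V_A$ is really $V_G$ and the simulated neutral divergence is, if
anything, too large — again conservative. $p$ is the proportion of
neutral $D$ values at or above the observed $D$.

On drift-null simulations the standard bootstrap rejects at roughly the
nominal rate and the parametric bootstrap rejects less often —
reproducing the qualitative pattern that parametric p values are larger
in two-group comparisons.

## The multivariate proportionality test

Under neutral divergence the between-species G-matrix is, on average,
proportional to the within-species G-matrix, with coefficient
$\rho_\mathrm{Exp} = m\,F_{st}(1-F_{st})$ ($m = 1$ for a highly selfing
species, $m = 2$ for an outcrosser; the selfing multiplier is the default
here and the outcrossing one is exposed — on our simulations, as in the
motivating study, the choice does not change verdicts). The observed
coefficient is estimated from a MANOVA on accession means, transformed
toward normality and mean-standardized per trait: $G_A$ is the residual
SSCP divided by its degrees of freedom, $\mathrm{MS_B}$ the
between-species SSCP on 1 df, and $G_S = (\mathrm{MS_B} - G_A)/n_0$ with
the unbalanced two-group coefficient $n_0 = 2n_1 n_2/(n_1+n_2)$.

Matrices are conditioned before any inversion: averaged with their
transpose, rounded to 12 decimal places (so symmetry lost to
floating-point cancellation becomes exact), and eigenvalues below
$10^{-10}\lambda_{max}$ lifted to that floor. The conditioning is
idempotent up to the rounding precision.

$\hat\rho$ maximizes the Wishart log-density of the between-species SSCP
with scale $G_A(1 + n_0\rho)$ — a one-dimensional profile likelihood
solved by bracketed search (relative tolerance $10^{-8}$). On exactly
proportional matrix pairs this recovers the constant to $10^{-6}$, which
is the correctness anchor for the whole module; with $p = 1$ it reduces
to the scalar ratio $g_s/g_a$.

The two-species comparison leaves one degree of freedom at the species
level, so no analytic CI for $\hat\rho$ exists. Instead accessions are
resampled within species (1,000 replicates by default) and the percentile
interval of the resampled $\hat\rho$ is compared with the interval for
$\rho_\mathrm{Exp}$ obtained by mapping the Fst CI endpoints through
$m\,F(1-F)$; the verdict is "nonneutral" only when the two intervals are
strictly disjoint.

**A known limitation, quantified.** The accession bootstrap cannot
resample the species-level draw itself — the one degree of freedom is
simply not replicated — so the interval understates the drift variance
of $\hat\rho$, and $\rho_\mathrm{Exp}$'s interval is very narrow. On
fully neutral simulations at the package's default study dimensions (9
traits, 31 + 33 accessions) the disjoint-interval rule calls
"nonneutral" in roughly a quarter to a third of null datasets, while
power against a true $\rho = 2$ versus
$\rho_\mathrm{Exp} \approx 0.25$ is essentially complete. A verdict of
selection from this test alone is therefore weaker evidence than its
95% label suggests and should be read together with the univariate
results, exactly as the two-species design forces in any case.

## The synthetic-data generator

The generator exists so that every stage is testable offline with a known
truth; its defaults are the study conditions of the motivating system,
not free parameters.

* **Genotypes** follow the Balding–Nichols model: ancestral frequency
  $p \sim \mathrm{Beta}(0.8, 0.8)$ (a mildly U-shaped frequency
  spectrum), species frequency
  $p_s \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},(1-p)\tfrac{1-F}{F}\big)$
  with $F$ the target Fst (0.44 by default), and genotypes drawn with
  heterozygote probability $2p_s(1-p_s)(1-f_{is})$. The inbreeding
  defaults $f_{is} = (0.95, 0.67)$ are the selfing-equilibrium values
  $s/(2-s)$ for selfing rates 0.95 and 0.5 advanced by one further
  generation of selfing, since the genotyped individuals are selfed
  offspring of wild plants. Loci monomorphic in both sampled species are
  redrawn, so every simulated locus passes the "all" ascertainment
  filter. Balding–Nichols is chosen because it makes Fst a direct input;
  no linkage disequilibrium or coalescent structure is simulated (the
  analyses treat loci exchangeably, and LD pruning is documented not to
  move these estimators on data of this type).
* **Phenotypes** are species mean + site effect + accession effect +
  residual, with accession effects optionally correlated across traits
  through a covariance matrix. The implied truth
  $Q_{st}^{*} = s^2_{sp}/(s^2_{sp} + 2\sigma^2_\mathrm{acc})$ with
  $s^2_{sp} = (m_1-m_2)^2/2$ is closed-form, which is what the recovery
  tests exploit. Site effects default to zero (the motivating design
  could not resolve within-species site structure; a variance knob
  exists). Herkogamy is simulated on its latent normal scale by default —
  rounding to the 0–5 integer score is available for realism but breaks
  exact variance-component recovery, so recovery tests leave it off.
* The **paper-like fixture** reproduces the study dimensions: 12 + 13
  sites, 31 + 33 accessions capped at three per site, two phenotyped
  selfed offspring per accession, one genotyped offspring for all but
  three accessions (61 genotyped), an 11% never-flowered rate (putting
  the flowering count near 114), 0.3% genotype missingness against the
  at-most-one-missing call-rate filter, and a trait panel whose species
  means match the published trait table with between-accession variances
  back-solved so the true Qst* spectrum spans roughly 0.35–0.9. Residual
  variance is set equal to the between-accession variance, a regime
  consistent with two-replicate designs where roughly half the
  within-species variance is genetic.

What the generator does **not** emulate: pleiotropy between genotyped
loci and traits (traits and SNPs are independent, so Qst–Fst coupling
enters only through the resampling machinery), LD, selection within
species, measurement error structure beyond i.i.d. residuals, and
non-Gaussian trait distributions. Passing tests therefore demonstrate
that the estimators and tests are correct and calibrated under the
stated model, not that the model captures every feature of real
greenhouse data.

## Numerical and design choices

* Variance components use raw (possibly negative) moment estimates
  internally and clamp only for reporting and for Qst*, keeping the
  chain unbiased.
* The drift-null simulations used in calibration tests scale the neutral
  between-species variance from $V_A = \sigma^2_\mathrm{BetwAcc}/2$,
  because the variance among selfed families approximates $V_G \approx
  2V_A$ for an additively controlled trait; using $V_G$ itself would
  overstate neutral divergence and masquerade as anti-conservatism of
  the test.
* Problem sizes in the shipped test-suite are desk-scale choices — a few
  hundred loci and 16–33 accessions per species for calibration loops,
  5,000 loci for Fst recovery, 100-seed null suites at 200 bootstrap
  replicates — selected so the whole suite documents calibration in
  minutes while the full pipeline defaults (1,000 replicates, 5,000+
  loci) remain the analysis-scale settings.
* Seeds: every randomized routine takes an explicit seed and restores the
  caller's RNG state, so pipelines are pure functions of (data, config,
  seed); rerunning a pipeline with the same seed reproduces every report
  byte for byte.
* Degenerate inputs are signalled, not silently patched: all-monomorphic
  genotype panels, a species with fewer than two accessions, a
  non-positive estimated $V_A$, and matrices that are not positive
  definite after conditioning all raise classed errors.

## Interfaces

The R functions are the interface: `simulate_dataset()`,
`ascertain_snps()`, `weir_cockerham_fst()` / `hudson_fst()` /
`fst_bootstrap_ci()`, `divergence_table()`, `qst_components()` /
`qst_star()`, `standard_bootstrap_test()` / `parametric_bootstrap_test()`
/ `run_trait_family()`, `accession_trait_matrix()` /
`estimate_g_matrices()` / `estimate_rho()` / `rho_bootstrap_ci()` /
`expected_rho()` / `multivariate_test()`, and `run_pipeline()` /
`report()` for the end-to-end run driven by a YAML configuration (two
ready-made configurations ship in `inst/extdata/`). Results are written
as TSV tables plus a JSON summary and manifest, so each stage can be
rerun from the intermediates of the previous one.
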