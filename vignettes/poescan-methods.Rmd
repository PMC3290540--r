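---
title: "Mapping parent-of-origin effects on litter traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping parent-of-origin effects on litter traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poescan)
```

# The scientific problem

Genomically imprinted genes are expressed from only one parental copy.
On the phenotype they surface as a contrast between the two reciprocal
heterozygote classes of a marker: writing the maternal allele first, a
`BA` individual (maternal B) and an `AB` individual (paternal B) carry
the same alleles but can differ in trait mean when the locus is
imprinted or linked to an imprinted QTL. Detecting such effects on sow
reproduction traits (total piglets born, born alive, litter weights)
requires three ingredients this package provides: (i) knowing the
parental origin of marker alleles, inferred from pedigree and family
genotypes; (ii) a mixed model that separates the imprinting contrast
from additive and dominance effects and from polygenic, permanent
environment and maternal sources of covariance between repeated litter
records; and (iii) multiplicity control over hundreds of markers.

# The model

For one population and one trait the repeatability animal model is

$$ y = Xb + Qq + Za + Z\,pe + Mv + e $$

* $y$: litter records of genotyped sows, parities 1–4;
* $Xb$: class effects of breed of the litter, parity of the sow, and the
  farm–year–season combination (treatment-coded, full rank);
* $Za$: additive polygenic effects over all pedigree individuals, with
  $\mathrm{var}(a) = A\sigma^2_a$ and $A$ the pedigree additive
  relationship matrix;
* $Z\,pe$: i.i.d. sow permanent-environment effects
  ($I\sigma^2_{pe}$) shared by a sow's repeated litters;
* $Mv$: i.i.d. maternal effects of the sows' dams ($I\sigma^2_m$);
  sows with unknown dam get a zero row in $M$. The maternal term guards
  against confounding between maternal and imprinting effects;
* $e$: i.i.d. residual ($I\sigma^2_e$).

The marker term uses the ordered genotype classes. With $G$ the
$n \times 4$ indicator of (AA, BA, AB, BB) and the contrast matrix

$$ S = \begin{pmatrix} 1&0&0\\ 0&1&1\\ 0&1&-1\\ -1&0&0 \end{pmatrix}, $$

$Q = GS$ has columns for the additive, dominance and imprinting effects:
$\beta_a$ is half the AA−BB difference, $\beta_d$ the heterozygote
deviation, and $\beta_i$ half the BA−AB difference, so $\beta_i > 0$
means the *maternal* B allele raises the trait. Any rescaling of $S$
would rescale the $\beta$'s without changing F-statistics or p-values;
this scaling is fixed by the convention that class means satisfy
$\bar y_{BA} - \bar y_{AB} = 2\beta_i$.

## Two-stage testing

Variance components are estimated once per trait by REML on the
no-marker model. Each marker is then fitted by generalized least squares
with $V = ZAZ'\sigma^2_a + ZZ'\sigma^2_{pe} + MM'\sigma^2_m +
I\sigma^2_e$ **fixed** at those estimates, and tested with incremental
F-ratios in Fisher order — additive first, dominance given additive,
imprinting given both — each on one numerator degree of freedom.
Records whose sow has a missing or unresolved-heterozygote genotype are
excluded for that marker only; markers with fewer than two ordered
classes among usable records are skipped with a reason.

**Denominator degrees of freedom.** We use the residual df,
$n_\text{used} - \mathrm{rank}[X|Q]$. A Kenward–Roger or Satterthwaite
adjustment corrects for *estimated* variance components; at the scan
stage the components are deliberately fixed, the correction machinery
has no variance-of-variance information to work with, and at several
hundred records the numerical difference is immaterial. No alternative
df method is offered for that reason.

**Variance explained.** Following the sequential (Fisher) attribution,
effect $k$ explains $100\,\hat b_k^2\,\mathrm{var}(\tilde q_k) /
\hat\sigma^2_p$ percent of phenotypic variance, where $\tilde q_k$ is
the $k$-th contrast column residualized on $X$ and the preceding
columns, $\hat b_k$ is the *stage* coefficient of that column, and
$\hat\sigma^2_p$ is the variance-component total from the no-marker
model. With stage coefficients the per-effect shares never exceed the
marker block's joint contribution (they sum to it exactly in the
ordinary-least-squares limit); for the imprinting effect — last in the
order — the stage and full-model coefficients coincide. Reported
estimates and standard errors are always full-model.

# REML: algorithm and numerical choices

The restricted likelihood is evaluated through the sparse mixed-model
equations. Parameterizing by variance ratios $\gamma_k =
\sigma^2_k/\sigma^2_e$ profiles out $\sigma^2_e$, leaving a 3-parameter
(or fewer) problem:

$$ -2\ell_R(\gamma) = (n-p)\left(\log 2\pi + 1 + \log\hat\sigma^2_e\right)
   + \log|C_\gamma| + \textstyle\sum_k q_k \log\gamma_k + \log|A| $$

with $C_\gamma$ the coefficient matrix of the mixed-model equations,
$A^{-1}$ built directly from the pedigree by Henderson's rules
(inbreeding included through the Mendelian sampling variances, which
also give $\log|A|$ as a by-product), and a single sparse Cholesky
factorization — whose symbolic pattern is computed once and reused —
per evaluation. The test suite verifies this expression against a dense
textbook computation of
$\log|V| + \log|X'V^{-1}X| + y'Py$ to $10^{-8}$.

The profiled deviance is maximized by quasi-Newton (L-BFGS-B) iterations
on $\log\gamma$, with convergence at a $10^{-8}$ change in the
restricted log-likelihood. Components whose ratio collapses toward the
lower bound are pinned to zero and the model is refitted without them —
mirroring the boundary estimates (printed as 0.00 with SE 0.00) that
occur in practice. Standard errors come from the inverse
average-information matrix evaluated at the optimum; each AI entry
$\tfrac12 w_i' P w_j$ needs only one extra mixed-model solve per
component, and pinned components get SE 0. The heritability is
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_m +
\sigma^2_e)$ — the full phenotypic denominator — with a delta-method SE.

Degenerate designs are detected rather than silently mis-estimated: with
one record per sow the permanent-environment component is
indistinguishable from the residual (and, if the pedigree carries no
parentage, so is the additive one); the affected terms are pinned and
the fit records which sums are identified. A constant response returns
all-zero components.

**Boundary bias.** Constrained REML is positively biased for a component
whose true value sits within a fraction of a sampling SD of zero: the
estimator behaves like a truncated normal. At the default study scale
(~500 sows) the maternal variance of litter-size traits (≈0.06 on the
count scale, sampling SD ≈ 0.19) is exactly in that regime, so
replicated recovery studies show a positive mean bias of ≈ +0.09 for
$\sigma^2_m$, partially compensated in $\sigma^2_a$ — while the same
design with a well-identified maternal variance (0.8) recovers all four
components without bias. This is a property of the estimator under
these conditions, not of the implementation.

# Genotype processing

**Mendelian screening.** Trio/duo rules flag impossible offspring
genotypes (opposite homozygotes between child and a parent; a
heterozygous child of two identical homozygotes). Only the offspring
genotype is flagged, and flagged entries are set to missing — the
conservative stand-in for constraint-based error correction over the
whole pedigree, which identifies *critical* genotypes rather than
correcting them.

**Parental origin.** Homozygotes order trivially. For heterozygotes,
rule R1 uses a homozygous parent to force the transmitted allele and
rule R2 completes the other allele's origin. A bounded-window
propagation step then handles the remaining heterozygotes whose
heterozygous parent has known phase: the transmitted parental strand is
borrowed from the nearest family-rule-resolved marker within a window of
at most six consecutive markers, assuming no recombination inside the
window; strand evidence on both sides must agree. Indicators are taken
*only* from family-rule assignments — propagated calls never seed
further propagation — so a wrong call requires a real crossover between
indicator and target, bounding the error rate by the within-window
recombination probability (verified on gene-dropped data with elevated
recombination). Everything still unresolved is labelled
unordered-heterozygote and excluded per marker from association. The
maternal-first notation is used throughout; no origin probabilities are
fabricated for unresolved cases.

**Marker QC.** Minor-allele frequency by allele counting; one-df
Hardy–Weinberg goodness-of-fit $\chi^2$ with collapsed heterozygote
classes, plus the empirical percentile of a marker's statistic among all
markers (the "is this marker's HWE deviation unusual?" check); LD as
haplotype-based $r^2 = D^2/(p_A p_a p_B p_b)$ from the resolved gametic
phases, with pairs below 30 informative haplotypes reported missing
(an invented but configurable information floor).

# Record filters

Applied in a fixed order: (1) parities 1–4 only; (2) litters with zero
total born or zero born alive lose all four trait values; (3) per trait,
values deviating more than 3 SD from the population mean are blanked
individually (other traits of the litter are kept — blanking single
values rather than whole records is our resolution of an ambiguity, as
is computing the mean/SD once on the records entering the outlier step).
A zero or undefined SD removes nothing. The outlier bounds are stored
with the filtered records and reused on re-application, which makes the
filter chain idempotent by construction — recomputing bounds on
already-filtered data would otherwise let the 3-SD rule cascade.

# Multiple testing

Storey–Tibshirani q-values with
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on
$\lambda \in \{0, 0.05, \ldots, 0.90\}$, smoothed by a cubic smoothing
spline with 3 df and read off at the largest $\lambda$ (clipped to
$(0,1]$); below 20 p-values a fixed $\lambda = 0.5$ is used. Then
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$, which reduces to
Benjamini–Hochberg at $\hat\pi_0 = 1$ (an oracle check in the tests).
q-values are computed separately per population × trait × effect
stratum — a scan object is one population × trait, so stratification is
by effect — and `q <= 0.05` is the significance rule.

# The simulator

The generator's defaults emulate the first of two Large-White-type
commercial dam lines: ~700 genotyped sows in paternal half-sib families
(25 sires per generation), four pedigree generations with earlier female
layers scaled by 0.4, repeated records for parities 1–4 drawn with
probabilities (0.25, 0.30, 0.30, 0.15) (mean 2.35 parities), total-born
mean 14.05 (SD 2.91), variance components (0.76, 0.62, 0.11, 6.41) for
total born, six litter breeds and roughly one farm–year–season level per
nine records (≈135 at full scale). The marker panel follows the
fifteen-candidate-region layout (13–32 SNPs per region, region-specific
MAF quartile bands); region spans cover the observed 0.55–4 Mb range.
One imprinted QTL sits mid-region 7_1 with effects (−0.23, −0.17, +0.58)
on the total-born scale — about 1.4% of phenotypic variance given the
reported ordered-class frequencies (18/107/61/316)/502, squarely in the
1–2% band of the motivating result.

Founder haplotypes come from a latent-Gaussian block model: within LD
blocks of 5–8 consecutive markers the latent variables follow an AR(1)
with correlation 0.9, thresholded at each marker's target MAF; blocks
are independent. This echoes the strong 6–7-marker LD blocks seen in
real candidate-region data while keeping MAF control exact. Gene drop
transmits recombinant gametes with per-interval crossover probability
proportional to physical distance (0.01/Mb), recording the true origin
of every allele. Phenotypes add pedigree-recursive breeding values
(Mendelian sampling variances honour inbreeding), i.i.d. permanent
environment, maternal and residual effects, the fixed effects, and the
QTL term — always on the latent continuous scale; count traits are then
rounded to integers. That Gaussian-then-round approximation adds
Uniform(−½, ½) noise, i.e. 1/12 to the effective residual variance of
count traits, which the recovery studies account for. Companion traits
(born alive from total born via a 6.5% loss rate; weights at 1.4 kg per
piglet) complete the files but only the focal trait carries the exact
variance structure.

All randomness derives from one master seed; stage-level sub-seeds are
drawn through the RNG itself so that nearby master seeds never share a
stream between stages or replicates. Written datasets (pedigree CSV,
phased VCF with `maternal|paternal` GT convention documented in the
header, map TSV, phenotype TSV, truth TSV) are byte-stable for a fixed
seed.

**What the simulator does not emulate.** Founder haplotypes are not
coalescent-realistic (no allele-frequency spectrum, no LD decay beyond
the block structure); selection over generations, genotyping error,
non-random missingness, and cross-trait genetic correlations are absent;
count traits are rounded Gaussians, not true overdispersed counts.
Passing tests therefore demonstrate correctness of the estimation and
testing machinery under the stated model, not robustness to the
model violations real data may carry.

# Power machinery

`simulate_qtl_study()` plants a marker with chosen additive/dominance/
imprinting effects on i.i.d. ordered-class draws over a half-sib
pedigree, and `power_study()` reports the fraction of replicates with
imprinting p < α at the planted marker, with Monte-Carlo SE; at zero
effect this is the empirical size. Variance components can be
re-estimated per replicate (`fix_vc = "reml"`, the full pipeline) or
fixed at the simulation truth (`"truth"`, much faster; the scan
conditions on fixed components either way). Under the full
repeated-records design the imprinting test is efficient: a QTL at 1% of
phenotypic variance is detected essentially always at n = 1000 sows.
Power claims from designs with other record structures are not
comparable — which is why the package's own checks are the size of the
test at zero effect and monotonicity of power in effect size and cohort
size, both verified in the acceptance suite.

# Problem sizes and runtime

The shipped tests run the replicated studies at reduced but
study-faithful sizes: variance-component recovery at 500 sows × 60
replicates, imprinting-effect recovery at 502 sows × 30 replicates,
size/FDR checks at 150–200 sows with 100–150 replicates, and the
exhaustive pedigree-oracle comparisons over all 4-individual pedigrees
plus random pedigrees to 8 individuals. A C1-scale REML fit (≈1200
records, ≈900 pedigree individuals, ≈140 fixed-effect columns) takes
about two seconds; a full 305-marker scan adds a few seconds per trait.
Dense relationship matrices are only formed where needed (oracles,
breeding-value simulation); the model machinery is sparse throughout.

# Known limitations

* Single-trait analyses only; no multi-trait REML, no genomic
  relationship matrices, no haplotype-based random-effect association.
* The origin-assignment rules are deterministic; likelihood-based
  phasing would resolve more heterozygotes at the cost of fabricating
  origin probabilities for ambiguous cases.
* Constrained REML's boundary bias for near-zero components (above) is
  inherent; interval estimates near the boundary should be read with
  care.
* The scan treats count traits as Gaussian, as is standard for litter
  size at these means and variances.
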