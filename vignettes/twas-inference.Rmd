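---
title: "Summary-statistic TWAS inference: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistic TWAS inference: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sumtwas` implements the inference chain that sits downstream of a
transcriptome-wide association study (TWAS): it consumes GWAS summary
statistics, expression SNP-weight panels and an LD reference, and produces
feature-level associations, correlation-aware significance thresholds,
regional joint/conditional analyses, colocalization posteriors, competitive
enrichment statistics and an expression-mediated heritability partition.
This vignette is the package's own account of the underlying models, the
tunable parameters, and the design decisions taken where the methodology
left genuine choices.

## The TWAS statistic and its null

A *feature* is one gene x expression-panel unit with a cis SNP-weight
vector $w$ estimated in an expression reference panel. Given marginal GWAS
Z scores $z$ and the SNP correlation (LD) matrix $R$ over the feature's
weight SNPs, the association of genetically predicted expression with the
trait is the quadratic-form statistic

$$Z_{TWAS} = \frac{w^\top z}{\sqrt{w^\top R w}},$$

which is standard normal under the GWAS null whenever $z$ is, regardless of
LD, because $w^\top R w$ is exactly the variance of $w^\top z$. The
denominator is the predicted-expression variance, so $Z_{TWAS}$ is
invariant to positive rescaling of the weights. Features with
$w^\top R w \le 10^{-10}$ carry no predicted-expression signal and are
rejected as degenerate.

Harmonization orients weights and summary statistics into the LD reference
allele frame: swapped alleles flip the sign of the weight or the Z score;
strand-ambiguous SNPs (A/T, C/G) are dropped outright rather than
frequency-matched because the input formats carry no allele frequencies;
allele mismatches and missing SNPs are dropped and counted, with one
summary message per scan rather than one per record.

## Transcriptome-wide significance

Features are correlated through LD: within a block,
$r_{ij} = w_i^\top R w_j / \sqrt{(w_i^\top R w_i)(w_j^\top R w_j)}$, and
exactly zero across blocks. A Bonferroni correction over all features would
therefore be conservative. The family-wise threshold is estimated by
sampling feature-score vectors from $\mathcal N(0, C)$ with $C$ the
block-diagonal feature correlation matrix, recording each draw's minimum
two-sided p over all features, and taking the $\alpha$ quantile of that
minimum-p distribution. This is equivalent in distribution to permuting a
null GWAS through the full pipeline but costs only multivariate-normal
draws from quantities the association stage already computes. The Monte
Carlo standard error is read off the order statistics adjacent to the
quantile. With independent features the threshold converges to the Sidak
value $1-(1-\alpha)^{1/m}$, and duplicated features do not pay a multiple
testing price — the two properties that motivate the construction. Defaults:
$\alpha = 0.05$ family-wise, 50,000 draws. Benjamini–Hochberg FDR-adjusted
p values are attached for comparison.

## Regional joint and conditional analysis

Significant features whose boundaries padded by 0.5 Mb overlap are merged
into regions by single linkage (reported combined associations use a 1 Mb
dependence window). Within a region, conditionally independent
associations are found by greedy forward selection: at each step the
feature with the smallest conditional p enters the model, where the
conditional Z of feature $j$ given the selected set $S$ is

$$z_{j|S} = \frac{z_j - C_{jS} C_{SS}^{-1} z_S}
                 {\sqrt{1 - C_{jS} C_{SS}^{-1} C_{Sj}}},$$

and selection stops when no remaining conditional p clears the
transcriptome-wide threshold. Selected features are *jointly significant*;
the remaining members are *marginally significant* — their signal is
accounted for by the selected set. Singular correlation submatrices
(near-duplicate features) receive a logged $10^{-6}$ diagonal ridge.

The same projection conditions individual GWAS SNPs on the predicted
expression of the selected features, using the SNP-feature correlation
$\rho_j = (Rw)_j / \sqrt{w^\top R w}$. The fraction of a SNP association
explained is reported as $1 - \chi^2_{cond} / \chi^2_{uncond}$. Note this
quantity is only guaranteed to lie in $[0,1]$ when the conditioning
features actually carry the SNP's signal; a SNP uncorrelated with the
features' Z scores but correlated with their expression can have its
conditional $\chi^2$ *increase*. The package reports the raw ratio without
clamping; a SNP collinear with the feature set
($1 - \rho^\top C^{-1} \rho \le 10^{-8}$) is reported as fully explained.

A gene's evidence is pooled across panels by the omnibus test: the panel Z
vector is whitened by the eigendecomposition of the panel correlation
matrix, components with eigenvalue below $10^{-4}$ of the maximum are
discarded, and the sum of squared whitened scores is chi-square with one
degree of freedom per retained component. With one retained component this
reproduces the two-sided per-feature p exactly.

As a functionally agnostic comparison, the SNP-wise mean gene test
averages GWAS $\chi^2$ over the SNPs within 10 kb of a gene. Its null is
the quadratic form $\sum_i \lambda_i \chi^2_1 / m$ with $\lambda$ the
eigenvalues of the window's LD matrix, approximated by a moment-matched
scaled chi-square (Satterthwaite: scale $\sum\lambda_i^2/\sum\lambda_i$,
df $(\sum\lambda_i)^2/\sum\lambda_i^2$). The approximation error is
negligible at these degrees of freedom and is checked by simulation rather
than by exact inversion of the quadratic form.

## Colocalization

Whether the GWAS and expression signals share a causal variant is assessed
with single-causal-variant approximate-Bayes-factor colocalization. Each
SNP's evidence is the Wakefield approximate Bayes factor,
$\log ABF = \tfrac12\log(1-r) + \tfrac12 z^2 r$ with $r = W/(W+v)$, prior
effect variance $W = 0.15^2$ and sampling variance $v = 1/N$ for a
standardized trait. Hypothesis sums (H0 none, H1/H2 one trait, H3 two
distinct causal SNPs, H4 one shared causal SNP) are accumulated in log
space with log-sum-exp; priors default to $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$ (the conventional single-causal coloc defaults — the
choice is configurable because the upstream literature does not pin it
down). The expression-side marginal statistics are not part of a weight
bundle, so they are reconstructed from the weights as
$z_e = \sqrt{N_{eqtl}}\,\rho_j\,\sqrt{h^2_{cis}}$ — the marginal
association implied when the true expression is the predicted expression
plus noise. This reconstruction is an interpretation, and it is the reason
the package's discrimination experiments simulate both traits' summary
statistics directly instead of relying on it.

In those experiments a 40-SNP AR(1) region ($\rho = 0.5$) is simulated at
$N = 50{,}000$ per trait with the causal SNP's expected marginal Z set to
8 — the strength of an unambiguous genome-wide-significant locus. At that
strength the shared-causal posterior pp4 and the distinct-causal posterior
pp3 both exceed 0.9 in well over 90% of replicates; at weaker signals
(expected Z near 7) the H3-versus-H1 margin collapses in unlucky draws
because a 2-SD-low causal Z no longer overcomes the
$p_{12}/(p_1 p_2)$ prior advantage of the shared-variant hypothesis.

## Competitive enrichment via a linear mixed model

The enrichment machinery asks whether a set of genes is *more* associated
than the rest of the transcriptome (competitive, not self-contained). The
response is the positive-oriented association score
$z_{assoc} = \Phi^{-1}(1-p)$ computed from the two-sided TWAS p value —
under the null it is exactly standard normal, and using the magnitude
rather than the signed $Z_{TWAS}$ prevents opposite-direction effects from
cancelling (splicing and transcript features of one gene frequently have
inverted signs). The model is

$$z_{assoc} = \beta_0 + \beta_s s + g + e,\qquad
  g \sim \mathcal N(0, \sigma^2_g K),\quad
  e \sim \mathcal N(0, \sigma^2_e I),$$

with $s$ the membership indicator (or a centered-and-scaled continuous
property score) and $K$ the feature-relatedness matrix assembled
block-wise from *squared* predicted-expression correlations. Squaring is
deliberate: the covariance of association *strength* between two features
does not depend on the sign of their expression correlation. Negative
eigenvalues introduced by clipping are set to zero and the matrix is
renormalized to unit diagonal. The unit of analysis is the feature, with
gene-level set membership propagated to all of a gene's features; the
all-ones blocks that duplicated genes create in $K$ absorb the redundancy.

Variance components are estimated by REML profiled on the eigenbasis of
$K$: with $K = U\Lambda U^\top$, rotating the model gives
$V = \sigma^2_e (I + \delta\Lambda)$, $\delta = \sigma^2_g/\sigma^2_e$, so
a single eigendecomposition (done block-wise) reduces each fit to a 1-D
bounded search over $\log\delta \in [-12, 10]$ with the $\delta \to 0$
(OLS) boundary checked explicitly. Inference on $\beta_s$ is a Wald t test
on $n - p$ degrees of freedom: one-sided for sets and panels (enrichment
only), two-sided for continuous properties, which can correlate
negatively. With $K = I$ the fit reduces *exactly* to OLS, which is the
package's closed-form oracle. Gene-set p values are FDR-corrected across
sets; the 19 developmental-stage property tests use Bonferroni at
$0.05/19$. No fixed-effect covariates are included by default; the number
of weight SNPs and cis-$h^2$ can be supplied as optional covariates.

## Heritability partition

For SNP $j$, the LD score is $\ell_j = \sum_k r^2_{jk}$ (self term
included) and the predicted-expression score is
$\ell^E_j = \sum_f \rho^2(j, f)$, the summed squared correlation between
the SNP and each feature's predicted expression — the natural stratified
annotation for "SNP tags predicted expression", additive over features.
The stratified regression

$$E[\chi^2_j] = 1 + N\,(\tau_T\,\ell_j + \tau_E\,\ell^E_j)$$

is fit by weighted least squares with a free intercept and block-jackknife
standard errors (200 contiguous SNP blocks by default). Because every
feature's predicted expression is scaled to unit variance, $\tau_E$ is the
per-feature mediated effect variance, so the mediated heritability is
$n_{features}\,\tau_E$ — the per-category normalizer $M_c$ is the number of
*units* the category averages over (SNPs for the total category, features
for the expression category). The total heritability is reported from the
same two-category fit as $M\tau_T + n_{feat}\tau_E$: under the generator
that regression is exactly correctly specified, whereas a separate
single-category fit is biased on mediated architectures through the
correlation between $\ell$ and $\ell^E$.

Regression weights are $1/\max(\ell_j, 1)$ times, by default, a second-pass
heteroskedasticity factor $1/(2\,\widehat{E[\chi^2_j]}^2)$. The second pass
matters: the variance of $\chi^2_j$ grows with the *square* of its mean, so
with pure $1/\ell$ weights the handful of high-signal SNPs dominate the
sampling error of $\tau_T$, which is then amplified by $M$; measured on
fully mediated simulations the standard deviation of the estimated
mediated proportion falls from roughly 60 to roughly 8 percentage points
when the second pass is enabled. `het_weights = FALSE` restores the
single-pass scheme.

Case-control (observed-scale) estimates convert to the liability scale by
$h^2_{liab} = h^2_{obs}\,K^2(1-K)^2 / (P(1-P)\,\varphi(t)^2)$,
$t = \Phi^{-1}(1-K)$, with population prevalence $K$ and sample case
proportion $P$ supplied by the user (for an autism-spectrum-disorder
case-control GWAS, $K = 0.012$ and $P = 0.3965$ are the conventional
values). The headline quantity is the percentage
$100\,h^2_{TWAS}/h^2_{total}$, reported with a warning — never clamped — if
it exceeds 100.

## What the generator emulates, and what it does not

The synthetic-data module generates every input with known ground truth:

* **LD**: block-diagonal AR(1), $R_{ij} = \rho^{|i-j|}$, default
  $\rho = 0.8$ and 100 SNPs per block at 1 kb spacing. Closed-form entries
  make the oracles exact (e.g. the interior-SNP LD score is a geometric
  series). Real LD is block-*ish*, not block-diagonal, and has long-range
  exceptions; nothing here tests robustness to mis-specified LD panels.
* **Weights**: a sparse subset (default 5%) of a block's SNPs with
  Gaussian weights rescaled so $w^\top R w = h^2_{cis}$ exactly (default
  0.2, a typical cis-heritability). Real FUSION weights come from
  penalized regressions with estimation noise; that noise is upstream of
  this package's scope.
* **GWAS**: marginal scores drawn at the summary level,
  $z = \sqrt N\,R\beta + \epsilon$, $\epsilon \sim \mathcal N(0, R)$ per
  block, with $\beta$ the sum of iid direct effects and mediated effects
  $\alpha_f w_f / \sqrt{w_f^\top R w_f}$ — so $\alpha_f$ is the
  standardized effect of predicted expression and
  $E[Z_{TWAS}] = \sqrt N \alpha_f$. No genotypes and no phenotype
  liability are ever simulated; sample overlap, stratification and
  imputation error are out of scope, which is why a passing calibration
  here does not certify calibration on real GWAS with inflated intercepts.
* **Defaults**: $N = 46{,}350$ (a modern psychiatric case-control GWAS);
  effect scales chosen so mediated heritability is roughly 13% of a total
  observed-scale 0.12 at the default 4,000 SNPs and 400 features.
* **Sets and properties**: membership sampled without replacement; genes
  in enriched sets get $\alpha^2$ inflated by `enriched_effect`; stage
  scores are drawn with a target correlation to $\alpha^2$.

Everything is a pure function of the configuration seed.

## Problem sizes

The validation suite runs at desk scale, chosen as the smallest sizes at
which the asymptotic checks are meaningful: 2,000 features over 100 LD
blocks for null calibration of $Z_{TWAS}$ and of 500 random gene sets;
50,000 draws for the threshold-versus-Sidak comparison at 100 features;
100 replicates per colocalization scenario; 20,000 SNPs, $N = 50{,}000$
and 50 replicates for heritability recovery at $h^2 = 0.3$, with the
fully mediated proportion averaged over 10 replicates (a single replicate
has a sampling sd of about 8 percentage points). The `analysis/` scripts
run a smaller 4,000-SNP, 800-feature showcase study end to end.

## Known limitations

* Single-causal-variant colocalization only; allelic heterogeneity within
  a region dilutes all five posteriors.
* The expression-side reconstruction used by `coloc_feature()` assumes the
  weight vector is the truth; weight estimation noise is not propagated.
* The forward-selection joint model is greedy; with near-collinear
  features the retained representative is the largest-Z one, which is not
  guaranteed to be the causal feature.
* `variance_explained` is a chi-square ratio, not a variance decomposition;
  see the conditioning section for when it can leave $[0,1]$.
* The heritability regression assumes homogeneous mediated-effect variance
  across features; real architectures with a few large-effect genes will
  inflate the jackknife standard errors.
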