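---
title: "Methods: the two-sample MR inference chain in strokemr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-sample MR inference chain in strokemr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemr)
```

# Scope and model

strokemr implements the complete inference chain of a two-sample Mendelian
randomization (MR) study linking genetic predispositions to clonal
hematopoiesis (CH) driver mutations with stroke subtypes: summary-statistic
reconstruction, instrument selection, allele harmonization, random-effects
inverse-variance-weighted (IVW) estimation with heterogeneity and pleiotropy
sensitivity tests, two-step product-method mediation, and Bayesian
colocalization. Every stage consumes and produces plain GWAS summary
statistics — no individual-level genotypes are involved anywhere.

The structural model is the standard instrumental-variable one. For
instrument $j$, let $\gamma_j$ be its effect on the exposure and
$\Gamma_j$ its effect on the outcome. Under the MR assumptions
(relevance, independence, exclusion restriction),
$\Gamma_j = \theta\,\gamma_j$, and $\theta$ — the causal effect of the
exposure on the outcome on the log-odds scale — is identified from
summary statistics alone.

# Summary-statistic reconstruction

Public GWAS frequently release only an odds ratio and a P value per SNP.
The additive effect and its standard error are recovered as

$$\beta = \ln(\mathrm{OR}), \qquad
  Z = \Phi^{-1}\!\left(1 - P/2\right), \qquad
  \mathrm{SE} = |\beta| / Z.$$

Three numerical choices matter here:

* **Natural log, not log10.** The product method and the OR = $e^\beta$
  reporting convention require effects additive in $\ln(\mathrm{OR})$.
* **Underflow floor.** Real GWAS files contain $P = 0$ rows; the quantile is
  undefined there, so P is floored at a configurable `p_floor`
  (default $10^{-300}$) first.
* **Upper-tail quantile.** $\Phi^{-1}(1-P/2)$ is evaluated as
  `qnorm(P/2, lower.tail = FALSE)`; the naive complement form rounds
  $1 - P/2$ to 1 in double precision once $P < 4\times10^{-16}$ and would
  return an infinite $Z$ (SE of zero).

When a row already carries a usable SE, it is passed through untouched;
reconstruction applies only where needed. Alleles are uppercased on read and
indel (multi-character) alleles are rejected, because the strand logic of
harmonization is defined only for single nucleotides. Positions are 1-based
throughout.

# Instrument selection

Instruments are the SNPs with $P < 5\times10^{-6}$ (strict inequality; a SNP
exactly at the threshold is excluded), followed by greedy LD clumping at
$r^2 < 0.001$ within 10,000 kb: candidates are ranked by ascending P value —
ties broken lexicographically by SNP id so results are identical across
platforms — and each successive index SNP removes every remaining candidate
on the same chromosome within the window whose squared correlation with it
reaches the threshold. SNPs absent from the LD panel are dropped with a
warning rather than assumed independent; treating unknown LD as zero would
leak correlated instruments into the IVW fit. Different chromosomes are
always independent.

# Harmonization

Exposure and outcome effects must refer to the same effect allele. Four
rules are applied per SNP, in a fixed order, and every instrument receives
exactly one disposition in an audit log:

1. **Palindromic pairs** (A/T, C/G) are always removed. Their strand is
   undecidable from alleles alone, so no correction can be trusted. The
   palindrome check runs first, before any strand logic, and there is no
   frequency-based rescue at intermediate allele frequencies: fidelity to the
   stated unconditional rule was preferred over the extra power a rescue
   would buy.
2. **Exact or swapped matches** are kept; a swap negates the outcome beta
   and replaces the outcome allele frequency by $1 - \mathrm{EAF}$.
3. **Complement-strand matches** (the outcome was reported on the opposite
   strand) are corrected, optionally with the same sign flip.
4. **Anything else is incompatible** and removed.

Exposure records are never modified. Duplicate outcome rows resolve to the
first occurrence with a warning — a deterministic rule for messy inputs.

# Estimation

With harmonized pairs $(\hat\beta_{Xj}, \hat\beta_{Yj}, \sigma_{Yj})$, the
IVW estimate is weighted least squares of outcome on exposure effects
through the origin with weights $w_j = 1/\sigma_{Yj}^2$:

$$\hat\theta = \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
                    {\sum_j w_j \hat\beta_{Xj}^2},\qquad
  \mathrm{SE}_{\mathrm{fixed}} = \Big(\sum_j w_j \hat\beta_{Xj}^2\Big)^{-1/2}.$$

The *random-effects* variant inflates the SE multiplicatively by
$\sqrt{\max(Q/(n-1),\,1)}$, where $Q$ is Cochran's statistic below. The
floor at 1 means the random-effects SE never shrinks below the
fixed-effects SE; under-dispersion is not rewarded. P values come from the
standard normal. A single instrument reduces to the Wald ratio
$\hat\beta_Y/\hat\beta_X$ with first-order SE $\sigma_Y/|\hat\beta_X|$
(second-order terms were left out; they change nothing at the instrument
strengths considered here). 95% intervals are Wald intervals
$\exp(\hat\theta \pm 1.96\,\mathrm{SE})$.

Association strength is tiered by P value: strong ($P \le 0.01$), moderate
($P \le 0.05$), weak ($P \le 0.1$), with inclusive boundaries, rendered as
`***`/`**`/`*` in the grid reports.

**Sensitivity.** Cochran's
$Q = \sum_j w_j^\ast (r_j - \hat\theta)^2$ over the per-instrument ratios
$r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order weights
$w_j^\ast = (\hat\beta_{Xj}/\sigma_{Yj})^2$ is referred to
$\chi^2_{n-1}$; $P > 0.05$ is read as no heterogeneity. The MR-Egger
intercept test fits weighted least squares *with* intercept after orienting
each pair so $\hat\beta_{Xj} \ge 0$ (the orientation is internal to the fit
and never alters stored pairs); a nonzero intercept indicates directional
pleiotropy. Egger SEs use the same multiplicative dispersion floored at 1,
and intercept/slope P values use the $t_{n-2}$ distribution — the
conventional small-sample treatment for the intercept test, whereas IVW
keeps the normal reference.

# Mediation

The two-step design asks four questions of four univariable MR fits at
level $\alpha = 0.05$: exposure→outcome, mediator→outcome, and
exposure→mediator must be significant, and the reverse outcome→exposure fit
must *not* be. The indirect effect is the product
$\beta_{EM}\,\beta_{MO}$ of the exposure→mediator and mediator→outcome
estimates, and the proportion mediated divides it by the total effect — all
on the log-odds scale, where the product method is additive. Computing the
proportion on the OR scale instead would not reproduce the published
arithmetic (ORs 1.23, 1.26, 1.29 give
$\ln 1.23 \cdot \ln 1.26 / \ln 1.29 \approx 0.188$).

The mediator→outcome leg uses the univariable estimate by default; a
mediator-adjusted direct-effect fit can be supplied as an option but is not
the default, since no multivariable machinery is part of the chain.
Proportions above 100% (inconsistent mediation) warn rather than error.
No delta-method interval is attached to the proportion; the component CIs
are reported instead.

# Colocalization

For a $\pm$500 kb window around the lead SNP — operationalized as the shared
SNP minimizing the product of the two traits' P values, since "most
significant pair" needs a concrete rule — each SNP gets a Wakefield
approximate Bayes factor. With $V = \mathrm{SE}^2$, $W$ the prior effect
variance and $Z = \beta/\mathrm{SE}$:

$$\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W}
  + \tfrac12 Z^2 \frac{W}{V+W}.$$

The prior effect SD defaults to 0.15 for case-control traits and 0.2 for
quantitative traits — the conventional defaults of the method — and is
configurable. Under the single-causal-variant-per-trait assumption the five
hypothesis weights are

$$w_0 = 1,\quad w_1 = p_1 S_1,\quad w_2 = p_2 S_2,\quad
  w_3 = p_1 p_2 (S_1 S_2 - S_{12}),\quad w_4 = p_{12} S_{12},$$

with $S_1 = \sum_i e^{l_{1i}}$, $S_2 = \sum_i e^{l_{2i}}$,
$S_{12} = \sum_i e^{l_{1i}+l_{2i}}$ and priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. Posteriors are the normalized
weights; $\mathrm{PP}(H_4) \ge 0.8$ is the colocalization verdict. All sums
run in log space (log-sum-exp), so $|Z|$ up to 100 cannot overflow, and the
$S_1 S_2 - S_{12}$ difference is taken through `log1p`. In a single-SNP
region $S_{12} = S_1 S_2$ exactly and $w_3$ is pinned to zero with a note —
two distinct causal variants are impossible there.

# The synthetic-data generator

The generator emulates the statistical structure of the source GWAS so the
chain is testable without any downloads. It simulates summary statistics
directly: per-SNP standard errors follow the
$1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ scaling at the configured sample
sizes (the defaults, 176,219 exposure and 500,000 outcome samples, match the
magnitudes of the source cohorts), observed effects are true effects plus
$N(0, \mathrm{SE}^2)$ noise, and P values are the two-sided normal tails —
so every record satisfies the Z/P/SE coherence invariant by construction.
Exposure and outcome panels use seeds `seed` and `seed + 1`: independent
samples (the two-sample design has no overlap) that remain jointly
reproducible from one integer.

Choices worth stating explicitly:

* **Instrument strength.** Instruments receive effects
  $\gamma_j = z_{\min}\mathrm{SE}_j + |N(0, \sigma_\gamma^2)|$ with
  $z_{\min} = 6$ and $\sigma_\gamma = 0.1$. The floor keeps every planted
  instrument's expected P value clear of the $5\times10^{-6}$ selection
  threshold; the spread matches the magnitude of published CH-risk log-ORs
  (roughly 0.1–0.4 at genome-wide-significant loci). At this strength the
  mean instrument F-statistic is in the hundreds, so weak-instrument
  regression dilution — a real bias of order $\theta/F$ that the IVW
  estimator inherits from noisy exposure effects — sits well below the
  Monte-Carlo resolution of the recovery suites. At much weaker settings
  that dilution becomes visible; it is a property of the data-generating
  process, not an estimator defect.
* **Positive orientation.** Instrument effect alleles are coded as the
  exposure-increasing allele ($\gamma_j \ge 0$), the usual convention for
  summary-level instruments. This matters for the Egger suite: with random
  effect signs, the $\beta_X \ge 0$ orientation inside the Egger fit would
  flip the sign of half the pleiotropic effects and the intercept would
  estimate a mean attenuated toward zero rather than the generating
  $\mu_\alpha$.
* **Pleiotropy.** Instrument-specific outcome effects
  $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ are drawn independently of
  instrument strength, so the InSIDE assumption holds by construction —
  the regime where the Egger intercept consistently estimates $\mu_\alpha$.
* **Mediation triples** use three disjoint instrument sets (exposure,
  mediator, outcome); the outcome-specific set has no exposure or mediator
  effect, so the reverse-MR condition is null by construction. The default
  path effects (0.21, 0.23, 0.21 direct) give a true proportion mediated of
  ~18.7%, mirroring the published magnitudes.
* **Colocalization regions** are one 1 Mb window of 200 SNPs with LD
  $r_{ij} = 0.9^{|i-j|}$ (two uncorrelated half-blocks in the
  distinct-causal case), true marginal Z of $10\,r_{ic}$ around the causal
  SNP, and *LD-correlated* noise (multivariate normal with the LD
  correlation) — the correct sampling model for marginal statistics computed
  on a single cohort.

What the generator deliberately does not model: realistic allele-frequency
spectra, imputation quality, sample overlap, trans-ancestry heterogeneity,
and selection-induced winner's curse (instruments are planted, not
discovered). Tests passing on this generator therefore certify the
*inference chain*, not robustness to those real-data pathologies.

# Calibration suites and problem sizes

The packaged calibration harnesses (`mr_replicates()`,
`coloc_replicates()`) drive the acceptance checks at these sizes, chosen to
give tight Monte-Carlo resolution at desk scale:

* Recovery: 1000 replicates at $\theta = 0.25$ with 17 instruments (the
  TET2 instrument count); mean recovery is checked against a
  $3\times$Monte-Carlo-SE band (a pre-registered 99.7% band) and CI coverage
  against [0.93, 0.97].
* Null calibration: 1000 replicates at $\theta = 0$ with 95 instruments —
  the largest published instrument set (the any-mutation exposure), where
  the $\chi^2$ and $t$ reference distributions are closest to exact.
  Rejection rates for IVW, Cochran's Q and the Egger intercept are all
  required to land in [0.03, 0.07]. A caveat stated here rather than
  hidden: the dispersion floor makes the random-effects IVW and Egger tests
  mildly conservative at small instrument counts (empirically ~0.03
  rejection around $n \approx 17$ for Egger); that conservativeness shrinks
  as $n$ grows.
* Egger recovery: 1000 replicates at $\mu_\alpha = 0.05$,
  $\sigma_\alpha = 0.02$, 17 instruments.
* Colocalization: 200 shared-causal and 200 distinct-causal regions;
  shared regions must reach $\mathrm{PP}(H_4) \ge 0.8$ and distinct regions
  $\mathrm{PP}(H_3) > \mathrm{PP}(H_4)$, each in at least 90% of
  replicates. The three-SNP posterior is additionally pinned to an
  exhaustive enumeration oracle at $10^{-10}$.

# Degenerate inputs and tie-breaking

* OR = 1 with only a P value: the SE is unrecoverable; error.
* $\hat\beta_X = 0$: the Wald ratio is undefined; error for the single-pair
  case (the SNP simply contributes nothing in IVW).
* Collinear Egger design (all oriented $\hat\beta_X$ equal): rank-deficient;
  signalled rather than silently inverted.
* Clumping ties in P: lexicographic SNP id. Lead-SNP ties in the P-value
  product: smaller minimum P, then lexicographic id.
* Zero usable instruments in a grid cell: the cell is reported as
  `insufficient_snps` (the gray box of the result heatmaps), never an
  exception; one unreadable input fails its cells, not the grid.

# Known limitations

The chain implements exactly the published procedure: no weighted-median or
mode estimators, no MR-PRESSO outlier removal, no Steiger filtering, no
multivariable MR, no proxy-SNP lookup for instruments missing in the
outcome, and no LD-aware (multi-causal) colocalization. The LD panel is an
input; the package does not compute LD from reference genotypes. P values
across the analysis grid are interpreted through the three-tier scheme
without multiple-testing correction, matching the source design; a
Bonferroni column can be appended to reports as a clearly labeled extension.
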