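---
title: "Information thermodynamics of cytosine methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information thermodynamics of cytosine methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylinfo)
```

## The model

Bisulfite sequencing reports, at each cytosine site $i$, a methylation level
$p_i = \#C_i / (\#C_i + \#nonC_i)$ — the fraction of reads supporting
methylation. At tissue level the methylation status of site $i$ is a
Bernoulli variable with parameter $p_i$, whose uncertainty is the binary
Shannon entropy

$$H(p_i) = -p_i \log_2 p_i - (1 - p_i)\log_2(1 - p_i)$$

with $0\log 0 = 0$. A methylation change in a genomic region $R$ between two
states (two samples, two generations, two tissues) processes an absolute
amount of information

$$I_R = \Bigl|\sum_{i \in R} H(p_i^{after}) - \sum_{i \in R} H(p_i^{before})\Bigr|,$$

and by Landauer's principle the minimum energy dissipated to process it is
$E_R = I_R\, k_B T \ln 2$. One bit at 298 K is about $3\times10^{-21}$ J.
Note the deliberate consequence that a site flipping from level 0 to level 1
carries zero information change: both states are certain, so no uncertainty
was created or destroyed. Missing observations (a site with no coverage in a
sample) contribute zero entropy, which leaves the sums unaffected — this is
why union-of-sites matrices over many methylomes remain usable without
imputation.

Because $I_R$ cannot discriminate between the certain states, three
information divergences complement it at site level: total variation
$TV(p,q) = |p-q|$, Kullback–Leibler
$KL(p,q) = p\log_2(p/q) + (1-p)\log_2\bigl((1-p)/(1-q)\bigr)$, and the
squared Hellinger divergence
$H^D(p,q) = (\sqrt{p}-\sqrt{q})^2 + (\sqrt{1-p}-\sqrt{1-q})^2 \le 2$.
Region divergences sum site divergences: $D_R = \sum_{k\in R} D_k$.

Two numerical conventions deserve mention. First, we use base-2 logarithms
throughout, so $I$ and $KL$ are in bits and Landauer's constant applies per
bit. Under this convention the textbook ordering $TV \le H^D \le KL$ does
*not* hold for small divergences (e.g. $TV(0.5,0.6)=0.1$ exceeds
$KL = 0.029$ bits), and the package does not enforce it. Second, $KL$
against a degenerate level ($q \in \{0,1\}$ with $p$ off the boundary) is
reported as an `Inf` sentinel rather than an error; distribution fitting
excludes non-finite values.

## The statistical-mechanical null

Under the assumptions of a maximum-entropy derivation for energies
dissipated across many independent regions, $E_R$ (hence $I_R$, hence any
divergence proportional to an energy) follows a generalized-gamma (GG)
distribution with location:

$$F(x \mid \alpha,\lambda,\mu,\psi) = \frac{\gamma\!\bigl(\psi, ((x-\mu)/\lambda)^\alpha\bigr)}{\Gamma(\psi)},$$

which reduces to the three-parameter Weibull CDF
$F(x) = 1 - e^{-((x-\mu)/\lambda)^\alpha}$ at $\psi = 1$. The scale
$\lambda(l)$ carries the physics: it is the contribution of all degrees of
freedom to the average energy per molecule, divided by $\ln 2$, and depends
on the region length $l$.

`fit_cdf()` estimates the parameters by nonlinear least squares of the model
CDF against the pointwise empirical CDF of the observed $I_R$ or $D_R$
values. Choices made here, with reasons:

* **Plotting positions.** Hazen positions $(i - 0.5)/n$ avoid the 0 and 1
  endpoints that distort tail fitting. (Whether the original analysis used
  binned or pointwise ECDFs is unknown; pointwise is the stricter target.)
* **Minimizer.** Bounded Gauss–Newton (`nls(algorithm = "port")`) with a
  small multi-start over $(\alpha_0, \mu_0)$, because the $(\mu, \lambda)$
  trade-off creates local optima near the support boundary, plus an
  `optim(L-BFGS-B)` fallback. Fits are deterministic given data.
* **Bounds.** $\alpha \in [10^{-3}, 50]$, $\lambda > 0$,
  $\mu \in [0, \min(x))$, $\psi \in [10^{-3}, 100]$. The negative-$\alpha$
  GG branch is implemented in `gg_cdf()` but not explored by default fits.
* **Value floor.** Values below `min_value` ($10^{-8}$ bits by default) are
  excluded: regions with near-zero information changes proliferate when
  tiles shrink below ~2 kb and visibly distort the fit.
* **Degenerate input** (all values equal) yields `converged = FALSE`, never
  a silent success.

Goodness of fit is reported as RSS, $R^2$, Stein's adjusted $R^2$
(an estimator of average cross-validated predictive power), and
least-squares AIC/BIC, $n\ln(\mathrm{RSS}/n) + 2(k+1)$.

**A caution on AIC for nested CDF fits.** ECDF residuals are strongly
autocorrelated, so least-squares AIC differences between nested models are
wildly optimistic: on data generated from a Weibull, the GG fit's extra
shape parameter routinely "wins" hundreds of AIC units while the fitted CDF
moves by less than 0.02 anywhere and $\hat\psi$ stays near 1. AIC is
therefore reported but `select_model()` also flags fits whose
$\hat\lambda$ is physically implausible (outside $[10^{-6}, 10^{6}]$ bits by
default, configurable); near-zero scales mean a meaningless average energy
per molecule regardless of AIC rank. This mirrors the original analysis,
where model selection leaned on the physical meaning of $\hat\lambda$, not
on information criteria alone.

## Persistence length from the scale trend

Averaging the fitted scales per region length gives the trend
$\bar\lambda(l)$ (`lambda_trend()`, two-stage: fit per sample, then average
— unweighted, as sample counts per length are typically equal). Treating
DNA as a worm-like chain links the trend to the persistence length $L_p$
(~50 nm for B-DNA). We fix the relation between scale and bending energy as
$\lambda(l) = a\,e^{2E(l)/(k_B T)}$; this is the unique reading consistent
with the entropic-spring energy $E(l) = \tfrac{3 k_B T}{4 L_p} l$ producing
the exponent $\tfrac{3}{2} l/L_p$ and the estimator $L_p = 3/(2\hat d)$
below (the printed source of this relation is typographically ambiguous).

* **Long fragments** ($l \gg L_p$; tiles of 2000–5000 bp):
  $\lambda(l) = (1-b)/\ln 2 + b\,l/(L_p \ln 2)$, so an OLS line
  $\hat\lambda(l) = a' + b'l$ gives $\hat L_p = (1 - a'\ln 2)/(b'\ln 2)$.
* **Short fragments** ($l \lesssim L_p$; methylation words):
  $\lambda(l) = a\,e^{3l/(2L_p)}$, so a nonlinear fit
  $\hat a e^{\hat d l}$ gives $\hat L_p = 3/(2\hat d)$.

Lengths must be in nm (0.34 nm per bp; the package refuses to estimate
$L_p$ from a bp-unit trend unless converted, because the estimate is unit-
dependent). Negative slopes or non-positive implied $L_p$ are flagged
invalid rather than returned silently.

**Conditioning.** The two estimators behave very differently under noise.
The exponential estimator depends only on the fitted decay rate and
recovers $L_p = 50$ nm to &lt; 5% median error under 2% multiplicative noise.
The linear estimator's numerator $1 - a'\ln 2$ requires extrapolating the
intercept to $l = 0$, three tile-lengths outside the observed 680–1700 nm
range; 2% noise on $\bar\lambda$ translates to ~40% median error on $L_p$
purely from conditioning. Both round-trip exactly ($<10^{-6}$ relative) on
noiseless forward-model data; only the exponential model is held to the
noisy-recovery tolerance in the acceptance suite.

## Calling DIMPs and DIMRs by signal detection

The fitted null CDF describes methylation *background noise* — changes
induced by thermal fluctuations that stabilize the molecule. For an observed
site divergence $d_0$, $P(D > d_0) = 1 - F(d_0)$ is the probability that
background alone produces a divergence at least as large, i.e. the false-
positive probability of declaring the site differentially methylated. A site
is a **DIMP** at level $\alpha$ iff that probability falls below $\alpha$;
regions of a common size are thresholded identically on $D_R$ (**DIMR**).
No multiple-testing adjustment is applied — the decision variable is the
false-positive probability itself, which is the signal-detection framing
that motivates the method. The default divergence is the squared Hellinger
($H^D$), the conservative choice; all kinds are exposed because no claim of
optimality among them is made. The null is fitted per sample pair on all
observed divergences (the candidate's own tail included, matching the
original procedure; a trimmed robust option exists but is off by default).

Fisher's exact test on the 2×2 read-count table is provided as the
classical comparator (`fisher_dmp()`, two-sided, unadjusted by default,
optional Benjamini–Hochberg). Note the two callers answer different
questions: Fisher detects any difference in level given the read depths —
at 30× coverage it fires on half the sites of a pair whose divergences
follow the default background law — while the SDT caller asks whether a
divergence is too large *for the physical background*.

## The binary methylation language

Pooling samples, a site is assigned digit 1 if its level is positive in at
least one methylome, else 0 (missing = no positive evidence). A **potential
word framework** (PWF) at threshold $d$ is a maximal substring starting and
ending in 1 whose internal zero-runs are all shorter than $d$; runs of
$\ge d$ zeros separate words, and the set of words at threshold $d$ is the
partition $S_d$. A long PWF from $S_d$ reads as a *sentence*: sub-words
(each from a finer partition $S_k$, $k$ = max internal zero-run + 1)
separated by zero-strings of length exactly $d-1$.

PWF length is measured in **digits** (cytosine sites); the genomic span in
bp is recorded alongside, because consecutive cytosines are not generally
adjacent base pairs. The digit length is converted at 0.34 nm per digit when
feeding the entropic-spring persistence estimate — exact only where every
position is a cytosine, which is the same approximation the source analysis
makes.

The length spectrum follows a Boltzmann (maximum-entropy) decay law
$f_l = \phi e^{-\gamma l}$ with $\phi = N_0/Z$; `fit_decay()` fits raw
counts (so $\phi$ has count units and the free energy
$\Delta F = RT\ln(N_0/\phi)$ applies directly, $R = 8.314$ J mol⁻¹ K⁻¹,
default $T = 298.15$ K). A non-decaying $\hat\gamma \le 0$ is flagged, not
hidden.

## What the simulator emulates — and what it does not

`sim_spec()` states the generator's world once:

* **Genome**: one 1 Mb chromosome, 20,000 cytosine sites at uniform random
  positions, contexts CG/CHG/CHH at 25/25/50% — a plant-like mixture.
* **Coverage**: negative binomial, mean 30×, size 5, with 2% of sites
  forced to zero coverage (missing), typical of bisulfite libraries.
* **Levels**: Beta per context — CG Beta(0.8, 0.2) (bimodal, mean 0.8),
  CHG Beta(0.3, 1.2), CHH Beta(0.2, 1.8) (mostly low).
* **Background divergence**: site $H^D$ Weibull with $\alpha = 1$,
  $\lambda = 0.3$, $\mu = 0.01$ — the shape/scale used in the calling
  examples.
* **Signal**: 100 spiked sites at divergence $\mu + 5\lambda$, whose null
  tail mass is $e^{-5} \approx 0.0067$.

`simulate_pair()` inverts the squared Hellinger divergence in closed form
(Bhattacharyya angle: $H^D = 2 - 2\cos(\theta_p - \theta_q)$ with
$\theta = \arcsin\sqrt{p}$) to place the query level at the drawn divergence
from the observed reference level; draws unattainable from a given reference
level are redrawn (capped, counted). Spiked sites are placed where the
reference level can attain the effect. Query counts are the rounded product
of level and coverage rather than a binomial draw: a binomial draw would
convolve the background law with sampling noise and the observed divergences
would no longer follow the stated Weibull. The price is quantization of
order $1/(2\,\text{coverage})$, visible as a slight thickening of the fitted
null.

The simulator targets *statistical structure*, not biology: no
autocorrelation of methylation along the chromosome, no context-specific
spatial patterning, no strand symmetry, no real annotation. A green test
therefore establishes that the estimators recover the laws they assume, at
realistic sample sizes — not that real methylomes obey those laws.

## Coordinates, formats, degenerate inputs

Internal coordinates are 1-based closed; BED output converts to 0-based
half-open. Strands are never merged (symmetric CG sites are two sites).
Contexts are pooled by default with an optional filter. Zero-coverage sites
are missing, not level-0. Terminal partial tiles are kept but flagged, and
excluded from distribution fits. Empty inputs (empty count table, empty
tile, empty PWF set) return empty results or warnings, not errors; invariant
violations (counts exceeding totals, duplicate site keys, malformed fields)
error with the offending line number.

## Known limitations

* The pipeline's persistence stage needs at least three converged tile-size
  fits; with the default four tile sizes a noisy pair can drop below that
  and the stage logs a skip. More fundamentally, the simulator's background
  divergences are i.i.d. across sites and encode no polymer mechanics, so a
  persistence length estimated from a *simulated* pair's tile trend is a
  smoke test of the plumbing, not a physical quantity (it is flagged
  invalid whenever the implied length is not positive). The estimators'
  correctness is established by the forward-model round trips
  (`simulate_lambda_trend()`), which do encode the two regression laws.
* DIMP false-call calibration is tested to a factor-of-two band around
  $\alpha$ at $n = 10^4$ sites; exact calibration would require the null to
  be fitted on divergences free of count quantization.
* The binary language analysis assumes the pooled binarization rule
  (any positive level anywhere = 1); with a very small number of samples the
  1-density is low and words fragment — the bias shrinks as methylomes are
  added, which the package does not correct for.
* Real-data headline quantities (persistence lengths of 39–67 nm on
  public Arabidopsis/human methylomes, promoter enrichment of words) require
  external data and are out of scope for the test suite.
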