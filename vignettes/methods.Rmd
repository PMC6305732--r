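---
title: "Methods: discriminant classification, distribution-shift scoring and kernel PLS for FOCM/TS metabolite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant classification, distribution-shift scoring and kernel PLS for FOCM/TS metabolite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

`focmshift` analyzes targeted plasma metabolomics panels covering two
linked pathways: folate-dependent one-carbon metabolism (FOCM — the
methylation arm: methionine, SAM, SAH, the SAM/SAH ratio, homocysteine,
adenosine) and transsulfuration (TS — the glutathione/redox arm: cysteine,
Glu-Cys, Cys-Gly, total and free reduced glutathione, GSSG, the two
GSH/GSSG ratios, and percent oxidized glutathione). Abnormalities in these
pathways have been repeatedly associated with autism spectrum disorder
(ASD), and several clinical treatments (methylcobalamin with folinic acid,
tetrahydrobiopterin, high-dose folinic acid) aim to correct them.

The package answers three questions with one connected toolchain:

1. **Classification** — how well does a small subset of the 15 measures
   separate an ASD cohort from typically developing (TD) controls?
2. **Treatment shift** — how far does a treatment move a cohort's
   metabolic profile *toward* the TD reference distribution?
3. **Behavior regression** — do changes in the metabolite panel predict
   changes in adaptive behavior (the Vineland Adaptive Behavior Scales
   Composite)?

Because the clinical cohorts this methodology was developed on are not
publicly deposited, the package ships a seeded synthetic-cohort generator
with the same tabular structure and the statistical features the analysis
relies on; every pipeline stage is exercised end-to-end on synthetic
studies.

## Fisher discriminant analysis

For a normalized sample-by-measure matrix split into cohorts, the
between-class scatter is

$$S_B = n_{A}(\bar x_A - \bar x)^T(\bar x_A - \bar x)
      + n_{T}(\bar x_T - \bar x)^T(\bar x_T - \bar x),$$

and the within-class scatter is the class-size-weighted sum of outer
products

$$S_W = n_A \sum_{i \in A}(x_i-\bar x_A)^T(x_i-\bar x_A)
      + n_T \sum_{i \in T}(x_i-\bar x_T)^T(x_i-\bar x_T).$$

Note the $n_A$, $n_T$ prefactors: this weighted form differs from the
textbook pooled within-class scatter. It is used deliberately and
consistently everywhere in the package, including in the closed-form
two-class solution $w \propto S_W^{-1}(\bar x_A - \bar x_T)$ that the test
suite uses as an independent oracle. (The prefactors change $S_W$ itself
— it is *not* a scalar multiple of the pooled form — so oracle and
implementation must, and do, agree on the same definition.)

The discriminant direction maximizes $J(w) = w^T S_B w / w^T S_W w$, i.e.
the leading eigenvector of $S_W^{-1} S_B$. Numerically we never form that
product: $S_W$ is regularized with a ridge $\varepsilon I$,
$\varepsilon = 10^{-8}\,\mathrm{tr}(S_W)/m$ (exhaustive subset search
visits nearly collinear panels), Cholesky-whitened, and the equivalent
symmetric eigenproblem is solved. The returned $w$ has unit Euclidean
norm and is oriented so the mean ASD score exceeds the mean TD score —
ASD on the positive axis. Neither the norm nor the sign convention is
forced by the mathematics; fixing them makes every downstream quantity
(thresholds, Type II errors, effect-size signs) well-defined.

Normalization is always *train/apply*: z-score parameters (sample
standard deviation, $n-1$) are estimated on the training cohort and
frozen into the model; validation and trial samples are transformed with
those frozen parameters, never their own moments.

Subset selection is exhaustive: every $\binom{m}{k}$ subset is fitted and
ranked by the C-statistic (rank-based AUC, ties counted one half) of the
*fitted* scores; cross-validation is then applied only to the chosen
model. This mirrors the two-stage practice the method comes from; the
fitted criterion is optimistically biased, which is why the package
reports leave-one-out confusion metrics for the final model. Degenerate
subsets are scored 0.5 and flagged rather than dropped, keeping the sweep
total over all subsets.

## Score densities and the balanced-error threshold

Discriminant scores of each cohort are smoothed with a Gaussian kernel
density estimate: one equal-weight kernel per reference score. The
bandwidth is Silverman's rule of thumb,
$h = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\,n^{-1/5}$, the standard
univariate default; it is recorded in every report so a reader can audit
what was smoothed and how. (Least-squares cross-validated bandwidths
could be substituted by passing `bandwidth` explicitly.)

Densities are tabulated on a fixed grid of 2048 equally spaced points
spanning the pooled score range extended by four bandwidths on each side,
and renormalized to unit trapezoidal mass — this removes edge truncation
and makes every probability mass a deterministic function of the grid.
Under the null hypothesis "the participant is TD", the Type I error at a
threshold $\theta$ is the TD mass above $\theta$, and the Type II error is
the ASD mass below it. The threshold $H_0$ is placed at the grid point
minimizing $|{\rm TypeI}(\theta) - {\rm TypeII}(\theta)|$; because the two
error curves are monotone in opposite directions the minimizer is
essentially unique, and tied grid points are resolved deterministically
(median tied index, lower-middle for even counts). At the 2048-point
resolution the achieved balance gap is at most about one grid cell of
probability mass (~$10^{-3}$); tests assert balance at $5\times10^{-3}$.

## Treatment shift as a change in Type II error

A frozen case-control model (direction, normalization and $H_0$) is
applied to a trial cohort's paired pre- and post-treatment panels.
Separate KDEs of the pre- and post-treatment score sets give
${\rm TypeII}_{\rm pre}$ and ${\rm TypeII}_{\rm post}$ — the mass of each
density on the TD side of the frozen threshold. The difference is the
shift metric: an *increase* in Type II error means the treated cohort has
become harder to distinguish from the TD reference, the desired outcome.

The effect size is the median paired pre-to-post change in discriminant
score, signed so that movement toward TD is positive (under the
ASD-positive orientation that is $\mathrm{median}(t_{\rm pre} -
t_{\rm post})$; the raw signed median is also carried in the report).
Its 95% confidence interval is the 0.025/0.975 percentile interval of
10,000 bootstrap replications resampling *participants* (paired rows,
never individual scores), from a single seeded generator recorded in the
report. The paired differences are sorted before resampling so the report
is invariant to participant ordering.

## Kernel partial least squares regression

Pre-to-post changes in a metabolite subset predict the change in VABS
Composite. The regression is dual-form kernel PLS with a Gaussian kernel
$K_{ij} = \exp(-\|x_i - x_j\|^2 / 2\sigma^2)$: the training kernel is
double-centered, and latent components are extracted one at a time as
directions of maximal covariance between the centered kernel and the
residual response, deflating both between components; the model is a
vector of dual coefficients, one per training sample. With a linear
kernel and full components this reduces exactly to ordinary least
squares, which the test suite exploits as an oracle; the linear kernel is
retained for that purpose only.

Two hyperparameters are not dictated by the methodology and are fixed by
deterministic defaults:

* **kernel width** — the median pairwise Euclidean distance among the
  z-scored training change-vectors (scale-adaptive, deterministic,
  recorded per fit);
* **number of components** — selected by an inner leave-one-out sweep
  over $1..\min(10, n-2)$ on the training set of the first outer fold,
  then held fixed (full nested selection is available by passing
  `components = NULL` to each fit, at quadratic cost).

Model assessment is leave-one-out cross-validation with the
normalization and kernel width refit inside every fold, so no information
from a held-out sample leaks into its own prediction:
$R^2 = 1 - \sum_i (y_i - \hat y_{-i})^2 / \sum_i (y_i - \bar y)^2$, which
can be negative. Fitted $R^2$ is always at least the cross-validated
$R^2$ in practice; the package's tests assert this optimism ordering.

## The synthetic-cohort generator

The generator emulates the structure the analysis needs, not the biology:

* **Raw concentrations** for the 11 measured metabolites are multivariate
  log-normal (non-negative, right-skewed), with a block correlation
  structure (correlation 0.3 within the methylation and thiol blocks, 0.1
  across, 0.75 between total and free glutathione) validated positive
  definite at configuration time. The inter-metabolite covariance of the
  real pathways is unknowable from published summaries; these values are
  fabricated and documented as such.
* **Ratios are derived, never sampled**, so every generated table
  satisfies the panel's algebraic invariants exactly (e.g.
  `pct_oxidized` $= 2\,\mathrm{GSSG}/(\mathrm{tGSH}+2\,\mathrm{GSSG})$).
* **Cohort separation**: the ASD log-mean offsets are concentrated in the
  redox measures (GSSG +1.6 within-cohort SD, total/free glutathione
  −0.7 SD) with smaller methylation offsets (methionine −0.5 SD), so that
  variable-importance code has a known answer to find. With the default
  sizes (92 ASD / 82 TD) the best five-measure discriminant model lands
  at a fitted C-statistic near 0.95 and leave-one-out sensitivity and
  specificity in the high-80s — the regime these methods are typically
  reported in, chosen once when the defaults were frozen.
* **Treatment** moves each participant's log-concentrations a configured
  fraction of the ASD-to-TD mean difference (defaults 0.8, 0.7, 0.3, 0.1
  for the four arms sized 33, 8, 14, 19), plus log-scale participant
  noise (SD 0.08).
* **Behavior link**: the change in VABS Composite is a linear combination
  of standardized metabolite changes (defaults over tGSH, GSSG and
  methionine) plus Gaussian noise. The noise draw is orthogonalized
  against the planted signal and rescaled so the link explains *exactly*
  the configured fraction `link_r2` (default 0.5) of the realized
  response variance — not merely in expectation — which makes parameter-
  recovery tests meaningful at trial-sized $n$. An optional quadratic
  term bends the link for nonlinearity studies.

What the generator does **not** emulate: assay noise structure, age/sex
covariates, missing-data mechanisms, integer-valued behavior scores, or
any real inter-cohort covariance differences. Passing tests on synthetic
studies therefore demonstrate the *correctness of the computations and
the recoverability of planted structure*, not clinical performance on
real cohorts.

All randomness flows from one integer seed per configuration; arm-level
seeds are derived deterministically from it, so individual arms are
reproducible in isolation.

## Numerical choices and degenerate inputs

* Constant training columns cannot be z-scored and raise an error naming
  the measure; incomplete rows are excluded at load time with a logged
  count.
* Derived-ratio columns present in input files are validated against
  recomputation (relative tolerance $10^{-6}$) and conflicts are
  rejected, preventing silent raw/derived inconsistency. Each derived
  measure checks only its own denominators, so a fully reduced
  glutathione pool (GSSG $= 0$) still yields `pct_oxidized` $= 0$ while
  the GSH/GSSG ratios correctly refuse to divide by zero.
* Two-time-point panels are averaged on the raw concentrations and the
  ratios re-derived from the averages; averaging the ratio columns
  directly would break the panel's algebraic invariants.
* Within-class scatter singular beyond the ridge is an error in a direct
  fit but scores 0.5 (flagged) inside the exhaustive sweep.
* Cross-validated confusion matrices refit the model, both densities and
  the threshold on every fold.
* The pipeline's frequency analysis caps the C-statistic cutoff at the
  best observed value so the report is never empty on data where the
  requested cutoff is unattainable; the applied threshold is recorded.

## Problem sizes

The test suite and the acceptance workflow run the generator at the
default study sizes (174 case-control participants, 74 pooled trial
participants), the full 3003-subset five-variable discriminant sweep, and
10,000-replication bootstraps; simulation-heavy property checks (null
coverage, noise-floor and recovery studies) use 100–200 replicate
studies with smaller per-study model configurations, sizes chosen to
estimate each property's rate with a few percent of Monte-Carlo error.

## Known limitations

* The balanced-error threshold is grid-quantized; sub-grid placement
  would require root-finding on the exact mixture CDFs (the exact-mixture
  computation exists in the test oracles but is not the shipped path).
* The fitted-C-statistic selection criterion is optimistically biased by
  design fidelity; the package surfaces cross-validated metrics alongside
  it rather than changing the selection rule.
* Component selection for kernel PLS on the first outer fold only is a
  cost compromise; fully nested selection is available but quadratic.
* The paper-regime clinical numbers (C-statistic 0.967, sensitivity 88%,
  cross-validated $R^2$ 0.471) depend on non-public data; nothing in this
  package claims to reproduce them, and the synthetic defaults are tuned
  only to land in a comparable regime so report formats are realistic.
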