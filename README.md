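# focmshift

Multivariate analysis of plasma metabolite panels spanning the
folate-dependent one-carbon metabolism (FOCM) and transsulfuration (TS)
pathways — the 15-measure panel (methionine, SAM, SAH, SAM/SAH,
homocysteine, adenosine, cysteine, Glu-Cys, Cys-Gly, tGSH, fGSH, GSSG,
tGSH/GSSG, fGSH/GSSG, percent oxidized glutathione) used in case–control
and treatment studies of autism spectrum disorder. The package is for
researchers who want to:

1. **classify** ASD vs typically developing (TD) cohorts with two-class
   Fisher discriminant analysis (FDA) over exhaustively searched measure
   subsets, ranked by the C-statistic;
2. **score treatments** by how far they shift a cohort's discriminant-score
   density toward the TD reference — measured as the change in Type II
   error against a frozen balanced-error threshold, with paired bootstrap
   effect sizes;
3. **predict behavior change** (Vineland Adaptive Behavior Composite) from
   metabolite changes with Gaussian-kernel partial least squares (KPLS)
   regression under leave-one-out cross-validation.

At its core: the discriminant direction **w** maximizes
J(w) = wᵀS_B w / wᵀS_W w, with S_B the between-class scatter and S_W the
class-size-weighted within-class scatter; scores tᵢ = xᵢ·w are smoothed
with Gaussian KDEs, and the null-hypothesis threshold H₀ ("participant is
TD") sits where Type I and Type II errors balance. Treatment shift is
ΔTypeII = TypeII_post − TypeII_pre at the frozen H₀ — here an *increase*
is the desirable outcome. The regression is dual-form KPLS,
K_ij = exp(−‖xᵢ−xⱼ‖²/2σ²), assessed by cross-validated
R² = 1 − Σ(yᵢ−ŷ₋ᵢ)²/Σ(yᵢ−ȳ)².

Because the clinical data behind this methodology are not publicly
deposited, the package includes a seeded synthetic-study generator
(log-normal concentrations, derived ratios, configurable cohort
separation, treatment shifts and a planted metabolite–behavior link) so
the whole pipeline runs end-to-end reproducibly.

## Worked example

```r
library(focmshift)

cfg   <- cohort_config(seed = 7)      # synthetic study: 92 ASD / 82 TD,
study <- generate_study(cfg)          # four arms n = 33, 8, 14, 19

# exhaustive 5-measure discriminant search (3003 subsets)
search <- search_fda(study$case_control, 5)
head(dplyr::select(search, subset_id, value), 3)
#> # A tibble: 3 × 2
#>   subset_id                                      value
#>   <chr>                                          <dbl>
#> 1 sam+sah+cys_gly+tgsh+pct_oxidized              0.968
#> 2 sam_sah+homocysteine+cys_gly+gssg+pct_oxidized 0.968
#> 3 sam+sah+cys_gly+gssg+pct_oxidized              0.967

model <- fit_fda(study$case_control, search$subset[[1]])
pair  <- fit_kde_pair(model$t_td, model$t_asd)
thr   <- find_threshold(pair$td, pair$asd)
thr
#> Balanced-error score threshold
#>   H0 threshold = -0.1333
#>   Type I error  = 0.115 (TD mass above H0)
#>   Type II error = 0.115 (ASD mass below H0)
#>   bandwidths: TD 0.1589, ASD 0.2194

evaluate_shift(model, thr, study$trials$mecbl_ldfa, seed = 7)
#> Treatment shift report (mecbl_ldfa)
#>   n = 33 participants
#>   Type II error: pre 18.8% -> post 69.5% (change +50.8 points)
#>   effect size (median paired score change toward TD): 1.043
#>   95% CI (0.953, 1.145), 10000 bootstrap reps, seed 7

deltas <- dplyr::bind_rows(lapply(study$trials, delta_table))
loo_kpls(deltas, c("methionine", "tgsh", "gssg"), components = 3)
#> Leave-one-out cross-validated kernel PLS
#>   predictors: methionine, tgsh, gssg
#>   components = 3, kernel = gaussian
#>   cross-validated R^2 = 0.365
```

Reading the output: the best five-measure subset separates the synthetic
cohorts with a fitted C-statistic of 0.968 (0.5 = chance, 1 = perfect);
the balanced threshold misclassifies 11.5% of each reference cohort. The
treatment arm's Type II error rises by 50.8 percentage points — half the
treated cohort's score density moved across the threshold to the TD side
— with a paired effect size of 1.04 score units (95% CI 0.95–1.15,
excluding zero). Changes in three metabolites predict the change in
adaptive behavior with a cross-validated R² of 0.365 against a planted
link explaining 0.5 of response variance.

One call chains every stage (search → fit → cross-validate → threshold →
per-arm shifts → pooled regression) and writes plot-ready CSV/JSON
reports plus a run manifest:

```r
report <- run_full_study(cohort_config(seed = 7), out_dir = "study_out")
```

`tidy()`/`glance()` methods expose models as tibbles, `autoplot()`
methods draw the score densities, frequency bars and
observed-vs-predicted scatter, and user data enter as CSV files via
`read_cohort_csv()` / `read_trial_csv()` (see `?focm_measures` for the
column contract). A thin command-line wrapper lives at
`inst/scripts/run_study.R`.

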