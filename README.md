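# bfcat

Multidimensional computerized adaptive testing (MCAT) for ordinal
patient-reported outcome questionnaires under a **bifactor graded response
model** (GRM). The package targets the common situation in
health-related-quality-of-life (HRQOL) measurement where a fixed-length
multi-domain instrument (such as a 44–54-item HRQOL inventory) is to be
turned into an adaptive short form: it calibrates the item bank, screens it
for locally dependent item pairs, simulates adaptive administrations under a
factorial set of stopping rules, and reports how much of the instrument can
be saved at what cost in precision.

## The model and the adaptive loop

Each of `J` items loads on a general factor `θ₀` and on at most one of `G`
group factors `θ_g`, all mutually uncorrelated (the bifactor constraint).
For an item with `K` ordered categories, slopes `a = (a_gen, a_grp)` and
strictly decreasing intercepts `d_1 > … > d_{K−1}`, the boundary
probabilities are

    P*_k(θ) = logistic(a_gen θ₀ + a_grp θ_g + d_k),   k = 1 … K−1,

with category probabilities `P_k = P*_k − P*_{k+1}`. Calibration is
full-information marginal maximum likelihood via Bock–Aitkin EM; the
bifactor structure reduces the `G+1`-dimensional integral to nested
two-dimensional quadratures, so a 10-group bank is as tractable as a
two-group one. Missing responses simply drop out of the likelihood (FIML).

The adaptive engine scores respondents by the multidimensional **MAP**
estimator under an MVN(0, I) prior, selects the next item by the
**determinant rule** (maximize `det` of the posterior information matrix
after hypothetically adding each candidate), and stops on any combination
of three criteria: general-factor SE threshold, group-factor SE threshold,
and a minimal change in the trait estimates between consecutive items.
Performance against the known simulation truths is reported as RMSD
`√(Σ(θ̂−θ)²/N)`, Pearson correlation, and item reduction
`100·(1 − mean items / bank size)`.

Local dependence is screened with **Yen's Q3** (correlations of
observed-minus-expected residuals at the full-pattern MAP estimate); in each
flagged pair the member with the lower prior-integrated information is
removed, walking pairs in descending Q3 order.

## Worked example

```r
library(bfcat)

bank <- generate_item_bank(bank_spec(), seed = 1)   # 44-item synthetic bank
bank
#> Bifactor item bank: 44 items, 10 group factor(s), D = 11
#>   categories 2-6; a_general in [0.97, 4.68]; a_group in [0.67, 5.01]

select_next_item(posterior_state(bank), bank)       # shared starting item
#> [1] "item33"

thetas    <- generate_thetas(200, bank$D, seed = 2)
responses <- simulate_responses(thetas, bank, seed = 3)
runs <- run_design(table3_design()[c("full", "sim3", "sim7")],
                   bank, responses)
summ <- summarize_simulation(runs, thetas, reference = "full")
summ[, c("design", "median_items", "item_reduction",
         "se_general_mean", "cor_general", "rmsd_general")]
#>   design median_items item_reduction se_general_mean cor_general rmsd_general
#> 1   full           44            0.0           0.227       0.977        0.231
#> 2   sim3           16           62.6           0.305       0.948        0.343
#> 3   sim7            9           78.1           0.383       0.920        0.422
```

Reading the table: the no-termination `full` row administers all 44 items
adaptively and sets the precision ceiling (general-factor correlation 0.98
with the simulated truth). Stopping once the general-factor SE drops below
0.32 (`sim3`, implied reliability 0.90) cuts the median administration to 16
items — a 63% reduction — while the correlation stays near 0.95; relaxing
to 0.40 (`sim7`, reliability 0.84) nearly halves it again at a visible cost
in RMSD. Calibrating a bank from raw responses is one call:
`fit <- bfgrm(responses, structure)`, with `coef()`, `predict()` (MAP
scores), `simulate()` and `residuals()` methods, and
`screen_local_dependence(q3_matrix(responses, fit$bank), fit$bank)` for the
Q3 screen.

A command-line wrapper for the whole study lives in
`inst/scripts/run_mcat_study.R`.

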