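# bphmm

Discovering shared behavioral states in ensembles of time-stamped software
activity logs with a sticky, discrete-emission **Beta-Process hidden Markov
model (BP-HMM)**.

## The problem

Instrumented software emits, per session, a time-stamped sequence of
activity codes — for the tile-game interface this package's defaults
emulate, the codes are `Sel` (select), `S` (swap, the scoring move), `R`
(reswap, a failed move) and `W` (wiggle, a drag gesture disabled in the
"static" interface condition). Analysts studying exploration, skill
acquisition and strategy want a small library of *behavioral states*
shared across all users, plus per-user descriptions: which states each
user visited, for how long, and how they moved between them.

The BP-HMM models every session as its own HMM whose states are drawn from
a global pool. A binary feature matrix `F` (sessions × states), governed
by a beta-process / Indian-buffet-process prior with mass γ and
concentration β, records which states each session uses; state *k* emits
symbols from a categorical distribution θ<sub>k</sub> ~ Dir(λ₀, …, λ₀)
over an alphabet that jointly encodes activity and tempo; each session's
transition matrix over its active states comes from sticky weights
η<sub>jk</sub> ~ Gamma(α + κ·δ(j,k), 1), normalized — extra mass κ on
self-transitions favors temporally persistent states. Inference is MCMC:
Metropolis–Hastings feature flips and birth/death moves with
forward-marginalized likelihoods, forward-filter backward-sampling of
hidden paths, and conjugate Dirichlet updates for emissions and
transitions.

Around the model sits the full pipeline: log reading and validation, a
50 ms recode collapsing select-then-act pairs, per-activity K-means
quantization of inter-event times (15 centroids × 4 activities = 60
symbols by default), a hyperparameter grid runner, representative-model
selection by K-means consensus, and derivative metrics — peaked/diffuse
state classification by excess kurtosis against the uniform benchmark
−1.2, time-in-state occupancy, peaked-time fractions, transition-category
statistics and a success heuristic. A synthetic-log generator makes every
stage testable end to end.

## Worked example

Simulate a small ensemble (3 wiggle-interface and 3 static subjects),
preprocess, quantize, fit, and classify:

```r
library(bphmm)

truth <- ground_truth(n_subjects = 6, sessions_per_subject = 1)
sim <- simulate_ensemble(truth, seed = 42, n_events = 300)

events   <- recode_selections(sim$events) |> compute_intervals()
codebook <- fit_codebook(events, k = 8, seed = 42)
encoded  <- encode_symbols(events, codebook)

fit <- run_mcmc(encoded, bp_hyperparams(),
                bp_mcmc_config(n_iterations = 500, seed = 42))
glance(fit)
#> # A tibble: 1 × 11
#>   n_sequences n_states alphabet_size log_lik iterations  seed gamma  beta kappa
#>         <int>    <int>         <int>   <dbl>      <int> <int> <dbl> <dbl> <dbl>
#> 1           6        5            32  -4673.        500    42     3     1   200
```

Six sessions were jointly modeled with 5 shared states over the 32-symbol
alphabet (8 tempo centroids × 4 activities). Classify states by the shape
of their activity profiles and measure how much session time each subject
spent in peaked states:

```r
cls <- classify_states(fit, codebook)
cls
#> # A tibble: 5 × 5
#>   state method   statistic threshold label
#>   <int> <chr>        <dbl>     <dbl> <chr>
#> 1     1 kurtosis     3.17       -1.2 peaked
#> 2     2 kurtosis     3.64       -1.2 peaked
#> 3     3 kurtosis    -1.43       -1.2 diffuse
#> 4     4 kurtosis     0.530      -1.2 peaked
#> 5     5 kurtosis     3.51       -1.2 peaked

occ <- state_occupancy(fit, encoded)
session_peakedness(occ, cls$state[cls$label == "peaked"])
#> # A tibble: 6 × 6
#>   session_id subject_id interface instruction peaked_fraction diffuse_fraction
#>   <chr>      <chr>      <chr>     <chr>                 <dbl>            <dbl>
#> 1 p01_s1     p01        wiggle    hint                  0.803            0.197
#> 2 p02_s1     p02        wiggle    none                  0.746            0.254
#> 3 p03_s1     p03        wiggle    hint                  0.814            0.186
#> 4 p04_s1     p04        static    none                  0.232            0.768
#> 5 p05_s1     p05        static    hint                  0.216            0.784
#> 6 p06_s1     p06        static    none                  0.185            0.815
```

States with excess kurtosis above −1.2 are *peaked* (a strong bias toward
specific activities, here the wiggle-dominated and reswap-dominated
modes); states below it are *diffuse* (integrated use of the interface).
The peaked-time fractions separate the two interface conditions cleanly:
wiggle-interface subjects spend ~75–81% of session time in peaked states,
static subjects ~19–23%.

Other entry points: `run_grid()` fits the standard 4×3×4 hyperparameter
grid; `select_representatives()` reduces a grid to one model per state
count; `activation_map()` + `autoplot()` draw the ordered feature
activation map; `run_pipeline()` chains every stage and writes all
artifacts; `load_fixture()` returns the packaged reference tables. A thin
CLI (`exec/bphmm`) exposes `simulate` and `pipeline` subcommands.

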