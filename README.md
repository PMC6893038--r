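# soundloc

Simulation and analysis of virtual sound-localization training studies.

## The problem

Virtual audio systems place sounds in 3D space by filtering them with
head-related transfer functions (HRTFs). Consumer systems use *generic*
HRTFs measured on someone else's head, so naive listeners mislocalize
virtual sources in characteristic ways: they confuse front and rear (the
cone of confusion), hear sources lower than they are, and push responses
too far toward the sides. Short bouts of training with visual positional
feedback shrink these errors within hours, and quantifying *how fast*, *by
how much*, and *whether the gains transfer to an HRTF set that was never
trained* is the core analysis problem this package addresses.

`soundloc` is for researchers designing or analysing such experiments. It
provides the complete measurement and analysis chain, plus a protocol
simulator driven by a parametric virtual listener, so every stage of the
pipeline can be exercised, power-checked and regression-tested without
human data.

## What it computes

Directions are handled in two spherical systems: single-pole
azimuth/elevation (θ, φ) and the auditory interaural-polar system with a
lateral angle λ off the median plane and a polar angle ρ around the
interaural axis. Four error measures are computed per trial, with the
standard eligibility gates:

- **spherical angle error** — the great-circle angle between target and
  response;
- **lateral error** — |λ(response) − λ(target)|;
- **polar angle error (PAE)** — |Δρ| wrapped to the shortest arc and scaled
  by cos λ(target), for non-confused trials only;
- **front–back confusion rate** — the percentage of responses in the wrong
  front/rear hemisphere, among trials whose target lies within 65° of the
  median plane;

plus signed variants (lateral overshoot, elevation bias, signed front–back
asymmetry). Group learning curves are summarised by bounded least-squares
fits of

```
error(x) = a exp(−b x) + c
```

against completed training blocks `x`, with adjusted R², the mean initial
error `ā + c̄`, the asymptote `c̄`, and the learning half-life `ln 2 / b̄`
(in blocks and in minutes of training). Group inference mirrors standard
practice: paired t-tests on per-participant medians, one-way ANCOVA on
final error with initial error as covariate and Tukey HSD post hoc
contrasts, Pearson correlation of stimulus exposure against improvement,
and pooled trained-vs-untrained HRTF contrasts.

The simulator reproduces the study design it models: 36 participants in
four groups (control n=9, non-gamified n=9, gamified n=7, active-gamified
n=11), three sessions on separate days with 12-minute training blocks (an
adaptive target-size staircase: −10% radius after three consecutive hits,
one step back after five misses at a size), and 48-trial testing blocks
(12 target regions × 4 jittered repeats, 3:1 trained:untrained HRTF).

## Worked example

```r
library(soundloc)
library(dplyr)

log <- simulate_study(seed = 1)       # full 3-day study, 36 virtual listeners
nrow(log)
#> [1] 26919

tests <- filter(log, block_type == "test")
sums  <- summarise_blocks(tests)      # per-participant x block medians

init <- filter(sums, block_index == 1)
round(c(fb   = mean(init$fb_rate, na.rm = TRUE),
        elev = mean(init$mean_signed_elevation),
        lat  = mean(init$mean_signed_lateral)), 1)
#>    fb  elev   lat
#>  41.9 -15.2   4.7
```

Before any training the simulated cohort confuses front and rear on ~42%
of eligible trials and hears sources ~15° below their true elevation, the
signature of listening through someone else's ears. Fitting the learning
curves:

```r
fits <- fit_group_curves(sums)
fits[setdiff(names(fits), "fit")]
#> # A tibble: 4 x 7
#>   group               a     b     c adj_r2 n_points converged
#>   <chr>           <dbl> <dbl> <dbl>  <dbl>    <int> <lgl>
#> 1 active_gamified  14.4 0.740  21.6  0.977        8 TRUE
#> 2 control           0   0      39.5 -0.75         8 TRUE
#> 3 gamified         15.7 0.227  21.0  0.970        8 TRUE
#> 4 non_gamified     11.6 0.308  24.1  0.941        8 TRUE

derived_summary(filter(fits, group != "control"))
#> # A tibble: 1 x 5
#>   initial_error final_error half_life_blocks half_life_minutes n_fits
#>           <dbl>       <dbl>            <dbl>             <dbl>  <int>
#> 1          36.2        22.3             1.63              19.6      3
```

The active-gamified group learns fastest (largest `b`), the control group's
flat series is rejected by the exponential (negative adjusted R²), and the
error halves in about a block and a half — twenty-ish minutes of training.
Applying the same summary to the published group-level fit parameters
shipped with the package:

```r
derived_summary(reference_fits())
#> # A tibble: 1 x 5
#>   initial_error final_error half_life_blocks half_life_minutes n_fits
#>           <dbl>       <dbl>            <dbl>             <dbl>  <int>
#> 1          43.4        25.5             1.60              19.2      3
```

`plot_learning_curves(sums, fits)`, `plot_signed_biases(sums)` and
`plot_error_by_sector(sector_summary(tests))` draw the standard figures;
`build_report(log)` assembles everything into one Markdown report. A thin
CLI over the same functions lives at `inst/cli/soundloc`
(`simulate | metrics | fitcurve | stats | report`).

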