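# crpcoord

Inter-joint coordination analysis for cyclic human movement, built around
**continuous relative phase (CRP)**. The package targets movement scientists
who quantify how a distal and a proximal joint (ankle–knee, knee–pelvis)
coordinate during a movement cycle — for example backward running in
handball defence — and who compare that coordination across groups and
training stages.

## What it computes

For each joint-angle series $x(t)$ the phase portrait is formed from the
amplitude-normalized angle and angular velocity,

$$x_{\mathrm{norm}} = \frac{2(x-\min x)}{\max x - \min x} - 1, \qquad
v_{\mathrm{norm}} = \frac{\dot x}{\max |\dot x|},$$

and the phase angle is
$\phi = \mathrm{atan2}(v_{\mathrm{norm}}, x_{\mathrm{norm}})$, unwrapped.
CRP of a coupling is $\theta = \phi_{\mathrm{distal}} - \phi_{\mathrm{proximal}}$
(an equivalent single-arctangent route is also implemented and agrees to
machine precision). Each curve is resampled onto the conventional 101-point
0–100% cycle grid, then reduced to

* $\mathrm{MARP} = \tfrac1N \sum_i |\theta_i|$ — low = in-phase, high =
  out-of-phase coordination;
* $\mathrm{DP} = \tfrac1N \sum_i \mathrm{SD}_i$ — mean across-cycle SD of
  CRP; low = stable coordination,

one value per subject, coupling, and stage. A gated parametric workflow
(Shapiro–Wilk and Levene checks; pooled/Welch independent t, paired t,
one-way ANOVA, pairwise post hoc t-tests; Cohen's d and $\eta^2$) compares
groups and stages. A synthetic cohort generator produces a full three-group,
two-stage study (7/7/14 subjects) with analytic MARP/DP ground truth, so the
entire chain is verifiable end to end. See
`vignettes/coordination-analysis.Rmd` for the methods account.

## Worked example

```r
library(crpcoord)

# a simulated cycle whose ankle lags the knee by 45 deg
trial <- simulate_joint_cycle(c("ankle-knee" = 45, "knee-pelvis" = 30))
curve <- crp_curve(trial, c("ankle", "knee"))
marp(curve)
#> [1] 45.00004

# deviation phase across two constant replicate curves at 0 and 10 deg
deviation_phase(list(rep(0, 101), rep(10, 101)))
#> [1] 7.071068

# audit a published-style t-test from printed summaries alone:
# groups 1.79 +/- 0.55 and 1.62 +/- 0.46, n = 7 each
summary_stat_t(1.79, 0.55, 7, 1.62, 0.46, 7)[, c("statistic", "df1", "p_value", "effect")]
#> # A tibble: 1 × 4
#>   statistic   df1 p_value effect
#>       <dbl> <dbl>   <dbl>  <dbl>
#> 1     0.627    12   0.542  0.335
```

The study-scale workflow lives in `analysis/` as numbered drivers
(simulate → CRP/metrics → statistics → audit → figures), writing under
`results/`. Running them in order prints, among other things, the key
baseline and training comparisons for ankle–knee MARP:

```
baseline novice t (control vs test):   t(12) =  -0.71, p = 0.492, cohen_d = -0.38
baseline 3-group ANOVA:                F(2,25) =  15.20, p = 0.000, eta_squared = 0.55
  post hoc control vs target:          t(19) =  -4.20, p = 0.000, cohen_d = -1.94
  post hoc test vs target:             t(19) =  -4.00, p = 0.001, cohen_d = -1.85
paired pre/post, control:              t(6) =   2.69, p = 0.036, cohen_dz = 1.02
paired pre/post, test:                 t(6) =   3.55, p = 0.012, cohen_dz = 1.34
post-training 3-group ANOVA:           F(2,25) =   1.93, p = 0.165, eta_squared = 0.13
```

i.e. the two novice groups are indistinguishable at baseline, professionals
are separated from both, training raises novice ankle–knee MARP toward the
professional value, and the post-training group effect vanishes.

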