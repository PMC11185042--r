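# pursuitlink

Analysis of the interaction between saccades and smooth pursuit eye
movements in step-ramp (Rashbass) tracking tasks, for oculomotor and
behavioral-neuroscience labs working with 1 kHz gaze recordings.

When a primate tracks a moving target, pursuit velocity immediately after
the first catch-up saccade exceeds pursuit velocity immediately before it
(*post-saccadic enhancement*), and with two moving targets the
post-saccadic pursuit becomes selective for the target the saccade chose.
`pursuitlink` implements the full measurement chain for both effects and
pairs it with a synthetic step-ramp gaze simulator with known latent
parameters, so every estimator can be verified by parameter recovery.

The core quantities:

* **Eye velocity** from 1 kHz position: 25 ms median filter, then the mean
  of central differences at 25 and 50 Hz spans.
* **Peri-saccadic windows**: 30 ms velocity windows ending 25 ms before
  saccade onset and starting 25 ms after saccade offset (the buffer keeps
  pupil-tracker edge artifacts out), a 30 ms fixation window, and a 10 ms
  post-saccadic position window. Trials are retained only if the saccade
  latency exceeds pursuit latency + 55 ms and both window speeds exceed
  0.5 deg/s.
* **Pursuit latency** per condition by bootstrapped threshold-linear
  fitting of the trial-averaged position trace,
  `e_p(t) = g·max(t − l, 0) + c`, with 1000 resamples.
* **Selection weights** solving `w·T1 + (1 − w)·T2 = E` for saccade
  endpoints and pre-/post-saccadic pursuit velocities, the regression
  `y = m·x + c` of pursuit weight on saccade weight, and the **choice
  probability** (ROC area separating pursuit weights by saccade choice)
  with 1000-resample bootstrap CIs.

## Worked example

Simulate a two-target session (two single-target reference conditions plus
a 0/90 deg two-target pairing at 5 deg/s, 150 trials each) and run the
selection analysis:

```r
library(pursuitlink)

cfg <- run_config(
  conditions = list(
    trial_condition(1, speed = 5, direction = 0,        step_size = 1),
    trial_condition(1, speed = 5, direction = 90,       step_size = 1),
    trial_condition(2, speed = 5, direction = c(0, 90), step_size = 1)),
  n_per_condition = 150,
  params  = eye_model_params(),   # gains 0.4 -> 0.8, coupling 0.7
  seed    = 42, latency_B = 1000, cp_B = 1000)

rep2 <- run_two_target_analysis(cfg)
rep2$latency
#> # A tibble: 2 x 7
#>   condition_id latency_ms n_traces     B  q025  q500  q975
#>   <chr>             <dbl>    <int> <dbl> <dbl> <dbl> <dbl>
#> 1 c01                188.      147  1000  178.  188.  193
#> 2 c02                186.      148  1000  162.  191.  196.
rep2$table2
#> # A tibble: 2 x 10
#>   condition_id directions     n epoch slope intercept choice_probability
#>   <chr>        <chr>      <int> <chr> <dbl>     <dbl>              <dbl>
#> 1 c03          0/90         129 pre   0.309    0.328               0.721
#> 2 c03          0/90         129 post  0.954    0.0202              1
#> # i 3 more variables: cp_ci_low <dbl>, cp_ci_high <dbl>, r_squared <dbl>
```

Reading the output: the bootstrapped pursuit latencies recover the
simulator's 190 ms ground truth within a few ms. In the weight table, the
pre-saccadic pursuit weight relates weakly to the saccade weight (slope
0.31, choice probability 0.72 — some selection information is present
before the saccade), while the post-saccadic weight follows the saccade
choice almost perfectly (slope 0.95, choice probability 1.0): pursuit
becomes selective for the saccade's target after the saccade.

`run_single_target_analysis()` produces the single-target velocity table
(fixation / pre- / post-saccadic means with t tests), the time-binned
pre/post comparison, and regressions of the velocity increase on saccade
duration and amplitude. A thin command-line wrapper is included:

```sh
Rscript inst/cli/pursuitlink.R full-run \
  --config inst/extdata/example-config.yaml --out out/
```

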