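# vrgait — spatiotemporal gait analysis from VR foot trackers

Consumer virtual-reality trackers (HTC VIVE class, Lighthouse laser-sweep
positioning) report world-frame position and orientation directly, at ~90 Hz.
Strapped to the instep of each shoe, they provide drift-free foot
trajectories at a fraction of the cost of camera systems or instrumented
walkways — an attractive platform for indoor gait analysis in clinics and
labs. `vrgait` is the analysis chain for that setup, for movement scientists
and rehabilitation researchers:

* **Events.** After zero-phase low-pass Butterworth filtering (3rd order,
  12 Hz) and linear detrending, the vertical foot trajectory traces a
  double-peaked excursion per swing: the first peak is toe off (TO), the
  second heel strike (HS). Peaks with ≥ 1 cm prominence, ≥ 100 ms apart,
  grouped per excursion, give the event sequence; HS→TO→HS triples form gait
  cycles.
* **Heel transform.** Features are defined at the heel; tracker pose maps to
  heel position via `heel = pos + R(q)·offset`, with the per-shoe-size offset
  measured statically and supplied by the user.
* **Features**, per stride i (2D, heel positions at event samples):
  - stride length `SL_i = ‖XY_HS(i) − XY_HS(i−1)‖`
  - stride time `ST_i = t_HS(i) − t_HS(i−1)`
  - stride width `SW_i = sqrt(d_i² − (SL_i/2)²)` (d_i: distance from the
    closing HS to the contralateral HS inside the cycle)
  - stride velocity `SV_i = SL_i / ST_i`
  - stance/swing percentages `STC% + SWC% = 100`
* **Validation.** Detected events are matched one-to-one to a reference
  stream (instrumented-walkway style) within a 33.3 ms window (3 samples at
  90 Hz); sensitivity `= 100·TP/(TP+FN)`; offsets are screened by a
  3.5 × scaled-MAD outlier rule, then summarized as mean ± SD, mean absolute
  error ± SD, RMSE, Pearson r and Bland–Altman limits of agreement
  (mean ± 1.96·SD).
* **Simulator.** A synthetic gait generator produces paired tracker +
  reference streams with analytic ground truth (configurable stride
  length/time/width, stance fraction, clearance peaks, sensor noise,
  independent sampling rates, known clock offset), so the whole chain is
  testable without hardware.

See `vignettes/gait-analysis-methods.Rmd` for the full methods account.

## Worked example

Simulate a 20-stride walk with 3 mm tracker noise, run the pipeline, and
validate it against the simulated reference stream:

```r
library(vrgait)

spec  <- synthetic_gait_spec(n_strides = 20, noise_sd_pos = 0.003, seed = 11)
trial <- simulate_trial(spec)
cfg   <- run_config()
res   <- run_gait_pipeline(trial$left, trial$right, cfg,
                           heel_offset_left  = spec$heel_offset,
                           heel_offset_right = spec$heel_offset)

head(res$features[, c("foot", "t_hs_cur", "SL_m", "ST_s", "SW_m", "SV_mps", "STC_pct")], 4)
#>    foot t_hs_cur     SL_m     ST_s       SW_m   SV_mps  STC_pct
#> 1 right 2.844444 1.251018 1.111111 0.09770867 1.125916 60.00000
#> 2  left 3.400000 1.252172 1.088889 0.10661962 1.149954 59.18367
#> 3 right 3.955556 1.251302 1.111111 0.08898607 1.126172 59.00000
#> 4  left 4.500000 1.249388 1.100000 0.10372409 1.135808 59.59596

validate_pipeline(res, trial$reference, trial$truth_features, cfg)
#> Validation report (matching window 33.3 ms)
#>   HS: sensitivity 100.0% (TP 40, FN 0, FP 0), mean offset -4.4 +/- 7.9 ms, mean |offset| 7.2 +/- 5.4 ms, outliers 0 (0.0%)
#>   TO: sensitivity 100.0% (TP 40, FN 0, FP 0), mean offset -2.8 +/- 4.7 ms, mean |offset| 4.7 +/- 2.7 ms, outliers 0 (0.0%)
#>   SL  [cm]: mean offset -0.01 +/- 0.23, MAE 0.17 +/- 0.14, RMSE 0.22, r NA, LoA [-0.46, 0.44] (n=38)
#>   ST  [ms]: mean offset -0.29 +/- 11.11, MAE 7.89 +/- 7.71, RMSE 10.96, r NA, LoA [-22.06, 21.48] (n=38)
#>   SW  [cm]: mean offset -0.06 +/- 1.21, MAE 0.94 +/- 0.74, RMSE 1.19, r NA, LoA [-2.42, 2.31] (n=38)
#>   SV  [cm/s]: mean offset 0.03 +/- 1.04, MAE 0.81 +/- 0.64, RMSE 1.03, r NA, LoA [-2.01, 2.07] (n=38)
#>   STC [%]: mean offset -0.02 +/- 0.65, MAE 0.50 +/- 0.40, RMSE 0.64, r NA, LoA [-1.29, 1.26] (n=38)
```

Reading it: every simulated gait event was recovered within the 33.3 ms
window (sensitivity 100%); event timing is accurate to a few ms (the 90 Hz
grid alone contributes ~3 ms); spatial features agree with ground truth to a
few mm and stride time to ~11 ms RMSE. Stride width is the least accurate
feature — it amplifies heel-position error through three sensor readings —
and the per-stride correlation is `NA` because simulated truth strides are
identical (zero variance). The 20 strides per foot yield 19 cycles each
(the first toe off has no preceding heel strike), and 38 strides enter the
feature comparison.

Real tracker logs enter through `read_tracker_log()` (CSV with columns
`t,x,y,z,qw,qx,qy,qz`), reference event tables through
`read_reference_events()` (CSV `kind,foot,t`), heel offsets through
`read_heel_offsets()` (see the template in `inst/extdata/`). A thin
command-line wrapper with `simulate`, `detect`, `features`, `all` and
`validate` subcommands lives at
`system.file("cli", "vrgait.R", package = "vrgait")`.

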