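# wristflow

Reconstitute and preprocess chunked wristband sensor data in R.

Research-grade wrist wearables such as the Empatica EmbracePlus record
electrodermal activity (EDA), blood volume pulse (BVP/PPG), peripheral skin
temperature, three-axis accelerometry, per-beat systolic-peak events and
button-press event tags continuously for days. The device does not deliver
one continuous file: raw signals arrive as Avro *chunk* files of at most
30 minutes each, timestamped in universal standard time and organised in a
`participant_data/YYYY-MM-DD/<subject>-<device>/` folder tree. Before any
analysis, those fragments must be discovered, sorted, concatenated, trimmed
to the period of interest, and reconciled with gaps — a chore every
wearables lab currently re-implements by hand.

`wristflow` is a headless toolkit for exactly that chore, plus the standard
preprocessing that follows. It is aimed at researchers in psychophysiology,
digital health and human-activity recognition who want scriptable, testable
pipelines rather than spreadsheet surgery.

## What it does

- **Read** chunk files in Avro (the device's native object-container
  format; reader and writer are built into the package) or the equivalent
  direct CSV conversion.
- **Reconstitute** per-modality timeseries over *default* windows (one per
  subject per local civil day) or *custom* wall-clock windows (e.g.
  09:30 to 10:30 + 24 h), with policies for overlapping windows
  (allow, or skip forward to the first non-overlapping start), NaN-padding
  of discontinuities, and NaN-extension to the full window length. Two
  chunks are treated as contiguous when the next start deviates from the
  previous end by at most half a sample period. Every window is half-open
  `[start, end)`.
- **Summarise missingness**: for each signal, the total duration, the
  expected number of points on the window's nominal grid
  (`floor((end - start) * fs / 1e6)`), and the percent missing.
- **Edit tags**: add (to the millisecond), delete, annotate; *apply* sorts
  tags into temporal order and relabels them densely `Tag 1..Tag n`;
  *reset* restores the tags as first loaded.
- **Preprocess**: resampling (linear/spline/pchip/makima, never across
  gaps); detrending — least-squares linear, iterative robust polynomial,
  and smoothness-priors detrending, which removes the trend
  `ẑ = (I + λ²D₂ᵀD₂)⁻¹ z` (D₂ the second-difference operator, λ the
  smoothness parameter, default 500); moving mean/median and zero-phase
  (forward–backward) Butterworth filters; sliding-window artifact detection
  by amplitude, z-score, variance, SD and slope thresholds with optional
  padding around detections; gap interpolation
  (previous/next/nearest/linear/spline/pchip/makima/moving statistics); and
  global or windowed z-scoring.
- **Epoch**: event-related, timepoint, sequential (e.g. twenty 30-s epochs
  forward from Tag 2) and A-to-B segmentation, sliced on the parent grid
  without resampling.
- **Export** each recording as a MAT-file (level 5) with `cfg` (read
  settings) and `dat` (per-segment tables of universal time, local time
  with UTC offset, and values; tags; missing-data summary), or as an XLSX
  workbook with one sheet per modality plus a tag sheet. Both reload
  losslessly.
- **Simulate**: a synthetic device generator produces multi-day,
  multi-subject chunked datasets — tonic EDA with phasic responses,
  pulsatile BVP with jittered beats and systolic-peak events, sinusoidal
  temperature, burst-modulated accelerometry, gaps, tags — so the entire
  pipeline runs and is tested without hardware.

## Worked example

Simulate a two-hour recording starting 08:00 Singapore time with a 15-min
dropout at the one-hour mark and three button presses, write it as Avro
chunks, and read back a custom 08:30–09:30 window:

```r
library(wristflow)

spec <- sim_spec(subjects = list(c("S001", "3YK31141P6")),
                 start = "2024-01-28 08:00:00", tz = "Asia/Singapore",
                 duration_h = 2, gaps = list(c(3600, 900)),
                 tag_times_s = c(1200, 2400, 4500), seed = 7)
rec   <- simulate_recording(spec)
root  <- tempfile()
files <- write_dataset(rec, root)   # 7 chunk files (one shortened by the gap)

cfg  <- read_config(root, timezone = "Asia/Singapore",
                    read_method = "custom", window = c("08:30", "09:30"),
                    pad_discontinuities = TRUE)
recs <- reconstitute(cfg)
recs[[1]]
#> <recording> S001-3YK31141P6
#>   window: 2024-01-28T08:30:00.000+08:00 -> 2024-01-28T09:30:00.000+08:00 (Asia/Singapore)
#>   EDA: 1 segment(s), 14400 sample(s) @ 4 Hz
#>   BVP: 1 segment(s), 230400 sample(s) @ 64 Hz
#>   Temp: 1 segment(s), 3600 sample(s) @ 1 Hz
#>   ACC: 1 segment(s), 230400 sample(s) @ 64 Hz
#>   SystP: 3239 event(s)
#>   tags: 2
#>   missing-data summary:
#>  modality total_duration_s total_points pct_missing
#>       EDA             3600        14400          25
#>       BVP             3600       230400          25
#>      Temp             3600         3600          25
#>       ACC             3600       230400          25
```

The one-hour window expects 14 400 EDA points at 4 Hz; the 15-min dropout
inside it leaves exactly 25 % missing, realised as a NaN run because
`pad_discontinuities` is on. Detrend the EDA, cut four one-minute epochs
from the first tag, and export:

```r
eda <- detrend_series(recs[[1]]$dat$EDA[[1]], "smoothness_priors",
                      lambda = 500)
eps <- epoch_data(recs[[1]], epoch_spec("sequential", anchor = "Tag 1",
                                        n = 4, length_s = 60))
eps[[1]]
#> <epoch> Epoch 1 [2024-01-28T08:40:00.000+08:00, 2024-01-28T08:41:00.000+08:00)

save_mat(recs[[1]], "S001-3YK31141P6_2024-01-28.mat")
save_xlsx(eps, "epochs.xlsx")
```

A command-line wrapper covering the same operations ships in
`inst/cli/wristflow`:

```sh
wristflow simulate --out data --hours 24 --seed 1
wristflow read --input data --timezone Asia/Singapore --window 09:00-10:00 --out out/
```

## Scope

The package is the computational core only: no GUI, no plotting beyond a
basic `plot()` method, no per-minute aggregate biomarkers, no E4 input, and
no cross-subject synchrony or feature-extraction analytics. The methods
vignette (`vignettes/wristflow.Rmd`) documents the models, parameter
defaults, numerical choices and limitations.
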