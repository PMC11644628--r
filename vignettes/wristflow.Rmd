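---
title: "Reconstituting and preprocessing chunked wristband data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstituting and preprocessing chunked wristband data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristflow)
```

## The problem

Wrist wearables of the EmbracePlus class store raw signals as *chunk*
files: each file holds at most 30 minutes of one recording, with
per-modality start timestamps in microseconds since the Unix epoch and a
per-modality sampling frequency. A week of data from one participant is
hundreds of fragments spread over date folders. This vignette documents
how `wristflow` turns those fragments into analysable series, the models
and parameters behind its preprocessing suite, what the synthetic device
generator does and does not emulate, and the numerical decisions a reader
should know before trusting the output.

## Time, windows, and the missing-data denominator

All internal times are integer-valued microseconds since the Unix epoch,
UTC, held in R doubles (exact below 2^53). Local civil time — including
daylight-saving shifts — is a projection applied for display and export,
never the primary key. Systolic-peak events keep the device's nanosecond
unit; near the current epoch a double quantises nanoseconds to ~256 ns,
far below any physiological relevance, and round trips through the
package's own files are still bit-exact because the codec encodes the
double's exact integer value.

Windows are half-open `[start, end)` everywhere. A sample, peak or tag at
exactly `end` belongs to the next window, which prevents double counting
at seams when consecutive windows abut (e.g. multi-day custom reads with
overlap disallowed).

A uniform series stores no per-sample timestamps: sample *i* (0-based)
lives at `start_us + round(i * 1e6 / fs)`. Percent missing is defined on
the *window's* nominal grid: over `[start, end)` at rate `fs` the expected
count is `floor((end - start) * fs / 1e6)`, and every expected point
without a finite sample is missing. The denominator question — the
requested window versus the data actually present — is genuinely open;
we chose the requested window because it is the only grid that is
unambiguous when data are absent, and it makes the summary invariant to
whether missingness is realised as absent chunks or as explicit NaN
padding.

## Reconstitution

Discovery walks `participant_data/YYYY-MM-DD/<subject>-<device>/`;
anything not fitting that naming is ignored. The *default* read method
yields one window per subject per local civil day — local midnight to next
local midnight in the configured zone, hence 23- or 25-hour windows across
daylight-saving transitions (wall-clock anchoring was chosen because
windows are specified in wall time). The *custom* method anchors a
wall-clock window on every date with data and extends it by `timespan_h`;
when overlap is disallowed, a window starting inside its predecessor is
advanced to the predecessor's end.

Within a window, chunks of one modality are sorted by start time and
concatenated. Two payloads are contiguous iff the next start deviates from
the previous nominal end by at most **half a sample period** — enough to
absorb microsecond rounding, never enough to bridge a real missing sample.
Larger deviations open a discontinuity: without padding, each continuous
run is kept as its own segment; with `pad_discontinuities`, runs are
placed on a common grid (anchored at the first sample, or at the window
start with `pad_to_max`) and the holes become NaN. Overlapping payloads
(duplicated chunks) resolve *later-chunk-wins* with a warning. A sampling
frequency change within a window is a hard error naming the offending
files — silently resampling device data would be worse than stopping.

When `pad_to_max` is off, the emitted series covers only the extent
actually spanned by data (trimmed to the window); whether the original
tool emits the requested span instead is unspecified, and this choice
keeps empty leading/trailing stretches out of summaries unless explicitly
requested.

## Storage fidelity

The Avro payloads mirror the device convention: EDA/BVP/temperature values
are 32-bit floats; accelerometry is stored as ADC counts with the
conversion parameters (`physicalMin/Max`, `digitalMin/Max`) carried in the
file and applied at read time, yielding units of g. The synthetic
generator quantises its ground truth through the same float32/ADC mapping,
which is why the chunk→write→read→concatenate invariant in the tests is
*bit-exact* rather than approximate. The CSV dialect (one file per
modality per chunk; column 1 Unix microseconds; remaining columns values;
peaks and tags as single-column files) round-trips through 17-significant-
digit text. Tag timestamps are standardised to microseconds internally and
rounded to the millisecond for display, matching the tag table's ms
precision.

## Preprocessing

Every operation preserves length, start time and rate (resampling changes
the rate but preserves the covered extent to within one sample period),
operates per channel on accelerometry, and never invents data across gaps:
NaN runs pass through untouched unless `fill_gaps()` is asked to fill
them.

**Resampling** interpolates each finite run on its own span (linear,
cubic spline, shape-preserving pchip, or modified Akima). No anti-alias
filter is applied by default — down-sampling picks interpolated grid
values, as plain interpolation implies — but an optional flag low-passes
at 0.45× the target rate first. Event series are never resampled.

**Detrending.**
*Linear* subtracts the least-squares line. *Robust* fits a polynomial of
order `order` (default 3) by iterated weighted least squares, zeroing the
weight of samples whose residual exceeds `thresh_sd` (default 3) residual
SDs, for `iters` (default 3) passes — a spike therefore does not drag the
baseline. *Smoothness-priors* estimates a slowly varying trend as the
solution of

$$\hat z = (I + \lambda^2 D_2^\top D_2)^{-1} z,$$

with $D_2$ the $(N-2)\times N$ second-difference operator, and returns
$z - \hat z$. This is the classical regularised detrender used for
heart-rate-variability series; $\lambda$ (default 500, a common choice in
that practice) sets the cut: $\lambda \to 0$ removes everything (the
residual is the zero vector), $\lambda \to \infty$ approaches linear
detrending. The solve uses a sparse banded Cholesky; the tests keep an
independent dense direct solve as oracle and require agreement to 1e-8 at
N = 2000. With missing samples, finite samples are compacted, detrended,
and scattered back — NaN in, NaN out.

**Filtering.** Moving mean/median use centred windows of odd sample
length derived from `window_s`, truncated at edges; both are
property-tested against a brute-force per-window oracle. The Butterworth
filter is applied forward–backward (zero phase), which doubles the
effective order — the order parameter refers to the underlying design.
Cutoffs at or above Nyquist are refused. Each finite run is filtered
separately; runs too short for the filter's padding are left unfiltered
with a warning rather than fabricated.

**Artifact detection** slides a `window_s` window every `step_s` (default
one sample) and unions five criteria: amplitude bounds flag individual
samples outside `[min, max]`; the z-score criterion uses the *global* mean
and SD (it is listed as its own criterion, separate from the windowed
statistics, so it is not windowed); variance and SD flag all samples of
any window whose statistic exceeds its threshold (both are implemented
independently even though SD = √variance makes them redundant at matched
thresholds — users may set them differently); slope flags adjacent finite
samples whose absolute first difference times `fs` exceeds the threshold
(units/second), and never flags across a gap. Detections are padded by
`pad_s` on both sides and merged. Applying a detection sets the flagged
samples to NaN — nothing else changes, so the missing-data summary
increases by exactly the flagged count.

**Gap filling** replaces NaN runs no longer than `max_gap_s`:
previous/next/nearest copy neighbouring scores (the only methods defined
at the series edges); linear/spline/pchip/makima interpolate from the
finite samples; moving mean/median use the centred window statistic of the
finite neighbours. The modified-Akima interpolant is implemented from its
published weights ($w_1 = |\delta_{i+1}-\delta_i| +
|\delta_{i+1}+\delta_i|/2$, mirrored on the left) with quadratic endpoint
extension, evaluated as a piecewise cubic Hermite.

**z-scoring** standardises by the finite samples' mean and SD, globally or
in a centred sliding window; a constant series is a refused
(no-variance) input rather than a silent division by zero.

## Epoching

Event and timepoint modes cut `[anchor - pre_s, anchor + post_s)`;
sequential mode cuts `n` epochs of `length_s` stepping
`length_s - overlap_s` forward from the anchor or mirrored backward ending
at it (generated anchor-first, labelled in temporal order); A-to-B cuts
the span between two tags and refuses an empty span. Epochs slice the
parent grid directly — the start snaps to the first grid sample at or
after the nominal start, so no resampling ever happens inside epoching,
and concatenating non-overlapping sequential epochs reproduces the parent
slice sample-for-sample. Epochs overrunning the recording are truncated
and flagged (`truncate = FALSE` turns that into an error); whether
truncation or rejection is the "right" behaviour is open, and the flag
preserves the information either way.

## Export

MAT-files use the uncompressed level-5 container for maximal cross-tool
readability (scipy and Matlab both read the output; the reader accepts
small- and long-format elements but not compressed ones). Each file holds
`cfg` (the read settings and window metadata) and `dat` (one table per
continuous segment per modality with universal time in microseconds, local
ISO-8601 time *with UTC offset* — unambiguous across DST — and the value
columns, plus the tag table and the missing-data summary). XLSX workbooks
carry the same columns, one sheet per modality (or per epoch × modality)
plus a tag sheet; cells store numeric microseconds rather than spreadsheet
datetimes so millisecond tag times survive exactly. Missing samples are
empty cells.

## The synthetic device generator

The generator exists to exercise timing, chunking, gaps and preprocessing
— it makes no physiological-realism claims. Its defaults are the device
conventions: EDA 4 Hz, BVP 64 Hz, temperature 1 Hz, accelerometry 64 Hz;
15-minute chunks (a continuous 24-h session spans 96 files; 30 minutes is
the enforced ceiling). Signal models: EDA is a tonic level (2 µS with slow
sinusoidal drift) plus Poisson-timed phasic responses (2 per minute,
lognormal amplitudes around 0.3 µS, instantaneous rise, 5-s exponential
decay) and Gaussian noise (SD 0.05 µS); BVP is a zero-mean pulsatile
waveform (systolic Gaussian bump with a smaller dicrotic bump) at 72 bpm
with 5 % beat-to-beat jitter, noise SD 0.02, and one systolic-peak event
per beat at the waveform maximum; temperature drifts sinusoidally around
33 °C (SD 0.01); accelerometry is Gaussian noise (SD 0.05 g) around a 1-g
gravity offset on z, with alternating 10-minute activity bursts carrying a
1-Hz square wave. Gaps delete samples (and the peaks/tags inside them);
chunk boundaries align to the session start, and a session crossing
midnight files its chunks under each date. One integer seed drives every
draw.

What it does **not** emulate: irregular chunk boundaries produced by real
hardware restarts, sensor drift and motion-coupled artifact structure,
pulse-rate variability beyond white jitter, device clock drift, or
corrupted files. Passing tests therefore demonstrate that the *plumbing* —
timing arithmetic, reconstitution, missing-data accounting, preprocessing
algebra — is correct on data whose ground truth is known exactly; they do
not validate physiological inference on real recordings.

## Problem sizes and runtime choices

The test suite runs one full-scale case — a 24-hour, all-modality session
(≈22 million samples across 96 chunk files) simulated, written, rediscovered
and reconstituted exactly — and keeps every other fixture at minutes of
simulated time, which is ample to exercise boundaries (gap edges, window
seams, DST transitions, chunk splits). Oracle tests use 1000 random short
series for the moving filters and N = 2000 for the dense smoothness-priors
solve. These sizes were chosen so the whole suite completes in a few
minutes while still covering one real-scale day end to end.

## Known limitations

- Avro reading supports the null codec only; deflate-compressed containers
  are refused with a clear error. Files written by this package always use
  the null codec.
- The Avro schema follows the device's published field layout; a future
  firmware adding fields is tolerated (schema-driven decoding), but a
  renamed field would need a reader update.
- MAT reading does not support compressed (`miCOMPRESSED`) elements.
- `fs` is stored as a 32-bit float in Avro payloads, as on the device;
  rates that are not float-representable (e.g. 0.1 Hz) round accordingly.
- Windowed z-scores and windowed artifact statistics use truncated windows
  at the series edges; the first/last few samples therefore see smaller
  windows, not reflected ones.
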