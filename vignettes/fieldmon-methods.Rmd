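---
title: "Methods: data collation, image selection and microclimate analytics in fieldmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data collation, image selection and microclimate analytics in fieldmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldmon)
```

`fieldmon` models a distributed plant-phenotyping deployment: in-field
workstations, one per monitored plot of a trial grid, each with a camera
and a microclimate sensor suite, synchronizing with a central collation
server over an unreliable network. This vignette is the package's own
account of the methods involved — the models, the tunable parameters, the
numerical choices, and where the design was genuinely open, why it was
resolved the way it was.

## The data model

A trial is an `Experiment` (geolocation, a `grid_rows x grid_cols` plot
grid) whose `Plot`s carry the experimental design (genotype, treatment,
replicate, drilling date) at 0-based row-major grid coordinates, row 0
being the north edge; the coordinate convention is arbitrary but must be
fixed once for heat maps to be meaningful. A `Device` monitors at most
one plot and owns a non-empty pre-shared key. Sensor readings are one
`(device, variable, timestamp, value)` tuple each; the triple
`(device, variable, timestamp)` — at one-second resolution, always UTC —
is the deduplication key on which every idempotency guarantee in the
system rests. Storage is SQLite via DBI: a single-file relational store
is exactly the right weight for one trial server, and `INSERT OR IGNORE`
against the primary key implements the dedupe contract atomically.

All timestamps are stored and exported as UTC ISO-8601. The single
deliberate exception is the late-blight rule (below), where *calendar
days* are cut in a configurable local timezone, because agronomic day
boundaries are local phenomena; storage stays UTC regardless.

## Representative-image selection

Each device captures several candidate images per day and uploads exactly
one. The three published selection criteria — file size, intensity,
clarity — are composed here as *two hard gates and one objective*:

- **File-size gate** (`min_file_size`, bytes; default 50% of the day's
  median file size): removes truncated or failed captures. A relative
  default adapts to whatever resolution and compression the camera
  produces.
- **Intensity gate** (`intensity_low = 40`, `intensity_high = 215` on the
  0–255 grayscale mean): removes black frames (failed exposure, night
  captures) and blown-out frames. The bounds sit roughly 15% inside the
  range ends, wide enough to accept dawn/dusk light.
- **Clarity objective**: among survivors, the image with the maximum
  clarity wins; ties break to the earliest capture. Clarity is the
  variance of the 3×3 discrete Laplacian (kernel centre −4, cross
  neighbours +1) of the grayscale image — the standard no-reference
  sharpness proxy: it is zero for a flat frame, strictly positive for any
  structure, and strictly decreased by blurring.

Gates-plus-argmax is the simplest composition of the three criteria that
is fully testable: the suite checks it against a brute-force oracle over
thousands of randomly scored candidate sets.

The chosen image is downsized from the native 2,592 × 1,944 capture to
640 × 480 for transmission (both 4:3; the resampling factor 4.05 is not
an integer). Resampling is **area-average**: output pixel *j* is the
exact area-weighted mean of the input pixels its footprint covers,
implemented as two 1-D sparse weight-matrix passes. The weights of each
output pixel sum to 1 and each input pixel contributes equal total
weight, so the global mean is preserved exactly in real arithmetic and to
within one gray level after 8-bit quantization — a property the tests
assert directly. Mismatched aspect ratios are refused rather than
cropped.

## Sync payloads, authentication, store-and-forward

A sync payload is one JSON document: device id, cursor (`since`), the
latest status snapshot, all readings strictly after the cursor, and the
newest unacknowledged daily representative (base64). Authentication is
HMAC-SHA-256 over a **canonical serialization** — keys sorted
lexicographically, no insignificant whitespace, numbers printed with
`%.17g` (which round-trips IEEE doubles, so parse-then-reserialize is the
identity) — keyed by the pre-shared secret. Canonicality is what makes
signatures byte-stable across the wire; flipping any body byte, or using
any other key, fails verification.

The server acknowledges with two cursors: the highest ingested reading
timestamp, and the capture time of the payload's image if present. Two
cursors are needed because a device syncing hourly will have advanced its
readings cursor past the midday capture time of a representative selected
at day close; a single timestamp cursor would silently strand that image.

During outages, serialized payloads accumulate in a FIFO queue and drain
oldest-first on reconnection; entries older than the retention horizon
(default 60 days, the onboard buffer capacity being emulated) are dropped
with a warning and never delivered. Since the cursor only advances on
acknowledgement, consecutive offline payloads overlap in readings; the
server-side dedupe absorbs the overlap. This yields the system's central
property, checked over random fault schedules: the final store after any
outage pattern (within retention) is *identical* — byte-for-byte, via a
content checksum — to the fault-free run.

Deltas, not full history, are retransmitted after an outage; the queue
already preserves everything the server has not acknowledged, so
resending history would only duplicate work.

## Device health classification

Health is a pure function of the latest reported mode, the silence time
since the last sync, and the expected cadence (default 30 minutes, the
shipped status/sensor update interval; payload sync defaults to hourly):
red for reported `error`/`terminated`, for no contact ever, or for
silence beyond 6 × cadence; amber for reported `idle` or silence beyond
2 × cadence; green otherwise. The cut-offs are expressed as cadence
multiples so the rule survives reconfiguration; 2× tolerates one missed
update plus jitter, 6× (three hours at default cadence) is long enough
that a field visit is warranted. The classification is monotone in
silence — more silence never improves the color — which the suite checks
as a property.

Uptime is the time from device boot to the latest image capture; a
capture before boot is reported as a clock-skew error, never silently
clamped, because silent clamping would hide exactly the clock faults the
statistic exists to surface.

## Plot-grid interpolation and validation

A climate frame for variable *v* at instant *t* aggregates each device's
readings within ±`window_hours` (default 12 h, i.e. a daily mean for a
midday frame) of *t* into its plot cell; those are **measured** cells.
Every other cell is filled by inverse-distance weighting over all
measured cells with power 2 on Euclidean distance in grid units. IDW was
chosen over kriging deliberately: with at most a few dozen sensors there
is no data to fit a variogram, and IDW's convex weights make three
properties provable and tested — exactness at measured cells,
boundedness within the measured range, and translation equivariance.
Whether the original presentation also smoothed temporally is unknowable
from the outside; the aggregation window is therefore an explicit
parameter rather than a hidden constant.

Heat-map series default to 14-day intervals (a 56-day window from early
booting to early grain filling gives 5 frames); frames with no readings
in the window become explicit empty markers rather than errors, so a
season with a data gap still renders. Rendering fixes one color scale
across the series and outlines measured cells red, interpolated cells
green.

Leave-one-out validation removes each sensor in turn and predicts its
cell from the rest with the same IDW scheme, reporting per-sensor errors
and RMSE. As the spatial field flattens the RMSE goes to zero (tested),
so the statistic directly measures how much spatial structure the network
fails to capture.

`sensor_correlation()` is plain Pearson correlation over
pairwise-complete points (via `stats::cor`), used e.g. to confirm soil
temperature tracks ambient temperature.

## The Smith-Period rule

A calendar day qualifies iff its minimum temperature over all 24 hourly
values is **≥ 10 °C** and at least **11** of the 24 hours have relative
humidity **≥ 90%**; a risk period is a maximal run of **≥ 2** consecutive
qualifying days. All thresholds are inclusive, matching the rule's "or
above" / "at least" phrasing. Days with fewer than 24 hourly points are
excluded with a warning rather than imputed; calendar gaps break runs.
The per-day criterion is a count and a minimum, hence order-free within
the day — shuffling a day's hours cannot change its qualification, which
the suite exploits as an invariance test, alongside equivalence to a
brute-force run-scan oracle on random synthetic months.

## The field simulator

The simulator is the package's substitute for hardware, not a caricature
of it. Defaults describe a temperate-spring wheat trial: mean ambient
15 °C with a ±5 °C diurnal sinusoid (peak 14:00, trough 02:00 — so the
noise-free model hits daily extrema of exactly 10 and 20 °C), a
+0.05 °C/day seasonal trend, relative humidity in anti-phase around 75%
(clipped to [0, 100]), a clear-sky half-sine of light between 06:00 and
18:00 peaking at 60,000 lux and exactly zero at night, soil temperature
as ambient lagged 2 h and damped (coefficient 0.5) toward the running
ambient mean, and soil moisture declining slowly from 35%. Per-variable
Gaussian noise defaults (0.5 °C, 3% RH, 2,000 lux, 0.3 °C, 1.5%) are of
the order of the consumer-grade sensors such stations carry. Every
(device, variable) pair derives its own RNG stream from the master seed,
so runs are reproducible and composable: adding a device never perturbs
existing series. The standard layout mirrors a realistic deployment — 16
monitored plots among 32 genotype plots on a 4 × 8 grid — as a default,
not a hard-coded shape.

Synthetic canopy images are a green-tinted low-frequency random field
plus fine-grained detail whose amplitude scales with `sharpness`, all
scaled by `exposure`; clarity is strictly increasing in sharpness at
fixed seed, mean intensity in exposure, and `exposure = 0` produces a
black frame the intensity gate must reject. The simulator emulates the
*statistical* features the pipeline keys on — diurnal structure, spatial
gradients, sharpness/exposure variation, dropout patterns — and none of
the things it does not: no radiative micrometeorology, no crop growth,
no real optics. Passing tests therefore certify the data-handling
contracts, not meteorological or photographic realism.

## Numerical and operational choices

- Dedupe equality at one-second resolution; sub-second precision is
  floored on entry.
- CSV values print with `%.17g` so export → parse is the identity on
  doubles; the CSV dialect is comma, LF, `.` decimal, header
  `device_id,variable,timestamp_utc,value`.
- Zip archives pin entry mtimes to a constant and fix the compression
  level, making archives byte-identical for identical store content; an
  imageless month yields a valid empty archive.
- Ingestion is transactional: any malformed part rejects the whole
  payload with the store untouched, which is what makes idempotency
  provable rather than probable.
- IDW at a zero distance (a sensor's own cell) short-circuits to the
  sensor value, avoiding the 1/0 weight.
- Selection ties (equal clarity) break to the earliest capture time, so
  selection is a deterministic function of the candidate set.
- The server store keeps *all* synchronized images, not only
  representatives, since monthly image-series archives must be
  downloadable; in the shipped flow devices upload only representatives,
  so the distinction is latent until a deployment uploads more.

## Problem sizes in the test suite

The suite exercises the partition-recovery property at 10 devices × 30
simulated days (daily syncs, two candidate captures per device-day at a
reduced 160 × 120 capture size), plus faster 2-device runs for the other
end-to-end properties; oracle-equivalence checks run at 1,000 random
candidate sets and 1,000 random months in the acceptance tests and ~200
in the unit tests. The full native-resolution 2,592 × 1,944 → 640 × 480
path is exercised directly in the downsizing tests. These sizes are the
package's chosen balance between coverage and a suite that stays pleasant
to run locally.

## Known limitations

- The store is single-writer per connection; a multi-tenant deployment
  would front it with one server process (as the in-process
  `server_receive()` models) or a server-grade SQL engine.
- The HTTP transport itself is out of scope: the wire format, signing,
  authentication, acknowledgement and queueing are all implemented and
  tested in-process; binding them to a socket is deployment plumbing.
- IDW cannot extrapolate beyond the measured range — a genuine hotspot
  with no nearby sensor is flattened toward its neighbours. The LOO RMSE
  is the honest measure of that risk for a given layout.
- Smith Periods are a screening rule, not an epidemiological model;
  inclusive thresholds at exactly 10 °C / 90% / 11 h / 2 days follow the
  rule's published wording, and boundary weather will flip qualification
  with sensor noise.
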