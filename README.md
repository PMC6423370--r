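# fieldmon

Distributed field-phenotyping experiments pair per-plot crop imagery with
per-plot microclimate: dozens of low-cost camera + sensor workstations sit
on the plots of a trial grid, each logging hourly readings (ambient
temperature, relative humidity, light, soil temperature, soil moisture)
and choosing one representative crop image per day, over field networks
that drop out for hours or days at a time. `fieldmon` is an R
implementation of the full information-management stack for such trials,
backed by a deterministic field simulator so every layer is testable with
no hardware:

- **Device agent** — scores candidate images on file size, mean intensity
  and clarity (the variance of a 3×3 discrete Laplacian of the grayscale
  image, a standard no-reference sharpness measure), gates out truncated
  and badly exposed frames, picks the maximum-clarity survivor as the
  day's representative, and downsizes it from the native 2,592 × 1,944
  capture to 640 × 480 by area-average resampling (mean intensity is
  preserved to within one gray level). Payloads — latest status, all
  readings since the last acknowledged instant, the newest unacknowledged
  representative — are one canonical JSON document signed with
  HMAC-SHA-256 under a pre-shared key, and buffer through a FIFO
  store-and-forward queue (60-day retention) across network outages.
- **Collation server** — authenticates and ingests payloads all-or-nothing
  and idempotently into a SQLite store, classifies device health
  (green/amber/red as a pure function of reported mode and silence time
  relative to the expected 30-minute cadence), computes uptime and storage
  accounting, assembles grid/device view documents, and exports sensor CSV
  and monthly image Zip archives that are byte-pure functions of store
  content.
- **Climate analytics** — aggregates readings into plot-grid frames,
  fills unsensed plots by inverse-distance-weighted interpolation (power
  2, convex weights: exact at sensors, bounded by the measured range),
  renders heat-map series at a 14-day default interval with measured cells
  outlined red and interpolated cells green, cross-validates the sensor
  network leave-one-out, and detects **Smith Periods** — late-blight risk
  windows of ≥ 2 consecutive days each with daily minimum temperature
  ≥ 10 °C and relative humidity ≥ 90% for ≥ 11 of the 24 hours.
- **Field simulator** — seeded diurnal weather (sinusoidal temperature,
  anti-phase humidity, day/night light, lagged and damped soil
  temperature), procedural canopy images with controllable sharpness and
  exposure, device lifecycles, and fault schedules (outages, failures).
  One pseudo-random stream per device per variable, so adding a device
  never perturbs another device's data.

The headline distributed-systems property, checked in the test suite over
random fault schedules: **for any outage pattern within the retention
horizon, the final server dataset equals the dataset of an outage-free run
over the same inputs.**

## Worked example

Simulate one week of a monitored trial, sync it into a collation server,
and analyse the collated microclimate:

```r
library(fieldmon)

server <- server_create(":memory:")
simulate_field_layout(server$store, "trial17", grid_rows = 2, grid_cols = 4,
                      n_monitored = 4, capture_width = 160, capture_height = 120)
transcript <- simulate_device_run(server, "trial17", days = 7,
                                  sync_every_h = 24, model = weather_model(seed = 42))
table(transcript$outcome)
#> delivered
#>        28

grid <- climate_grid(server$store, "trial17", "ambient_temp_C",
                     "2017-05-04T12:00:00Z")
round(grid$values, 2)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 15.04 15.20 15.30 15.28
#> [2,] 15.23 15.24 15.32 15.29
grid$measured
#>       [,1]  [,2] [,3]  [,4]
#> [1,]  TRUE FALSE TRUE FALSE
#> [2,]  TRUE FALSE TRUE FALSE
```

28 payloads (4 devices × 7 daily syncs) were delivered. The climate grid
holds midday ambient temperature for every plot: `TRUE` cells are direct
sensor readings, `FALSE` cells were interpolated from them, and the warm
south-east corner reflects the simulator's spatial gradient.
`autoplot(grid)` (or `render_heatmap()` for a frame series) draws the
heat map with red/green provenance outlines.

Leave-one-out validation quantifies how well the sensor network supports
that interpolation:

```r
loo <- loo_validation(store_readings(server$store, variable = "ambient_temp_C"),
                      store_plots(server$store, "trial17"),
                      "ambient_temp_C", "2017-05-04T12:00:00Z")
glance(loo)
#>    rmse n_sensors variable       at
#> 1 0.123         4 ambient_temp_C 2017-05-04 12:00:00
```

— each sensor, predicted from the other three, misses its own reading by
0.12 °C RMS. Finally, a humid fortnight scanned for late-blight risk:

```r
wx <- simulate_weather(weather_model(mean_temp_C = 15.5, rh_base_pct = 90,
                                     rh_diurnal_amplitude_pct = 6, seed = 42),
                       days = 14)
detect_smith_periods(wx)
#>   start_day    end_day n_days  rule
#> 1 2017-05-01 2017-05-03     3 smith
#> 2 2017-05-05 2017-05-06     2 smith
#> 3 2017-05-08 2017-05-12     5 smith
```

Three risk windows: runs of at least two consecutive days whose minimum
temperature stayed at or above 10 °C with at least 11 high-humidity hours
each. `smith_daily_table()` exposes the per-day qualification behind them
and `autoplot()` shades the windows over the temperature trace.

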