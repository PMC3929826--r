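# clinicflow

Discrete-event simulation of patient flow through an orthopedic outpatient
clinic, built to study how staffing and schedule changes reduce waiting
times. The package models a teaching-hospital clinic in which patients are
admitted from early morning but the physicians attend only from mid-morning,
so most of the waiting accumulates *before* the physician even arrives. It
provides the full study pipeline: distribution fitting from patient event
logs, model validation against observed per-station waits, and a replicated
what-if comparison of ten improvement scenarios.

## The model

Patients arrive during an admission window with interarrival times
X ~ N(μ = 4.2, σ = 5.8) minutes, clipped at zero (negative draws become
simultaneous arrivals). Each patient passes registration and the cash desk,
is examined by a resident — previously admitted inpatients by a **novice
resident** (2 servers, service ~ LN matched to mean 3.46, SD 2.06 min),
new and follow-up outpatients by an **experienced resident** (1 server,
4.91 ± 0.93 min) — may be referred to the **senior staff physician**
(1 server, 4.20 ± 0.93 min) and may need paraclinic services. Every queue
is FIFO with scheduled multi-server stations: residents attend 10:00–13:20,
the senior staff physician 10:45–12:25, and patients may queue long before
attendance starts. The queueing delay at a physician station is split
around the attendance start t₀:

    W_before = max(0, min(t_start, t₀) − t_join),   W_after = W − W_before

Scenarios are data — named sets of field deltas on the configuration
(more residents, earlier attendance, shifted admission) — and are compared
over n = 1000 replicated clinic days with common random numbers, using the
weighted-mean score over the three physician servers

    W̄ = (2·W_novice + 2·W_experienced + 1·W_senior) / 5

and the percent reduction 100·(W̄_base − W̄_scenario)/W̄_base.

The engine's event calendar is written in C++ (via Rcpp) and is verified
against Erlang-C/M/M/c closed forms, Little's law, and a brute-force pure-R
replay oracle.

## Worked example

```r
library(clinicflow)
cmp <- compare_scenarios(calibrated_base_case(), 0:10, n_reps = 200, seed = 1)
print(cmp)
```

```
<scenario_comparison: 11 scenarios x 200 reps>
 scenario_id weighted_mean pct_reduction
           0         57.78          0.00
           1         56.16          2.80
           2         54.98          4.85
           3         35.26         38.97
           4         49.84         13.75
           5         39.18         32.20
           6         53.36          7.65
           7         26.47         54.18
           8         36.23         37.29
           9         14.33         75.19
          10         24.66         57.33
best scenario: 9
```

The base case scores a weighted-mean wait of ~58 min; scenario 9 (residents
attending from 09:00 for 260 min, senior staff from 10:00 for 160 min,
admission from 08:00) is the best lever, cutting the score by ~75% — the
same ranking and headline conclusion as the original study (71.40% from its
published tables). Drilling in:

```r
print(cmp$summaries[["9"]])
```

```
<replication_summary: scenario 9 (Mix of scenarios 3, 4 and 5), 200 reps, ~48.8 patients/day>
  novice_resident       before   6.81  after   2.25  total   9.06 min
  experienced_resident  before   6.64  after   2.46  total   9.10 min
  senior_staff          before  17.59  after  17.76  total  35.35 min
  weighted mean (2:2:1): 14.33 min
```

Moving attendance earlier collapses the before-attendance component
(~45 min in the base case) to under 7 minutes for the residents.

Other entry points: `simulate_clinic()` (one day, full event log),
`generate_patient_log()` / `fit_interarrival()` / `fit_service_times()` /
`runs_test()` (the estimation phase), `validate_waits()` (observed vs
simulated), `calibrate()` (tunes the unpublished mix/routing parameters),
`reported_scenario_waits()` (the published tables as data). A CLI wrapper
lives at `inst/cli/clinicflow.R` (`generate` and `compare` subcommands).

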