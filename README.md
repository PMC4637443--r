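# ischsim

In-silico detection of early (10-minute) myocardial ischemia in the ECG.

`ischsim` is a simulation laboratory for a question that is hard to study
clinically: *which kinds of early left-ventricular ischemia are visible in
which body-surface lead systems, and does a better ST feature or an extra
electrode help?* ECGs from the first minutes of an occlusion are rarely
available, and the true location and size of the ischemic region is never
known precisely — so the package generates everything: parametric
voxelized biventricular anatomies with 17-segment AHA labels inside
cylindrical torsos, hemispherical ischemic regions of graded severity
(central ischemic zone + border zone), single paced beats via a
first-arrival cellular automaton with ischemia-slowed conduction,
phenomenological action-potential templates modulated by a per-voxel zone
factor, and body-surface potentials from an equivalent current-dipole
forward model. It is aimed at biosignal/electrophysiology researchers who
want a fully reproducible, desk-scale testbed for ST-deviation detection
logic.

## The two ST features

For a baseline-corrected multichannel record `b(e, t)` (µV, 2 ms frames):

* **ST-segment deviation (STSD)** — the mean deviation over the 25
  samples between 110 ms and 158 ms, maximized over leads:

  `STSD = max_e | (1/25) Σ_{t=110..158ms} b(e, t) |`

* **K point deviation (KPD)** — the across-lead envelope of absolute
  values, `env(t) = max_e |b(e, t)|`, is minimized over the interval from
  the R peak (40 ms) to the T peak (320 ms); the minimizing time is the
  *K point* (a robust substitute for the hard-to-detect J point) and

  `KPD = min_t max_e |b(e, t)|`

  An elevation-only variant clips negative samples before the envelope.
  KPD's advantage: ST deviation that alternates in sign cancels in the
  STSD mean but cannot pull the envelope to zero (see the packaged
  `inst/extdata/alternating_st.csv` fixture: STSD = 0, KPD = 48 µV).

A setup counts as *detected* at threshold τ when the feature is ≥ τ;
detection rates are averaged over standard threshold grids (54 steps on
24–240 µV for STSD, 36 steps on 9–150 µV for KPD) and broken down by
lead system (3-channel, 12-lead, 12+R with right-sided Wilson leads,
12-lead + 1 optimized electrode, full body-surface map), ischemia radius,
border-zone size, transmurality, subject, and AHA segment.

## Worked example

Simulate one transmural anterior ischemic beat and extract the features:

```r
library(ischsim)

subject <- default_subjects()[["K-like"]]
setup   <- ischemia_setup("K-like", segment = 7,   # mid anterior
                          total_radius = 25, bz_radius = 4.8)
sim <- simulate_beat(subject, setup, voxel_size = 2, n_bspm = 100)

sim$field$transmural_flag
#> [1] "transmural"

rec12 <- extract_scenario(sim$record, "12-lead", sim$electrodes)
ecg_features(rec12)
#> # A tibble: 1 × 6
#>    stsd stsd_lead   kpd k_elevation k_point_time scenario
#>   <dbl> <chr>     <dbl>       <dbl>        <dbl> <chr>
#> 1  157. V3         78.6        38.2          116 12-lead
```

A 25 mm region spanning the anterior wall produces a 157 µV ST-segment
deviation (largest in V3, the lead overlying the region) and a 79 µV
K point deviation at 116 ms — ST elevation where a small subendocardial
region at the same site yields ST *depression* in the overlying
electrode.

A full reduced study (one subject, 17 segments × 2 radii, 34 setups,
about a minute) and its threshold-free summaries:

```r
study <- run_study(fast_study_config())
glance(study)                       # setup counts + 12-lead averaged rates
averaged_rate(study, "BSPM", "kpd") # grid-averaged BSPM sensitivity
subgroup_report(study, "radius", "12-lead", "kpd")
optimize_additional_electrode(study, "common")
autoplot(study, feature = "kpd")    # rate-vs-threshold curves per lead system
```

`tidy(study)` returns the long study table (one row per setup ×
scenario × feature), `run_study(study_config())` runs the full default
grid of 765 ischemic setups across all three subjects.

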