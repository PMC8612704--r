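# axocascade

Single-axon live-imaging analysis of the axon degeneration cascade.

After an axon is severed, activation of the NAD⁺ hydrolase SARM1 triggers a
stereotyped sequence of failures in the detached segment: cellular ATP
falls, mitochondria stop moving and then depolarize, extracellular calcium
floods in, phosphatidylserine appears on the outer membrane leaflet, the
membrane loses integrity, and the axon fragments. Because individual axons
degenerate asynchronously, this ordering is only visible when each axon is
imaged and analysed on its own. `axocascade` is an R toolkit for exactly
that analysis — aimed at labs doing live fluorescence imaging of injured
neurons (GCaMP6, TMRM, PercevalHR, mRuby3, Annexin-V, mitochondrial
kymographs) and at method developers who need a fully synthetic but
statistically faithful test bed for event-ordering pipelines.

## What it computes

**Per-axon event detection** (module `events`): channel baselines from the
pre-injury window; calcium-influx onset as the first sustained rise to
F/F_base ≥ 2 after the injury transient; the TMRM "drastic drop" as the
first frame-to-frame reduction > 30% (Diff_TMRM); the beginning of
degeneration as a sustained > 50% loss of the cytosolic mRuby3 signal;
Annexin-V (phosphatidylserine) onset; the percent PercevalHR (ATP sensor)
decline at 3.5 h; second-calcium-peak initiation, duration and intensity;
and a morphology-based **axon degeneration index**
DI = fragment-like area / total axonal area (fragment-like: circularity
4πA/P² ≥ 0.2), with degeneration at DI > 0.4 and baseline QC at DI < 0.2.

**Kymograph motility** (module `kymo`): track extraction from space–time
images, the net-displacement motility criterion (mobile iff > 5 µm per
300-s bout), per-bout mobile fractions, and arrest-time estimation (first
all-stationary bout never followed by renewed movement).

**Cohort ordering statistics** (module `ordering`): signed event-time
differences ΔT = t_later − t_earlier summarised as mean ± SEM,
frame-binned strict-before/same-frame ordering fractions, ordinary
least-squares regressions with R², and the paired ATP-decline versus
motility-stalling analysis.

**Synthetic cohorts** (module `simulate`): a generative model of the
cascade — per-axon crisis times, ordered event offsets, logistic ATP
decline coupled to mitochondrial stalling, per-channel traces at the real
acquisition cadences with ~10% multiplicative frame noise, kymograph
bouts, and morphology images — with defaults calibrated to the published
single-axon cohort statistics (ΔT ≈ 0.42 h arrest→calcium, 0.51 h
calcium→PS, ~100 min calcium→degeneration, 5/7 strict TMRM-before-calcium
at 10-min frames, R² ≈ 0.61/0.76 for the ATP–motility regressions).

File formats are plain TSV (traces, event tables, track tables), PNG
(morphology), and JSON (configuration, reports); see `?read_traces`,
`?pipeline_config`, `?run_pipeline`.

## Worked example

```r
library(axocascade)
p <- cascade_params()                        # calibrated cascade defaults
co <- generate_cohort(10, p, seed = 1, protocol = "calcium_annexin")
calls <- analyze_cohort(co)                  # run every detector per axon
delta_t(calls, "ca_onset", "ps_exposure")
#> deltaT(ca_onset -> ps_exposure): 0.500 +/- 0.050 h (mean +/- SEM, n = 10, 0 excluded)
delta_t(calls, "ca_onset", "degeneration")
#> deltaT(ca_onset -> degeneration): 1.650 +/- 0.039 h (mean +/- SEM, n = 10, 0 excluded)
```

Ten simulated axons, imaged every 10 min, analysed exactly as real traces
would be: calcium influx precedes phosphatidylserine exposure by half an
hour and the beginning of degeneration by ~1.65 h (≈100 min), with
per-axon scatter of the magnitude the calibrated generator encodes. The
same `calls` table feeds `ordering_fraction()`, `cohort_report()` and,
for protocols with kymograph bouts, `atp_motility_analysis()`.

The methods vignette (`vignettes/cascade-methods.Rmd`) documents the
generative model, every detector's operational definition and boundary
semantics, the calibration of the noise parameters, and what the
synthetic validation does and does not demonstrate.

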