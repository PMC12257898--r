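# spotpet

Spot-by-spot in-beam PET range verification for proton therapy.

## The problem

In pencil-beam-scanned proton therapy, the sharpest lever on treatment
quality — and the biggest risk — is the distal edge of the dose, where a few
millimetres of range error move dose from tumor into healthy tissue.  Proton
irradiation activates tissue into positron emitters, and their annihilation
photons can be imaged in coincidence by a PET system watching the patient
during delivery.  The dominant emitters, ¹⁵O and ¹¹C, decay over minutes and
give no prompt feedback; the very short-lived ¹²N (half-life 11.0 ms,
λ = 63.01 s⁻¹) decays within the ~60-ms beam pause that can be inserted
after each spot, making *instantaneous, per-spot* verification of the distal
energy layers possible.

`spotpet` is an R implementation of that measurement chain for medical
physicists studying the method: a synthetic generator of delivery logs and
list-mode coincidence streams (standing in for accelerator, phantom,
particle transport and detector), and the analysis that turns list-mode data
into per-spot range estimates:

* **Positron activity range (PAR)** — the 50% distal fall-off position of
  the 1D longitudinal activity profile, from a weighted least-squares fit of
  the sigmoid `A(z) = A0 / (1 + exp((z - PAR)/r))` to the lateral projection
  of the mid-plane LOR-intersection image (8×8 mm² pixels, no corrections).
* **Proton dose range (PDR)** — the 80% distal dose level of the
  longitudinal depth-dose curve, by linear interpolation.
* **Range shifts** — per-spot PAR differences between a nominal and a
  range-shifted delivery, with quadrature uncertainties, and inverse-variance
  aggregation over the spots of an energy layer.
* **Predicted activity images** — per-isotope production maps weighted by
  the per-spot ¹²N decay factor and the cross-spot accumulated ¹⁵O/¹¹C decay
  factors from the delivery log, composed into a total predicted image.

## Worked example

Simulate the first two energy layers of a head-like irradiation (one
146.5-MeV spot, seven 143.5-MeV spots, 2.8–5.3×10⁸ protons per spot, 60-ms
inter-spot pauses), then segment, reconstruct and fit every spot:

```r
library(spotpet)

sim <- simulate_listmode(head_like_plan(pre_beam_s = 1), seed = 42)
sim$stream
#> <listmode_stream> 5481 events over 2.530 s

ana <- analyze_spots(sim, fit_range = c(8, 96))
ana$report[, c("spot_id", "PAR_mm", "sigma_PAR_mm", "r_mm", "p_value")]
#>   spot_id PAR_mm sigma_PAR_mm r_mm p_value
#> 1   01/01   59.1         1.12 1.89   0.829
#> 2   02/01   53.8         2.03 4.34   0.658
#> 3   02/02   54.6         1.21 2.69   0.841
#> 4   02/03   52.9         1.13 3.46   0.268
#> 5   02/04   56.4         1.18 2.81   0.269
#> 6   02/05   55.9         1.33 2.37   0.653
#> 7   02/06   52.5         1.99 4.10   0.966
#> 8   02/07   54.5         1.47 4.01   0.250
```

Each row is one beam spot (labelled layer/spot in delivery order): the
fitted activity range in mm relative to the isocenter, its 1σ uncertainty —
1–2 mm per spot from ~600–1000 coincidences collected in the 60 ms after the
spot — the fall-off steepness `r`, and the two-tailed χ² probability of the
fit.  The first, most distal spot:

```r
ana$fits[["01/01"]]
#> <sigmoid_fit> PAR = 59.07 +/- 1.12 mm, A0 = 38.7, r = 1.89 mm
#>   chi2/dof = 8.20/8 (p = 0.829), range [8, 96] mm
```

The activity range sits systematically proximal to the dose range, because
nuclear production thresholds stop emitter creation a few mm short of the
proton range:

```r
pdrs <- lapply(seq_len(nrow(sim$log)), function(k)
  pdr_from_dose(depth_dose_profile(as.list(sim$log[k, ]), sim$phantom),
                spot_id = sim$log$spot_id[k]))
names(pdrs) <- sim$log$spot_id
offs <- par_pdr_offset_table(ana$fits, pdrs)
attr(offs, "mean_offset_mm"); attr(offs, "sd_offset_mm")
#> mean offset: -6.59 mm, sd: 1.35 mm
```

A 5-mm water-equivalent slab placed upstream (a simulated range error) is
detected by aggregating the second energy layer, with sub-millimetre
combined uncertainty:

```r
shifted <- analyze_spots(simulate_listmode(
  head_like_plan(pre_beam_s = 1),
  phantom_model(shifter_wet_mm = 5), seed = 42), fit_range = c(8, 96))
ids <- grep("^02/", sim$log$spot_id, value = TRUE)
aggregate_shifts(lapply(ids, function(id)
  par_shift(ana$fits[[id]], shifted$fits[[id]])))
#> <shift_result> PAR shift = 4.87 +/- 0.81 mm (n = 6)
```

`run_pipeline(run_config(seed = 1, scenario = "shifter_5mm"), "out/")`
runs the whole chain (simulation, segmentation, reconstruction, fitting,
prediction, comparison against a nominal run with the same seed) and writes
every artifact — delivery log, list-mode CSV, interval table, fit report,
prediction report, comparison table and a manifest — to a directory.  A
command-line wrapper lives at `inst/cli/spotpet.R`.

The methods vignette (`vignettes/range-verification.Rmd`) documents the
generator's physics model, the fitting and uncertainty conventions, and the
known limitations.

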