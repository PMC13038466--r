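# dnsnmr

Planning, simulation and evaluation of **dynamic-number-of-scans (DNS)
super-resolution acquisition** for the indirect dimension of 2D (solid-state)
NMR experiments.

Resolution along t₁ is limited by the effective transverse decay rate
R₂ = π·FWHH. DNS acquisition varies the number of co-added scans per t₁
increment following an exponential-cosine weighting,

    ns(t₁) = N₁ · exp(R_enh·t₁) · cos(ω_apo·t₁),      R_enh = R₂(1 − f),

which cancels a fraction *f* of the signal decay during acquisition itself:
the stored FID decays with R₂·f, so *f* = 0.5 halves the apparent linewidth.
The cosine rolls the scan count back to zero at
t_max = 3π/(2·R_enh), keeping the experiment time finite. Compared with
applying the same window digitally to a conventional data set, DNS
concentrates signal averaging where the FID is weak and wins roughly
15–20% in signal-to-noise at equal measurement time (continuous-limit bound:
RMS/mean of the window ≈ 1.17).

The package is aimed at spectroscopists who want to

* generate the per-increment scan schedule and the **TopSpin
  variable-counter list (vclist)** from a linewidth estimate
  (`build_schedule()`, `write_vclist()`),
* simulate conventional vs DNS interferograms with a per-scan noise model
  and scalar J-coupling modulation (`nmr_peaks()`, `acquire()`),
* process them (NS_cont/NS_disc smoothing, exponential-cosine apodization,
  qsine truncation compensation, zero-filled FT), and
* quantify resolution/sensitivity gains and robustness to a misestimated R₂
  (`measure_fwhh()`, `measure_snr()`, `compare_strategies()`,
  `robustness_scan()`).

## Worked example

A 334 Hz peak-width estimate (R₂ ≈ 1049 s⁻¹ ≈ 1050 at three significant
figures), *f* = 0.5, a 29.53 µs indirect dwell, 4 scans in the first
increment and a 4-step phase cycle:

```r
library(dnsnmr)
params <- acquisition_params(fwhh = 334, f = 0.5, dwell = 2.953e-5)
sched  <- build_schedule(params)
sched
#> DNS sampling schedule
#>   R2 = 1049.29 1/s, f = 0.5 -> R_enh = 524.646 1/s
#>   n_t1 = 304 (1216 stored FIDs), dwell = 2.953e-05 s, t_max = 8.948 ms
#>   omega_apo = 175.555 rad/s
#>   scans: first = 4, max = 52, total = 8260
#>   time-equivalent uniform scans = 27.17 (uniform experiment: 28)
write_vclist(sched, "vclist")   # 1216 lines, one integer per stored FID
```

304 distinct t₁ values are sampled (1216 stored FIDs under hypercomplex
replication), the scan count ramps from 4 up to 52 and back to the
phase-cycle floor, and the whole schedule costs the same measurement time as
a uniform 28-scan experiment — 28 being the phase-cycle-feasible scan count
a matched conventional experiment would use.

Comparing strategies on a synthetic 180 Hz Lorentzian at equal scan budget:

```r
model <- nmr_peaks(offset = 0, fwhh = 180)
compare_strategies(model, noise_model(0.5, seed = 1), params, n_seeds = 50)
#> Strategy comparison (50 noise realizations, LOD threshold 3)
#>      strategy   fwhh   snr snr_se n_peaks_lod total_scans
#>  conventional 179.80 35.97  0.418           1        8512
#>      apodized  96.71 12.64  0.248           1        8512
#>           dns  96.71 14.63  0.248           1        8260
#>   resolution gain (conventional / DNS): 1.859
#>   SNR gain of DNS vs apodized: 1.158  (vs conventional: 0.4067)
```

DNS and digital apodization narrow the line identically (the net window is
the same — noiselessly the two spectra are proportional to machine
precision), both pay a sensitivity price relative to the unwindowed
conventional spectrum, and DNS keeps a ~16% SNR edge over apodization at
this discretization. `robustness_scan()` shows the gain surviving a two-fold
overestimate of R₂ and fading toward 1 under a two-fold underestimate.

The same workflow is available from a shell via the installed `exec/dnsnmr`
script (`schedule`, `simulate`, `process`, `compare`, `robustness`
subcommands; every flag can also come from a `key = value` config file).

## Acceptance script

`scripts/acceptance.R` rebuilds the headline quantities from scratch with
the installed package — the time-equivalent uniform scan count of the
default schedule, the seed-averaged SNR advantage of DNS over matched
post-acquisition apodization, and the noiseless resolution gain for a
180 Hz Lorentzian at the R₂ = 1050 s⁻¹ operating point — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/schedule.R` — weighting, quantization, schedule construction
* `R/signal.R` — peak models, noise model, summed-scan acquisition
* `R/processing.R` — smoothing, windows, Fourier transform
* `R/analysis.R` — FWHH/SNR/LOD, strategy comparison, robustness scan
* `R/io.R` — vclist, peak-model, interferogram, spectrum, config formats
* `R/cli.R` + `exec/dnsnmr` — command-line surface
* `vignettes/dns-acquisition.Rmd` — model, assumptions and design choices
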