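---
title: "Dynamic-number-of-scans acquisition: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-number-of-scans acquisition: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnsnmr)
```

## The method

Resolution in the indirect dimension of a 2D NMR experiment is limited by how
far the evolution time $t_1$ is sampled relative to the effective transverse
decay time $T_2^*$. Dynamic-number-of-scans (DNS) acquisition varies the
number of co-added scans per $t_1$ increment,

$$
\mathrm{ns}(t_1) \;=\; N_1\, e^{R_\mathrm{enh} t_1} \cos(\omega_\mathrm{apo} t_1),
\qquad R_\mathrm{enh} = R_2 (1 - f),
$$

so that the growing exponential cancels a fraction $f$ of the signal decay
$e^{-R_2 t_1}$ *physically, during acquisition*. The stored (summed) FID then
decays with the reduced rate $R_2 f$; for the default $f = 0.5$ the apparent
linewidth is halved. The cosine factor rolls the scan count back to zero so
the experiment time stays finite; its quarter period sets the sampled
interval, $t_\mathrm{max} = 3\pi / (2 R_\mathrm{enh})$, and
$\omega_\mathrm{apo} = (\pi/2)/\big((n_{t_1}-1)\,\Delta t\big)$ places the
cosine zero exactly on the last sampled point. The number of distinct $t_1$
values is $n_{t_1} = \mathrm{round}\!\big(\tfrac{3}{4}\cdot
2\pi/(R_\mathrm{enh}\Delta t)\big)$; four FIDs are stored per $t_1$ value
(hypercomplex acquisition), which is what a variable-counter list enumerates.

The same net window could be applied digitally to a conventionally acquired
data set ($e^{R_\mathrm{enh}t}\cos(\omega_\mathrm{apo}t)$ apodization), and
noiselessly the two routes give proportional spectra — a property the test
suite verifies to $10^{-6}$ relative error. They differ in noise: DNS
accumulates many scans exactly where the FID is weak, so the late-point noise
variance is $\sigma^2(t) = \sigma_0^2 / \mathrm{ns}(t)$ *per averaged scan*
(here: $\mathrm{ns}(t)\sigma_0^2$ for the summed point whose signal grew by
$\mathrm{ns}(t)$), whereas digital apodization amplifies the full thermal
noise of the late increments. At equal total measurement time the predicted
SNR ratio is $\mathrm{RMS}(w)/\mathrm{mean}(w) \approx 1.17$ for the
continuous window $w$ at $f = 0.5$; Cauchy–Schwarz guarantees it is $\ge 1$.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `r2` / `fwhh` | s$^{-1}$ / Hz | — | decay-rate estimate, $R_2 = \pi\,\mathrm{FWHH}$; sets $t_\mathrm{max}$ and the ramp |
| `f` | — | 0.5 | fraction of the decay cancelled; 0.5 halves the linewidth |
| `dwell` | s | — | indirect increment $\Delta t$ (from the spectral width) |
| `n1` | scans | 4 | scan count of the first increment |
| `step` | scans | 4 | phase-cycle size; every count is a multiple of it |
| `replication` | — | 4 | stored FIDs per $t_1$ value in the vclist |

`discretize_scans()` quantizes the continuous counts to the nearest multiple
of `step` (ties up), floored at one full phase cycle, and the first increment
is forced to exactly `n1`. The quantization leaves small steps on the FID
envelope; `smoothing_window()` corrects them by the ratio
$\mathrm{NS}_\mathrm{cont}/\mathrm{NS}_\mathrm{disc}$, restoring the
continuous envelope exactly in the noiseless case.

**The 28-scan equivalence.** The mean of the quantized list at the defaults
is $\approx 27.2$ scans (the continuous-limit mean is
$6.896\,N_1 = 27.6$). A matched *uniform* experiment cannot run a fractional
or non-phase-cycle scan count, so the package reports the time-equivalent
uniform experiment as the mean quantized to the phase cycle —
`ns_uniform = 28` — alongside the raw mean. This is the reference scan count
used by `compare_strategies()`, mirroring how an equal-time conventional
spectrum would actually be acquired; it gives the uniform reference a
$\sim$3% scan-budget advantage rather than handicapping it.

## What the simulator emulates — and what it does not

`ideal_fid()` builds the indirect-dimension interferogram of a peak list:
complex exponentials at each offset, Lorentzian
($e^{-\pi F t}$) or Gaussian ($e^{-(\pi F t)^2/(4\ln 2)}$, an
inhomogeneous-broadening stand-in) envelopes calibrated so the fully relaxed
linewidth equals the nominal FWHH, and $\prod_j \cos(\pi J_j t)$ modulation
for scalar couplings — the factor that splits peaks once the acquisition
time approaches $1/(2J)$ ($\approx 13$ ms for the 35–38 Hz carbon–carbon
couplings, which is what caps DNS acquisition times in uniformly labelled
samples). `acquire()` sums `ns` scans per point with independent complex
Gaussian noise of standard deviation $\sigma_0$ per scan and quadrature
channel; the sum is drawn as a single Gaussian of standard deviation
$\sigma_0\sqrt{\mathrm{ns}}$, which is distributionally identical and keeps
the seed contract simple (identical inputs give bit-identical output).

Not emulated: the direct dimension (the method acts only on $t_1$),
coherence-transfer dynamics (CP/DARR/TEDOR efficiencies), decoupling
imperfections, MAS-rate dependence, $B_0$/temperature drift, and real
lineshape heterogeneity. A green simulation therefore establishes the
*windowing and noise accounting* of the method — not that a particular real
sample will show a given peak count. The default robustness examples use
Lorentzian lines; the true lineshape of heterogeneous capsid samples is not
known, so `shape` is exposed as a parameter.

## Numerical choices

* **Spectrum pipeline.** First point halved before the FFT (baseline-offset
  convention), zero-filling to 8 times the next power of two (linewidth
  interpolation error < 1%), real-part display with zero phase (simulated
  signals carry none). Frequencies span $\pm 1/(2\Delta t)$.
* **FWHH.** Local maximum near the requested position; half-height crossings
  by linear interpolation between bins. A missing local maximum is a
  `dnsnmr_peak_error`, not a silent `NA`.
* **SNR.** Peak maximum over the rmsd about the mean of a stated peak-free
  region ("sino" convention). An rmsd at the double-precision floor of the
  spectrum ($\le 10^{-12}$ of the maximum) reports `Inf` — a Lorentzian tail
  in the "noise" region is genuine signal and yields a finite value.
* **qsine.** `cos^2(\pi t/(2 t_\mathrm{max}))` (TopSpin QSINE, SSB = 2,
  maximum at the first point) — the conventional truncation-suppressing
  choice when no other shift is specified.
* **Quantization ties.** Half-way cases round up (`floor(x/step + 0.5)`),
  never to zero scans.
* **Eq.-count rounding.** $n_{t_1}$ rounds to the nearest integer; because
  of this rounding the last sample can sit up to $1.5\,\Delta t$ in
  rate–time away from the nominal $3\pi/2$ pinning.
* **Grid-mean accuracy.** The mean of the continuous counts over the grid
  carries a left-Riemann error of about $-25/n_{t_1}$, i.e. below 1% for
  $n_{t_1} \ge 100$; the closed-form check in the tests evaluates the
  antiderivative at the schedule's actual $(R_\mathrm{enh} t_\mathrm{max},
  \omega_\mathrm{apo} t_\mathrm{max})$.

## Design choices that were genuinely open

* **Stored FIDs vs distinct $t_1$ values.** The factor 4 in the increment
  count is interpreted as hypercomplex replication: weighting and
  apodization frequency are evaluated on the $n_{t_1}$ distinct $t_1$
  values, and the vclist repeats each count four times. Using the stored-FID
  count inside the weighting would quadruple $t_\mathrm{max}$ and produce
  schedules whose scan counts explode; the chosen reading reproduces the
  $\approx 9$ ms acquisition cap of a 1050 s$^{-1}$ schedule.
* **Uniform reference scan count.** Quantized mean (28), as argued above.
* **Robustness protocol.** `robustness_scan()` rebuilds the schedule from
  $k \cdot R_2^\mathrm{true}$, simulates noiselessly, and applies the qsine
  compensation only for $k \ge 3$, where the weighted FID is visibly
  truncated; the report records whether qsine was applied. Under-estimation
  ($k = 0.5$) leaves a residual decay of $0.75\,R_2$, so the noiseless
  linewidth gain tends toward (but does not reach) 1; in practice the
  sensitivity penalty of the slow scan ramp is what erases the benefit.
* **Comparison geometry.** Resolution gains are always referenced to the
  conventionally acquired, unapodized spectrum with the same $n_{t_1}$ and
  scan budget. SNR averages use 200 seeded realizations by default and are
  reported with standard errors; the LOD threshold defaults to SNR $\ge 3$
  and is configurable.

## Worked example

```{r example}
params <- acquisition_params(fwhh = 334, f = 0.5, dwell = 2.953e-5,
                             n1 = 4, step = 4)
sched <- build_schedule(params)
sched

model <- nmr_peaks(offset = 0, fwhh = 180)
rep <- compare_strategies(model, noise_model(0.5, seed = 1), params,
                          n_seeds = 50)
rep

robustness_scan(model, params, k = c(0.5, 1, 2, 3, 4))
```

The resolution gain of about 1.9 at this operating point and the
$\sim$15% SNR advantage of DNS over digital apodization (the continuous-limit
bound is 17.5%; phase-cycle quantization and the uniform reference's rounded-up
scan budget account for the difference) are exactly the numbers the
acceptance script recomputes.

## Known limitations

* The simulator's equal-budget comparison gives the uniform reference the
  small scan-budget advantage of rounding up to a full phase cycle; gains
  are therefore conservative.
* Linear prediction is incompatible with the cosine-weighted envelope and is
  deliberately absent, as are phase and baseline correction.
* No real spectrometer data are read; the vclist writer and the text
  interferogram/spectrum formats are the exchange surface.
```
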