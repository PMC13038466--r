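# Spectrum analysis: linewidths, SNR, LOD counts, strategy comparison and
# robustness to decay-rate misestimation.

long_axis_spectrum <- function(shape, fwhh = 180, offset = 0) {
  # acquisition much longer than T2* so the measured width is the nominal one
  m <- nmr_peaks(offset = offset, fwhh = fwhh, shape = shape)
  fid <- acquire(m, noise_model(0), 1, dwell = 4e-5, n_t1 = 1024)
  to_spectrum(fid)
}

test_that("FWHH measurement recovers nominal Lorentzian and Gaussian widths", {
  expect_equal(measure_fwhh(long_axis_spectrum("lorentzian"), 0), 180,
               tolerance = 0.01)
  expect_equal(measure_fwhh(long_axis_spectrum("gaussian"), 0), 180,
               tolerance = 0.01)
  # matched-R2 DNS weighting narrows the same line
  sched <- op_schedule()
  quiet <- noise_model(0)
  m <- lorentz_model()
  conv <- to_spectrum(acquire(m, quiet, 4, dwell = sched$params$dwell,
                              n_t1 = sched$n_t1))
  dns <- to_spectrum(apply_smoothing(acquire(m, quiet, sched), sched))
  expect_lt(measure_fwhh(dns, 0), measure_fwhh(conv, 0))
})

test_that("FWHH errors when no local maximum exists near the position", {
  sp <- long_axis_spectrum("lorentzian", offset = 0)
  expect_error(measure_fwhh(sp, position = 8000, search_hz = 500),
               class = "dnsnmr_peak_error")
})

test_that("SNR: sentinel, linearity and sqrt(total scans) scaling", {
  # noiseless sentinel: a Gaussian line leaves the far field at the numerical
  # floor (a Lorentzian's tail is genuine signal there, so SNR stays finite)
  sp0 <- long_axis_spectrum("gaussian")
  expect_identical(measure_snr(sp0, 0, noise_region = c(5000, 9000)), Inf)
  dwell <- 4e-5; n_t1 <- 256L
  region <- c(5000, 9000)
  snr_of <- function(amp, scans, seed) {
    m <- nmr_peaks(offset = 0, fwhh = 180, amplitude = amp)
    fid <- acquire(m, noise_model(0.5, seed), scans, dwell = dwell, n_t1 = n_t1)
    measure_snr(to_spectrum(fid), 0, region)
  }
  # doubling the amplitude at fixed noise draw roughly doubles the SNR
  expect_equal(snr_of(2, 16L, 11) / snr_of(1, 16L, 11), 2, tolerance = 0.05)
  # uniform acquisition: SNR grows as sqrt(total scans)
  mean_snr <- function(scans) mean(vapply(1:80, function(i)
    snr_of(1, scans, 300 + i), numeric(1)))
  expect_equal(mean_snr(64L) / mean_snr(16L), 2, tolerance = 0.1)
  expect_error(measure_snr(sp0, 0, noise_region = c(1e6, 2e6)),
               class = "dnsnmr_param_error")
})

test_that("LOD counting: noiseless and pure-noise limits", {
  offs <- c(-4000, -1500, 1000, 3500)
  m <- nmr_peaks(offset = offs, fwhh = 150)
  fid <- acquire(m, noise_model(0), 4, dwell = 4e-5, n_t1 = 512)
  sp <- to_spectrum(fid)
  expect_identical(count_above_lod(sp, offs, noise_region = c(8000, 12000)), 4L)
  # all-noise spectrum: at most rare threshold exceedances
  empty <- nmr_peaks(numeric(0), numeric(0))
  fid0 <- acquire(empty, noise_model(1, 21), 4, dwell = 4e-5, n_t1 = 512)
  n0 <- count_above_lod(to_spectrum(fid0), offs, noise_region = c(8000, 12000))
  expect_lte(n0, 1L)
})

test_that("DNS keeps at least as many graded peaks above the LOD as apodization", {
  # graded-amplitude peak ladder at fixed per-scan noise, equal scan budget
  sched <- op_schedule()
  n_pk <- 50L
  offs <- seq(-14000, 14000, length.out = n_pk)
  amps <- seq(0.02, 1, length.out = n_pk)
  m <- nmr_peaks(offset = offs, fwhh = 180, amplitude = amps)
  nm <- noise_model(2, seed = 17)
  region <- c(15500, 16500)
  dns <- to_spectrum(apply_smoothing(acquire(m, nm, sched), sched))
  conv <- acquire(m, nm, sched$ns_uniform, dwell = sched$params$dwell,
                  n_t1 = sched$n_t1)
  apo <- to_spectrum(exp_cos_apodize(conv, sched$r_enh, sched$omega_apo))
  n_dns <- count_above_lod(dns, offs, region, search_hz = 120)
  n_apo <- count_above_lod(apo, offs, region, search_hz = 120)
  expect_gte(n_dns, n_apo)
  expect_gt(n_dns, 0L)
  expect_lt(n_dns, n_pk)  # the ladder actually straddles the LOD
})

test_that("strategy comparison: ordering, gains and the analytic noise oracle", {
  m <- lorentz_model()
  nm <- noise_model(0.5, seed = 31)
  params <- op_params()
  rep <- compare_strategies(m, nm, params, n_seeds = 60)
  tab <- rep$table
  expect_identical(tab$strategy, c("conventional", "apodized", "dns"))
  # sensitivity ordering at equal budget
  snr <- structure(tab$snr, names = tab$strategy)
  expect_gt(snr[["conventional"]], snr[["dns"]])
  expect_gt(snr[["dns"]], snr[["apodized"]])
  # resolution gain at the published operating point (R2,est/R2,true ~ 1.86)
  expect_gt(rep$resolution_gain, 1.8)
  expect_lt(rep$resolution_gain, 2.2)
  # simulation matches the exact discretized window oracle
  sched <- rep$schedule
  w <- sched$ns_cont
  oracle <- (sum(w) / sqrt(sum(w^2 / sched$ns_disc))) /
    (sqrt(sched$ns_uniform) * sum(w) / sqrt(sum(w^2)))
  expect_equal(rep$snr_gain_vs_apodized, oracle, tolerance = 0.03)
  expect_equal(window_snr_gain(sched), oracle, tolerance = 1e-10)
  # and sits a discretization step below the continuous-limit RMS/mean bound
  expect_equal(oracle, 1.1749, tolerance = 0.03)
  expect_gt(oracle, 1)
})

test_that("budget mismatches are rejected", {
  m <- lorentz_model()
  expect_error(
    compare_strategies(m, noise_model(0.5), op_params(), n_seeds = 2,
                       uniform_scans = 56L),
    class = "dnsnmr_budget_error")
})

test_that("matched-estimate robustness: gain bands and trend", {
  m <- lorentz_model()  # R2,true = pi * 180 = 565 1/s
  tab <- robustness_scan(m, op_params(), k = c(0.5, 1, 2, 3, 4))
  g <- structure(tab$gain, names = as.character(tab$k))
  expect_gt(g[["1"]], 1.6)   # matched estimate
  expect_lt(g[["1"]], 2.1)
  expect_gt(g[["2"]], 1.8)   # two-fold overestimate retains the factor ~2
  expect_lt(g[["2"]], 2.2)
  # beyond two-fold the gain decays; qsine is applied from k = 3
  expect_lte(g[["3"]], g[["2"]])
  expect_lte(g[["4"]], g[["3"]])
  expect_identical(tab$qsine, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # underestimation approaches no benefit
  expect_lt(g[["0.5"]], g[["1"]])
  expect_lt(g[["0.5"]], 1.5)
  expect_gte(g[["0.5"]], 1)
})

test_that("J coupling inflates the DNS linewidth once t_max passes 1/(2J)", {
  # slow decay: schedule t_max ~ 30 ms > 1/(2*35 Hz) = 14.3 ms
  params <- acquisition_params(fwhh = 100, dwell = 2.953e-5)
  sched <- build_schedule(params)
  expect_gt(sched$t_max, 1 / (2 * 35))
  quiet <- noise_model(0)
  plain <- nmr_peaks(offset = 0, fwhh = 100)
  coupled <- nmr_peaks(offset = 0, fwhh = 100, j = list(35))
  w_plain <- measure_fwhh(to_spectrum(
    apply_smoothing(acquire(plain, quiet, sched), sched)), 0)
  w_coupled <- measure_fwhh(to_spectrum(
    apply_smoothing(acquire(coupled, quiet, sched), sched)), 0)
  expect_gt(w_coupled, w_plain)
})
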