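# DNS sampling schedules: from an R2 (or linewidth) estimate to the
# per-increment scan counts written into a TopSpin variable-counter list.
#
# The scan count per t1 increment follows an exponential-cosine weighting
#   ns(t) = N1 * exp(R_enh * t) * cos(omega_apo * t)
# with R_enh = R2 * (1 - f). The growing exponential counteracts the signal
# decay exp(-R2 * t), leaving an apparent decay of R2 * f; the cosine rolls
# the scan count back to zero at the end of the sampled interval so that the
# total experiment time stays finite and the effective window is apodized.

#' Convert a peak width to a transverse decay rate
#'
#' The effective transverse decay rate of a Lorentzian line relates to its
#' full width at half height (FWHH) as `R2 = pi * FWHH`.
#'
#' @param fwhh Full width at half height in Hz (non-negative).
#' @return Decay rate \eqn{R_2} in s\eqn{^{-1}}.
#' @examples
#' r2_from_fwhh(334)  # ~1049.3, i.e. 1050 at three significant figures
#' @seealso [fwhh_from_r2()], [build_schedule()]
#' @export
r2_from_fwhh <- function(fwhh) {
  check_number(fwhh, "fwhh", lower = 0)
  pi * fwhh
}

#' @rdname r2_from_fwhh
#' @param r2 Decay rate in s\eqn{^{-1}} (non-negative).
#' @export
fwhh_from_r2 <- function(r2) {
  check_number(r2, "r2", lower = 0)
  r2 / pi
}

#' Enhanced (reduced) decay rate targeted by the weighting
#'
#' `R_enh = R2 * (1 - f)`: the apparent decay rate left after the exponential
#' part of the weighting has cancelled a fraction `f` of the true decay.
#' `f = 0.5` halves the apparent linewidth.
#'
#' @param r2 Estimated transverse decay rate, s\eqn{^{-1}} (> 0).
#' @param f Resolution-enhancement (reduction) factor in \[0, 1\].
#' @return Enhanced rate in s\eqn{^{-1}}. A value of 0 (from `f = 1`) is
#'   returned as such but is rejected by downstream schedule construction,
#'   where it would imply an infinite acquisition time.
#' @export
enhanced_rate <- function(r2, f) {
  check_number(r2, "r2", lower = 0, strict_lower = TRUE)
  check_number(f, "f", lower = 0, upper = 1)
  r2 * (1 - f)
}

#' Number of indirect-dimension time points for a DNS schedule
#'
#' The sampled interval is pinned near `t_max = 3*pi / (2 * R_enh)` (three
#' quarters of a full period of the apodizing cosine's quarter-wave, i.e.
#' `(3/4) * 2*pi / R_enh`), giving
#' `n_t1 = round((3/4) * 2*pi / (r_enh * dwell))` distinct t1 values.
#' The stored-FID count is `4 * n_t1`: hypercomplex (States-type) acquisition
#' stores four FIDs per t1 value.
#'
#' @param r_enh Enhanced decay rate, s\eqn{^{-1}} (> 0).
#' @param dwell Indirect-dimension increment \eqn{\Delta t} in seconds (> 0).
#' @return A list with integer elements `n_t1` (distinct t1 values) and
#'   `n_increment = 4 * n_t1` (stored FIDs).
#' @export
n_time_points <- function(r_enh, dwell) {
  check_number(r_enh, "r_enh", lower = 0, strict_lower = TRUE)
  check_number(dwell, "dwell", lower = 0, strict_lower = TRUE)
  n_t1 <- as.integer(round(0.75 * 2 * pi / (r_enh * dwell)))
  if (n_t1 < 2L)
    stop_param(sprintf(
      "r_enh * dwell = %g is too large: fewer than 2 indirect time points",
      r_enh * dwell))
  list(n_t1 = n_t1, n_increment = 4L * n_t1)
}

#' Apodization frequency of the cosine weighting
#'
#' `omega_apo = (pi/2) / ((n_t1 - 1) * dwell)`: the cosine term reaches zero
#' exactly at the last sampled t1 value `t_max = (n_t1 - 1) * dwell`.
#'
#' @param n_t1 Number of distinct t1 values (>= 2).
#' @param dwell Indirect increment in seconds (> 0).
#' @return Angular frequency in rad/s.
#' @export
apodization_frequency <- function(n_t1, dwell) {
  n_t1 <- check_count(n_t1, "n_t1")
  check_number(dwell, "dwell", lower = 0, strict_lower = TRUE)
  if (n_t1 < 2L) stop_param("`n_t1` must be >= 2")
  (pi / 2) / ((n_t1 - 1) * dwell)
}

#' Continuous (real-valued) scan count at evolution time t
#'
#' Evaluates the exponential-cosine weighting
#' `ns(t) = n1 * exp(r_enh * t) * cos(omega_apo * t)`.
#'
#' @param t Evolution time(s) in seconds.
#' @param n1 Scan count of the first increment.
#' @param r_enh Enhanced decay rate, s\eqn{^{-1}}.
#' @param omega_apo Apodization angular frequency, rad/s.
#' @return Real-valued scan counts, same length as `t`.
#' @export
continuous_scans <- function(t, n1, r_enh, omega_apo) {
  n1 * exp(r_enh * t) * cos(omega_apo * t)
}

#' Quantize scan counts to the phase cycle
#'
#' Rounds to the nearest multiple of `step` with half-way cases rounded up,
#' floored at one full phase cycle (`step`): a spectrometer cannot acquire
#' zero or fractional phase-cycle blocks.
#'
#' @param ns_cont Continuous scan count(s) (non-negative).
#' @param step Phase-cycle size, a positive integer.
#' @return Integer scan counts, multiples of `step`.
#' @examples
#' discretize_scans(53.6, 4)  # 52
#' discretize_scans(1.0, 4)   # 4 (floor at one phase cycle)
#' discretize_scans(6.0, 4)   # 8 (half-way rounds up)
#' @export
discretize_scans <- function(ns_cont, step) {
  if (!is.numeric(ns_cont) || any(!is.finite(ns_cont)) || any(ns_cont < 0))
    stop_param("`ns_cont` must be finite and non-negative")
  step <- check_count(step, "step")
  as.integer(pmax(step, step * floor(ns_cont / step + 0.5)))
}

#' Acquisition parameters for a DNS schedule
#'
#' Bundles and validates the user-facing inputs that fully determine a DNS
#' sampling schedule. Exactly one of `r2` or `fwhh` must be supplied; with
#' `fwhh` the rate is derived as `R2 = pi * FWHH`.
#'
#' @param r2 Estimated transverse decay rate in s\eqn{^{-1}} (> 0).
#' @param fwhh Estimated peak full width at half height in Hz (> 0),
#'   alternative to `r2`.
#' @param f Resolution-enhancement factor, strictly between 0 and 1
#'   (default 0.5, which halves the apparent linewidth).
#' @param dwell Indirect-dimension increment \eqn{\Delta t} in seconds.
#' @param n1 Scan count of the first increment (integer multiple of `step`).
#' @param step Phase-cycle size: the minimum granularity of any scan count.
#' @param replication How many stored FIDs share each t1 value in the
#'   variable-counter list (4 for hypercomplex acquisition).
#' @return An object of class `dns_params`.
#' @seealso [build_schedule()]
#' @export
acquisition_params <- function(r2 = NULL, fwhh = NULL, f = 0.5, dwell,
                               n1 = 4L, step = 4L, replication = 4L) {
  if (is.null(r2) == is.null(fwhh))
    stop_param("supply exactly one of `r2` or `fwhh`")
  if (is.null(r2)) {
    check_number(fwhh, "fwhh", lower = 0, strict_lower = TRUE)
    r2 <- r2_from_fwhh(fwhh)
  }
  check_number(r2, "r2", lower = 0, strict_lower = TRUE)
  check_number(f, "f", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(dwell, "dwell", lower = 0, strict_lower = TRUE)
  n1 <- check_count(n1, "n1")
  step <- check_count(step, "step")
  replication <- check_count(replication, "replication")
  if (n1 < step) stop_param("`n1` must be >= `step`")
  if (n1 %% step != 0L)
    stop_param("`n1` must be an integer multiple of `step`")
  structure(
    list(r2 = r2, fwhh = r2 / pi, f = f, dwell = dwell,
         n1 = n1, step = step, replication = replication),
    class = "dns_params")
}

#' Build a DNS sampling schedule
#'
#' Derives the full per-increment scan-count schedule from acquisition
#' parameters: enhanced rate, time grid, apodization frequency, continuous
#' and phase-cycle-quantized scan counts, and scan-budget summaries.
#'
#' The first increment is forced to exactly `n1`. The time-equivalent
#' uniform scan count is reported three ways: `ns_equivalent` (the raw mean
#' of the quantized list), its nearest integer, and `ns_uniform`, the mean
#' quantized to the phase cycle with [discretize_scans()] - the scan count a
#' matched conventional experiment would actually use, since uniform
#' acquisition is also restricted to multiples of the phase cycle.
#'
#' @param params A `dns_params` object from [acquisition_params()], or `NULL`
#'   to build one from `...`.
#' @param ... Arguments forwarded to [acquisition_params()] when `params` is
#'   not supplied.
#' @return An object of class `dns_schedule`: a list with elements `params`,
#'   `r_enh`, `n_t1`, `n_increment`, `t`, `t_max`, `omega_apo`, `ns_cont`,
#'   `ns_disc`, `total_scans`, `ns_equivalent`, `ns_uniform`.
#' @examples
#' sched <- build_schedule(acquisition_params(r2 = 1050, dwell = 2.953e-5))
#' sched$n_t1        # 304 distinct t1 values (1216 stored FIDs)
#' sched$ns_uniform  # 28: the matched uniform-experiment scan count
#' @export
build_schedule <- function(params = NULL, ...) {
  if (is.null(params)) params <- acquisition_params(...)
  if (!inherits(params, "dns_params"))
    stop_param("`params` must be created by acquisition_params()")
  r_enh <- enhanced_rate(params$r2, params$f)
  if (r_enh <= 0)
    stop_param("enhanced rate is zero (f = 1): acquisition time is unbounded")
  np <- n_time_points(r_enh, params$dwell)
  t <- (seq_len(np$n_t1) - 1) * params$dwell
  omega_apo <- apodization_frequency(np$n_t1, params$dwell)
  ns_cont <- continuous_scans(t, params$n1, r_enh, omega_apo)
  # the cosine zero at t_max can land a few ulp below zero
  ns_cont[ns_cont < 0 & ns_cont > -1e-6] <- 0
  ns_disc <- discretize_scans(ns_cont, params$step)
  ns_disc[1L] <- params$n1
  total <- sum(ns_disc)
  ns_eq <- total / np$n_t1
  structure(
    list(params = params,
         r_enh = r_enh,
         n_t1 = np$n_t1,
         n_increment = np$n_increment,
         t = t,
         t_max = t[np$n_t1],
         omega_apo = omega_apo,
         ns_cont = ns_cont,
         ns_disc = ns_disc,
         total_scans = total,
         ns_equivalent = ns_eq,
         ns_uniform = discretize_scans(ns_eq, params$step)),
    class = "dns_schedule")
}

#' @export
print.dns_params <- function(x, ...) {
  cat("DNS acquisition parameters\n")
  cat(sprintf("  R2 = %s 1/s (FWHH %s Hz), f = %g\n",
              fmt_num(x$r2), fmt_num(x$fwhh, 4), x$f))
  cat(sprintf("  dwell = %s s, n1 = %d, phase-cycle step = %d, replication = %d\n",
              fmt_num(x$dwell), x$n1, x$step, x$replication))
  invisible(x)
}

#' @export
print.dns_schedule <- function(x, ...) {
  cat("DNS sampling schedule\n")
  cat(sprintf("  R2 = %s 1/s, f = %g -> R_enh = %s 1/s\n",
              fmt_num(x$params$r2), x$params$f, fmt_num(x$r_enh)))
  cat(sprintf("  n_t1 = %d (%d stored FIDs), dwell = %s s, t_max = %s ms\n",
              x$n_t1, x$n_increment, fmt_num(x$params$dwell),
              fmt_num(1e3 * x$t_max, 4)))
  cat(sprintf("  omega_apo = %s rad/s\n", fmt_num(x$omega_apo)))
  cat(sprintf("  scans: first = %d, max = %d, total = %d\n",
              x$ns_disc[1L], max(x$ns_disc), x$total_scans))
  cat(sprintf("  time-equivalent uniform scans = %s (uniform experiment: %d)\n",
              fmt_num(x$ns_equivalent, 4), x$ns_uniform))
  invisible(x)
}
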