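# Interferogram-to-spectrum processing: smoothing of the phase-cycle
# discretization, post-acquisition windows and Fourier transformation.

#' Smoothing window correcting phase-cycle discretization
#'
#' The per-increment correction `ns_cont / ns_disc`: the scan count that
#' should have been acquired divided by the count that was feasible given
#' the phase cycle. Multiplying a DNS interferogram by these weights
#' restores the continuous exponential-cosine envelope exactly in the
#' noiseless case.
#'
#' @param schedule A [build_schedule()] object.
#' @return Numeric weights, one per t1 value.
#' @seealso [apply_smoothing()]
#' @export
smoothing_window <- function(schedule) {
  if (!inherits(schedule, "dns_schedule"))
    stop_param("`schedule` must be a dns_schedule")
  schedule$ns_cont / schedule$ns_disc
}

#' Apply the smoothing window to a DNS interferogram
#'
#' @param fid An [acquire()]d `nmr_interferogram`.
#' @param schedule The schedule the interferogram was acquired with.
#' @return The interferogram with smoothed values and updated provenance.
#' @export
apply_smoothing <- function(fid, schedule) {
  check_fid(fid)
  w <- smoothing_window(schedule)
  if (length(w) != length(fid$values))
    stop_runtime("schedule length does not match the interferogram",
                 class = "dnsnmr_shape_error")
  fid$values <- fid$values * w
  fid$provenance <- c(fid$provenance, "smoothing")
  fid
}

#' Post-acquisition exponential-cosine apodization
#'
#' Multiplies point `k` by `exp(r_enh * t_k) * cos(omega_apo * t_k)`: the
#' same resolution-enhancing window that DNS acquisition applies physically,
#' here applied digitally to a conventionally acquired interferogram.
#'
#' @param fid An `nmr_interferogram`.
#' @param r_enh Enhanced decay rate, s\eqn{^{-1}}.
#' @param omega_apo Apodization angular frequency, rad/s.
#' @return The apodized interferogram.
#' @export
exp_cos_apodize <- function(fid, r_enh, omega_apo) {
  check_fid(fid)
  fid$values <- fid$values * exp(r_enh * fid$t) * cos(omega_apo * fid$t)
  fid$provenance <- c(fid$provenance, "exp_cos_apodization")
  fid
}

#' Squared sine-bell (qsine) window
#'
#' Multiplies point `k` by `cos(pi * t_k / (2 * t_max))^exponent` with
#' `t_max` the last sampled time: a sine-bell raised to `exponent` with its
#' maximum at `t = 0` and zero at `t_max` (the TopSpin QSINE window with
#' SSB = 2 for `exponent = 2`). Used to suppress truncation (sinc-wiggle)
#' artifacts when the weighted FID has not decayed by `t_max`.
#'
#' @param fid An `nmr_interferogram`.
#' @param exponent Power of the sine bell (2 = qsine).
#' @return The windowed interferogram.
#' @export
qsine_window <- function(fid, exponent = 2) {
  check_fid(fid)
  check_number(exponent, "exponent", lower = 0, strict_lower = TRUE)
  t_max <- fid$t[length(fid$t)]
  fid$values <- fid$values * cos(pi * fid$t / (2 * t_max))^exponent
  fid$provenance <- c(fid$provenance, sprintf("qsine(exponent=%g)", exponent))
  fid
}

#' Fourier transform an interferogram into a spectrum
#'
#' The first point is halved (baseline-offset convention for a signal whose
#' t = 0 sample would otherwise be double-counted), the FID is zero-filled
#' to `zero_fill` times the next power of two, discrete-Fourier transformed
#' and the real (absorption) part returned with a frequency axis in Hz
#' spanning plus/minus half the spectral width `1/dwell`. Simulated signals
#' carry zero phase, so no phase correction is applied.
#'
#' @param fid An `nmr_interferogram`.
#' @param zero_fill Zero-filling factor (>= 1); the default of 8 keeps the
#'   linewidth interpolation error below 1 percent.
#' @return An object of class `nmr_spectrum`: list with `freq` (Hz),
#'   `intensity`, `dwell`, `provenance`.
#' @export
to_spectrum <- function(fid, zero_fill = 8) {
  check_fid(fid)
  check_number(zero_fill, "zero_fill", lower = 1)
  n <- length(fid$values)
  if (n == 0L) stop_param("empty interferogram")
  x <- fid$values
  x[1L] <- x[1L] / 2
  nfft <- as.integer(round(zero_fill * 2^ceiling(log2(n))))
  sp <- stats::fft(c(x, complex(length.out = nfft - n)))
  half <- nfft %/% 2L
  sp <- c(sp[(half + 1L):nfft], sp[1:half])  # fftshift
  freq <- (seq_len(nfft) - 1L - half) / (nfft * fid$dwell)
  structure(
    list(freq = freq, intensity = Re(sp), dwell = fid$dwell,
         provenance = c(fid$provenance, sprintf("fft(zero_fill=%g)", zero_fill))),
    class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %s to %s Hz\n",
              length(x$freq), fmt_num(min(x$freq), 4), fmt_num(max(x$freq), 4)))
  if (length(x$provenance))
    cat("  processing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

check_fid <- function(fid) {
  if (!inherits(fid, "nmr_interferogram"))
    stop_param("expected an nmr_interferogram (see acquire())")
  invisible(fid)
}
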