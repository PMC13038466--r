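# Synthetic indirect-dimension signals: peak models, per-scan noise and
# summed-scan acquisition under uniform or DNS scan schedules.

#' Define a synthetic peak model
#'
#' A peak list for the indirect-dimension simulator. Each peak contributes
#' `A * exp(2i*pi*offset*t) * E(t) * prod_j cos(pi * J_j * t)` to the
#' per-scan signal, where the envelope `E(t)` is `exp(-pi*FWHH*t)` for a
#' Lorentzian line and `exp(-(pi*FWHH*t)^2 / (4*log(2)))` for a Gaussian
#' line; both are normalized so the fully relaxed spectrum has full width at
#' half height equal to `fwhh`. Scalar J couplings modulate the signal with
#' cosines whose first zero crossing falls at `t = 1/(2J)`.
#'
#' @param offset Peak offset(s) from the carrier, Hz.
#' @param fwhh Full width(s) at half height, Hz (> 0).
#' @param amplitude Per-scan amplitude(s) (>= 0), recycled.
#' @param shape `"lorentzian"` or `"gaussian"`, recycled.
#' @param j List of numeric vectors of scalar couplings in Hz (one vector
#'   per peak), or a single vector applied to every peak.
#' @return A data frame of class `nmr_peaks` with a list column `j`.
#' @export
nmr_peaks <- function(offset, fwhh, amplitude = 1, shape = "lorentzian",
                      j = list(numeric(0))) {
  n <- length(offset)
  if (any(!is.finite(offset))) stop_param("`offset` must be finite")
  if (length(fwhh) != n && length(fwhh) != 1L)
    stop_param("`fwhh` must have length 1 or length(offset)")
  fwhh <- rep_len(fwhh, n)
  if (any(fwhh <= 0)) stop_param("`fwhh` must be > 0")
  amplitude <- rep_len(amplitude, n)
  if (any(amplitude < 0)) stop_param("`amplitude` must be >= 0")
  shape <- rep_len(match.arg(shape, c("lorentzian", "gaussian"),
                             several.ok = TRUE), n)
  if (is.numeric(j)) j <- list(j)
  j <- rep_len(j, n)
  out <- data.frame(offset = offset, fwhh = fwhh, amplitude = amplitude,
                    shape = shape, stringsAsFactors = FALSE)
  out$j <- j
  class(out) <- c("nmr_peaks", "data.frame")
  out
}

#' Per-scan noise model
#'
#' @param sigma0 Standard deviation of the complex noise added per scan and
#'   per point, applied independently to the real and imaginary channel.
#' @param seed Integer seed making acquisitions reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma0, seed = 1L) {
  check_number(sigma0, "sigma0", lower = 0)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  structure(list(sigma0 = sigma0, seed = seed), class = "noise_model")
}

#' Ideal (noise-free, per-scan) indirect-dimension FID
#'
#' @param model An [nmr_peaks()] peak list; an empty model gives a zero
#'   signal.
#' @param t Time axis in seconds, starting at 0 with uniform spacing.
#' @return Complex vector of the per-scan signal at each `t`.
#' @export
ideal_fid <- function(model, t) {
  if (length(t) == 0L) stop_param("`t` must be non-empty")
  if (t[1L] != 0) stop_param("`t` must start at 0")
  if (length(t) > 2L && diff(range(diff(t))) > 1e-9 * max(diff(t)))
    stop_param("`t` must be uniformly spaced")
  s <- complex(length.out = length(t))
  if (is.null(model) || nrow(model) == 0L) return(s)
  for (p in seq_len(nrow(model))) {
    env <- switch(model$shape[p],
      lorentzian = exp(-pi * model$fwhh[p] * t),
      gaussian = exp(-(pi * model$fwhh[p] * t)^2 / (4 * log(2))))
    jmod <- rep(1, length(t))
    for (jj in model$j[[p]]) jmod <- jmod * cospi(jj * t)
    s <- s + model$amplitude[p] * exp(2i * pi * model$offset[p] * t) * env * jmod
  }
  s
}

#' Acquire an interferogram with summed scans
#'
#' Simulates spectrometer accumulation: the stored value at `t_k` is the sum
#' over `ns(t_k)` scans of the per-scan signal plus independent complex
#' Gaussian noise of standard deviation `sigma0` per quadrature component.
#' The stored point therefore has expectation `ns(t_k) * s(t_k)` and noise
#' variance `ns(t_k) * sigma0^2` per component: under DNS the scan-count
#' envelope is the exponential-cosine weighting applied physically. (The sum
#' over scans is drawn as a single Gaussian with standard deviation
#' `sigma0 * sqrt(ns)`, which has the identical distribution.)
#'
#' @param model An [nmr_peaks()] peak list.
#' @param noise A [noise_model()]; draws are seeded and do not disturb the
#'   session RNG.
#' @param scans A [build_schedule()] object (DNS acquisition on the
#'   schedule's own time grid), or a single scan count, or a vector of
#'   per-point scan counts (uniform/custom acquisition; `dwell` and, for a
#'   scalar, `n_t1` must then be given).
#' @param dwell Indirect increment in seconds (taken from the schedule when
#'   `scans` is a `dns_schedule`).
#' @param n_t1 Number of t1 values when `scans` is a single number.
#' @return An object of class `nmr_interferogram`: list with `values`
#'   (complex), `t`, `dwell`, `scans`, `mode` (`"dns"` or `"conventional"`),
#'   `sigma0`, `seed`.
#' @export
acquire <- function(model, noise, scans, dwell = NULL, n_t1 = NULL) {
  if (!inherits(noise, "noise_model"))
    stop_param("`noise` must be created by noise_model()")
  if (inherits(scans, "dns_schedule")) {
    t <- scans$t
    dwell <- scans$params$dwell
    ns <- scans$ns_disc
    mode <- "dns"
  } else {
    if (is.null(dwell)) stop_param("`dwell` is required when `scans` is numeric")
    if (length(scans) == 1L) {
      if (is.null(n_t1)) stop_param("`n_t1` is required for a single scan count")
      n_t1 <- check_count(n_t1, "n_t1")
      ns <- rep(check_count(scans, "scans"), n_t1)
    } else {
      ns <- vapply(scans, check_count, integer(1), name = "scans")
    }
    t <- (seq_along(ns) - 1) * dwell
    mode <- "conventional"
  }
  if (any(ns <= 0L)) stop_param("scan counts must be positive")
  s <- ideal_fid(model, t)
  if (length(s) != length(ns))
    stop_runtime("schedule length does not match the time axis",
                 class = "dnsnmr_shape_error")
  values <- ns * s
  if (noise$sigma0 > 0) {
    n <- length(ns)
    eps <- with_seed(noise$seed, {
      sd_pt <- noise$sigma0 * sqrt(ns)
      complex(real = stats::rnorm(n, 0, sd_pt),
              imaginary = stats::rnorm(n, 0, sd_pt))
    })
    values <- values + eps
  }
  structure(
    list(values = values, t = t, dwell = dwell, scans = as.integer(ns),
         mode = mode, sigma0 = noise$sigma0, seed = noise$seed),
    class = "nmr_interferogram")
}

#' @export
print.nmr_interferogram <- function(x, ...) {
  cat(sprintf("<nmr_interferogram> %d points, dwell %s s, mode %s\n",
              length(x$values), fmt_num(x$dwell), x$mode))
  cat(sprintf("  scans: %d..%d (total %d), sigma0 = %g, seed = %d\n",
              min(x$scans), max(x$scans), sum(x$scans), x$sigma0, x$seed))
  invisible(x)
}

#' @export
print.nmr_peaks <- function(x, ...) {
  cat(sprintf("<nmr_peaks> %d peak(s)\n", nrow(x)))
  df <- as.data.frame(x)
  df$j <- vapply(df$j, function(v) paste(v, collapse = ";"), character(1))
  print(df)
  invisible(x)
}
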