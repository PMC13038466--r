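# Shared fixtures: the operating point used throughout is the published
# DARR setting (R2 = 1050 1/s from a 334 Hz width, f = 0.5, dwell chosen so
# the schedule has 304 distinct t1 values / 1216 stored FIDs).

op_params <- function(...) {
  acquisition_params(r2 = 1050, f = 0.5, dwell = 2.953e-5,
                     n1 = 4L, step = 4L, ...)
}

op_schedule <- function() build_schedule(op_params())

lorentz_model <- function(fwhh = 180, offset = 0, ...) {
  nmr_peaks(offset = offset, fwhh = fwhh, ...)
}

# A grid of (r2, dwell) pairs whose schedules all have >= 100 t1 values,
# used for property-style loops.
param_grid <- function() {
  expand.grid(r2 = c(400, 700, 1050, 2000), dwell = c(1.2e-5, 2.953e-5))
}

# Closed-form mean of exp(a x) cos(b x) over [0, 1].
expcos_mean <- function(a, b) {
  (exp(a) * (a * cos(b) + b * sin(b)) - a) / (a^2 + b^2)
}
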