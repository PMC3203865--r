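#' Parametric model of the vibrating stimulation probe
#'
#' Describes the probe-tip oscillation excited by the spring-loaded
#' collision mechanism of the stimulation device: a damped sinusoid with a
#' dominant frequency around 140 Hz and a zero-to-peak excursion around
#' 70 um, the values measured for the device both inside and outside the
#' gel. `damping_time = Inf` disables the decay envelope (a sustained
#' oscillation), which is convenient for spectral characterization.
#'
#' @param frequency Oscillation frequency in Hz (> 0).
#' @param amplitude Zero-to-peak tip excursion in um (>= 0).
#' @param damping_time Exponential decay constant of the envelope in s
#'   (> 0, or `Inf` for no damping).
#' @param duration Trace length in s (> 0).
#' @param sampling_rate Samples per second in Hz; must exceed twice the
#'   oscillation frequency (Nyquist).
#' @return An object of class `equipment_model`.
#' @seealso [generate_probe_trace()]
#' @export
equipment_model <- function(frequency = 140, amplitude = 70,
                            damping_time = 0.1, duration = 0.5,
                            sampling_rate = 10000) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop_param("'frequency' must be a single positive number (Hz)")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop_param("'amplitude' must be a single non-negative number (um)")
  if (!is.numeric(damping_time) || length(damping_time) != 1L ||
      damping_time <= 0)
    stop_param("'damping_time' must be positive (s); use Inf for no damping")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop_param("'duration' must be a single positive number (s)")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 2 * frequency)
    stop_param("'sampling_rate' must exceed 2 * frequency = %g Hz (Nyquist)",
               2 * frequency)
  structure(
    list(frequency = frequency, amplitude = amplitude,
         damping_time = damping_time, duration = duration,
         sampling_rate = sampling_rate),
    class = "equipment_model"
  )
}

#' Generate a probe-tip displacement trace
#'
#' Samples the damped sinusoid
#' `a(t) = amplitude * exp(-t / damping_time) * sin(2 * pi * frequency * t)`
#' at `sampling_rate` over `duration`. The trace is deterministic for a
#' given model; `seed` is reserved for optional timing jitter of the trigger
#' (off by default).
#'
#' @param model An [equipment_model()].
#' @param seed Optional integer seed; only used when `jitter_sd > 0`.
#' @param jitter_sd Standard deviation (s) of a random trigger-time offset;
#'   0 disables jitter.
#' @return A data frame with columns `time_s` and `displacement_um`.
#' @examples
#' tr <- generate_probe_trace(equipment_model(damping_time = Inf))
#' dominant_frequency(tr)  # 140 Hz at the defaults
#' @export
generate_probe_trace <- function(model = equipment_model(), seed = NULL,
                                 jitter_sd = 0) {
  stopifnot(inherits(model, "equipment_model"))
  n <- round(model$duration * model$sampling_rate)
  if (n < 2L) stop_param("trace too short: %d samples", n)
  t <- (seq_len(n) - 1) / model$sampling_rate
  t0 <- 0
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    t0 <- stats::rnorm(1L, 0, jitter_sd)
  }
  env <- if (is.finite(model$damping_time)) {
    exp(-pmax(t - t0, 0) / model$damping_time)
  } else rep(1, n)
  disp <- model$amplitude * env * sin(2 * pi * model$frequency * pmax(t - t0, 0))
  data.frame(time_s = t, displacement_um = disp)
}

#' Dominant frequency of a displacement trace
#'
#' Estimates the dominant oscillation frequency as the location of the peak
#' of the magnitude spectrum (discrete Fourier transform, positive
#' frequencies only). The resolution is one frequency bin,
#' `1 / duration` Hz.
#'
#' @param trace A data frame from [generate_probe_trace()], or a numeric
#'   vector of displacements (then `sampling_rate` is required).
#' @param sampling_rate Samples per second; inferred from the `time_s`
#'   column when `trace` is a data frame.
#' @return Peak frequency in Hz.
#' @export
dominant_frequency <- function(trace, sampling_rate = NULL) {
  if (is.data.frame(trace)) {
    v <- trace$displacement_um
    if (is.null(sampling_rate))
      sampling_rate <- 1 / median(diff(trace$time_s))
  } else {
    v <- as.numeric(trace)
    if (is.null(sampling_rate))
      stop_param("'sampling_rate' is required for a bare numeric trace")
  }
  n <- length(v)
  if (n < 4L) stop_param("trace too short for spectral estimation")
  spec <- Mod(fft(v - mean(v)))
  half <- seq(2L, floor(n / 2) + 1L)  # positive frequencies, DC excluded
  freqs <- (half - 1L) * sampling_rate / n
  freqs[which.max(spec[half])]
}

#' Peak excursion of a displacement trace
#'
#' Maximum absolute displacement over the trace, in um.
#'
#' @param trace A data frame from [generate_probe_trace()] or numeric vector.
#' @return Peak |displacement| in um.
#' @export
peak_excursion <- function(trace) {
  v <- if (is.data.frame(trace)) trace$displacement_um else as.numeric(trace)
  max(abs(v))
}
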