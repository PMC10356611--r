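# Spike and membrane-potential utilities and the spike-rate-to-
# fluorescence forward model used to interpret calcium kinetics.

#' Construct a voltage recording
#'
#' @param t Times in seconds (uniform, typically 10 kHz).
#' @param vm_mV Membrane potential in mV.
#' @param junction_corrected Whether the junction-potential correction
#'   has already been applied.
#' @return Object of class `voltage_recording`.
#' @export
voltage_recording <- function(t, vm_mV, junction_corrected = FALSE) {
  stopifnot(length(t) == length(vm_mV), all(is.finite(vm_mV)))
  structure(list(t = t, vm_mV = vm_mV,
                 junction_corrected = junction_corrected),
            class = "voltage_recording")
}

#' Apply the liquid-junction-potential correction once
#'
#' Subtracts `junction_mV` (default 13 mV) from the recorded membrane
#' potential.  Refuses to run twice: applying it to an
#' already-corrected recording is an error.
#'
#' @param rec A [voltage_recording()].
#' @param junction_mV Junction potential in mV.
#' @return The corrected recording, flagged.
#' @export
junction_correct <- function(rec, junction_mV = 13) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (rec$junction_corrected)
    stop("junction correction already applied")
  rec$vm_mV <- rec$vm_mV - junction_mV
  rec$junction_corrected <- TRUE
  rec
}

#' Detect spikes from a voltage recording
#'
#' High-pass filters Vm (2nd-order Butterworth, zero phase) and finds
#' local maxima above a threshold; peaks closer than `min_sep_s`
#' (default 1 ms) are resolved by keeping the larger of each violating
#' pair.  The default threshold is `thresh_sd` robust standard
#' deviations (MAD) of the filtered trace; cutoff and threshold vary
#' with recording quality in practice, so both are parameters.
#'
#' @param rec A [voltage_recording()].
#' @param highpass_hz High-pass cutoff in Hz.
#' @param thresh_mV Absolute threshold on the filtered trace; when
#'   `NULL`, `thresh_sd * mad(filtered)` is used (6 robust SDs keeps
#'   the false-positive rate negligible over 10 kHz recordings).
#' @param thresh_sd Robust-SD multiplier for the automatic threshold.
#' @param min_sep_s Minimum separation between retained spikes.
#' @return Numeric vector of spike times (possibly empty), strictly
#'   increasing.
#' @export
detect_spikes <- function(rec, highpass_hz = 100, thresh_mV = NULL,
                          thresh_sd = 6, min_sep_s = 0.001) {
  stopifnot(inherits(rec, "voltage_recording"))
  t <- rec$t
  fs <- 1 / (t[2] - t[1])
  bf <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
  hp <- as.numeric(signal::filtfilt(bf, rec$vm_mV))
  if (is.null(thresh_mV)) thresh_mV <- thresh_sd * stats::mad(hp)
  n <- length(hp)
  is_peak <- c(FALSE, hp[2:(n - 1)] > hp[1:(n - 2)] &
                 hp[2:(n - 1)] >= hp[3:n], FALSE)
  # guard band against zero-phase filter edge transients
  guard <- 5 / highpass_hz
  is_peak[t < t[1] + guard | t > t[n] - guard] <- FALSE
  pk <- which(is_peak & hp > thresh_mV)
  if (!length(pk)) return(numeric(0))
  # enforce the separation rule: of any pair closer than min_sep_s,
  # keep the larger peak; repeat until no violations remain
  repeat {
    if (length(pk) < 2) break
    gaps <- diff(t[pk])
    v <- which(gaps < min_sep_s)[1]
    if (is.na(v)) break
    drop <- if (hp[pk[v]] >= hp[pk[v + 1]]) v + 1L else v
    pk <- pk[-drop]
  }
  t[pk]
}

#' Sliding-window spike rate
#'
#' Counts spikes in a window of `window_s` seconds slid in steps of
#' `step_s`, divides by the window, and assigns each value to the
#' middle of its counting interval.
#'
#' @param spike_times Sorted spike times.
#' @param span `c(t0, t1)` range of the recording in seconds.
#' @param window_s Counting window in seconds (5 s, or 0.1 s for the
#'   fast variant).
#' @param step_s Step between window centres in seconds.
#' @return Data frame `t_s, rate` (spikes per second).
#' @export
spike_rate <- function(spike_times, span, window_s = 5, step_s = 1e-4) {
  stopifnot(length(span) == 2, span[2] > span[1])
  if (window_s > span[2] - span[1])
    stop("window exceeds the recording span")
  centres <- seq(span[1] + window_s / 2, span[2] - window_s / 2,
                 by = step_s)
  counts <- findInterval(centres + window_s / 2, spike_times) -
    findInterval(centres - window_s / 2 - 1e-12, spike_times)
  data.frame(t_s = centres, rate = counts / window_s)
}

#' Remove spike waveforms from a voltage trace
#'
#' Converts `blank_s` seconds of data centred on each spike peak to NA;
#' overlapping blanking windows merge.
#'
#' @param vm_mV Voltage samples.
#' @param t Sample times.
#' @param spike_times Spike peak times.
#' @param blank_s Total blanked window per spike.
#' @return Voltage vector with NAs in the blanked union of intervals.
#' @export
despike_vm <- function(vm_mV, t, spike_times, blank_s = 0.150) {
  out <- vm_mV
  h <- blank_s / 2
  for (s in spike_times)
    out[t >= s - h - 1e-12 & t <= s + h + 1e-12] <- NA_real_
  out
}

#' GCaMP kinetic forward model for a spike-rate trace
#'
#' Convolves the rate with a causal exponential kernel (unit area, time
#' constant `tau_s`, the indicator off-kinetics) and then a centred
#' boxcar of width `boxcar_s` (the slowest imaging frame period).  Both
#' kernels preserve a constant input, so the output is a fluorescence
#' proxy on the same grid and scale.
#'
#' @param rate Rate values on a uniform grid.
#' @param dt Grid interval in seconds.
#' @param tau_s Exponential time constant.
#' @param boxcar_s Boxcar width.
#' @return Fluorescence-proxy values on the same grid.
#' @export
gcamp_forward_model <- function(rate, dt, tau_s = 0.300, boxcar_s = 2.8) {
  if (!(tau_s > 0) || !(boxcar_s > 0))
    stop("tau_s and boxcar_s must be positive")
  a <- exp(-dt / tau_s)
  # unit-gain causal exponential as a first-order recursive filter
  y <- stats::filter((1 - a) * rate, a, method = "recursive")
  boxcar(as.numeric(y), boxcar_s, dt)
}

#' Half-decay time after cessation of stimulation
#'
#' Time after `stim_end_s` for the trace to return half-way between its
#' value at the end of stimulation and the mean over the `pre_window_s`
#' seconds preceding stimulation, with linear interpolation between
#' samples.  Returns NA (with `defined = FALSE`) if the trace never
#' crosses the midpoint in the available tail.
#'
#' @param x Trace values on a uniform grid.
#' @param t Grid times.
#' @param stim_end_s Time stimulation ceased.
#' @param pre_window_s Pre-stimulation averaging window in seconds.
#' @param stim_start_s Stimulation onset; the pre-stimulation window is
#'   the `pre_window_s` seconds before it.  Defaults to `stim_end_s`
#'   (pre window immediately preceding the reference point).
#' @return List `half_decay_s`, `defined`.
#' @export
half_decay_time <- function(x, t, stim_end_s, pre_window_s = 5,
                            stim_start_s = stim_end_s) {
  pre <- x[t >= stim_start_s - pre_window_s & t < stim_start_s]
  if (!length(pre)) stop("trace does not cover the pre-stimulation window")
  i_end <- max(which(t <= stim_end_s + 1e-12))
  v_end <- x[i_end]
  mid <- (v_end + mean(pre, na.rm = TRUE)) / 2
  tail_idx <- which(t > stim_end_s)
  if (!length(tail_idx))
    return(list(half_decay_s = NA_real_, defined = FALSE))
  decaying <- v_end >= mid
  crossed <- if (decaying) x[tail_idx] <= mid else x[tail_idx] >= mid
  j <- tail_idx[crossed][1]
  if (is.na(j)) return(list(half_decay_s = NA_real_, defined = FALSE))
  jprev <- j - 1L
  x0 <- x[jprev]; x1 <- x[j]
  frac <- if (x1 == x0) 0 else (mid - x0) / (x1 - x0)
  t_cross <- t[jprev] + frac * (t[j] - t[jprev])
  list(half_decay_s = t_cross - stim_end_s, defined = TRUE)
}
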