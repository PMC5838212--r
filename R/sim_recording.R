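#' Ground truth for simulated multielectrode-array recordings
#'
#' Generates, per electrode, the true spike times and burst windows that
#' [simulate_recording()] will render into voltage traces. Background
#' (tonic) spikes follow a homogeneous Poisson process; bursts are clusters
#' of 4-8 spikes with intra-burst inter-spike intervals drawn uniformly from
#' 20-50 ms. Background spikes that fall within the detector dead time of
#' another spike are dropped from the truth, so every true spike is
#' resolvable.
#'
#' @param duration recording length, s.
#' @param n_electrodes number of electrodes.
#' @param sampling_rate Hz (>= 10 kHz).
#' @param noise_sd baseline noise SD, microvolts.
#' @param spike_amplitude absolute waveform peak, as a multiple of
#'   `noise_sd`.
#' @param background_rate tonic spike rate, spikes/s.
#' @param burst_rate bursts per minute.
#' @param dead_time minimum spacing between resolvable spikes, s.
#' @param seed RNG seed.
#' @return An object of class `trace_sim_truth`: per-electrode
#'   `spike_times` (sorted, s) and `burst_windows` (two-column matrices,
#'   start/end s), plus all generation parameters.
#' @export
trace_sim_truth <- function(duration, n_electrodes = 1,
                            sampling_rate = 25000, noise_sd = 5,
                            spike_amplitude = 10, background_rate = 2,
                            burst_rate = 10, dead_time = 0.001, seed = 1) {
  if (sampling_rate < 10000) stop("sampling_rate must be >= 10 kHz")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  with_seed(seed, {
    spike_times <- vector("list", n_electrodes)
    burst_windows <- vector("list", n_electrodes)
    for (e in seq_len(n_electrodes)) {
      n_bursts <- rpois(1, burst_rate * duration / 60)
      bursts <- list()
      for (b in seq_len(n_bursts)) {
        n_sp <- sample(4:8, 1)
        isis <- runif(n_sp - 1, 0.02, 0.05)
        t0 <- runif(1, 0, max(duration - sum(isis) - 0.01, 0))
        ts <- t0 + c(0, cumsum(isis))
        if (max(ts) < duration) bursts[[length(bursts) + 1]] <- ts
      }
      burst_sp <- as.numeric(sort(unlist(bursts)))
      n_bg <- rpois(1, background_rate * duration)
      bg <- sort(runif(n_bg, 0, duration - 0.002))
      # drop background spikes colliding with any kept spike
      kept <- burst_sp
      for (t in bg) {
        if (!length(kept) || min(abs(kept - t)) > dead_time) {
          kept <- sort(c(kept, t))
        }
      }
      spike_times[[e]] <- kept
      burst_windows[[e]] <- if (length(bursts)) {
        do.call(rbind, lapply(bursts, function(ts) range(ts)))
      } else {
        matrix(numeric(0), ncol = 2)
      }
    }
    truth <- structure(
      list(spike_times = spike_times, burst_windows = burst_windows,
           duration = duration, n_electrodes = n_electrodes,
           sampling_rate = sampling_rate, noise_sd = noise_sd,
           spike_amplitude = spike_amplitude,
           background_rate = background_rate, burst_rate = burst_rate,
           dead_time = dead_time, seed = as.integer(seed)),
      class = "trace_sim_truth"
    )
    validate_trace_truth(truth)
    truth
  })
}

validate_trace_truth <- function(truth) {
  for (e in seq_len(truth$n_electrodes)) {
    ts <- truth$spike_times[[e]]
    if (is.unsorted(ts)) stop("spike times must be sorted")
    if (length(ts) && (min(ts) < 0 || max(ts) > truth$duration)) {
      stop("spike times must lie within [0, duration]")
    }
    bw <- truth$burst_windows[[e]]
    for (b in seq_len(nrow(bw))) {
      inb <- ts[ts >= bw[b, 1] - 1e-9 & ts <= bw[b, 2] + 1e-9]
      if (length(inb) < 4 || any(diff(inb) > 0.1 + 1e-9)) {
        stop("burst window must contain >= 4 spikes with gaps <= 0.1 s")
      }
    }
  }
  invisible(truth)
}

# Biphasic (negative-then-positive) ~1 ms extracellular spike template with
# absolute peak `amplitude`.
spike_template <- function(sampling_rate, amplitude, width = 0.001) {
  k <- max(round(sampling_rate * width), 4)
  -amplitude * sin(2 * pi * seq(0, k - 1) / k)
}

#' Render simulated extracellular voltage traces
#'
#' Adds a biphasic ~1 ms spike waveform at every true spike time on top of
#' Gaussian baseline noise. Rendering is fully determined by the truth
#' object (per-electrode noise seeds are derived from `truth$seed`).
#'
#' @param duration recording length, s (must equal `truth$duration`).
#' @param electrodes number of electrodes (must equal
#'   `truth$n_electrodes`).
#' @param truth a [trace_sim_truth].
#' @param epoch epoch label attached to each recording (`"pre"`/`"post"`).
#' @return A list of `electrode_recording` objects (fields `electrode_id`,
#'   `sampling_rate`, `samples` in microvolts, `epoch`, `duration`).
#' @export
simulate_recording <- function(duration, electrodes, truth, epoch = "pre") {
  stopifnot(inherits(truth, "trace_sim_truth"))
  if (duration != truth$duration || electrodes != truth$n_electrodes) {
    stop("duration/electrodes must match the truth object")
  }
  fs <- truth$sampling_rate
  n <- round(duration * fs)
  tmpl <- spike_template(fs, truth$spike_amplitude * truth$noise_sd)
  lapply(seq_len(electrodes), function(e) {
    ts <- truth$spike_times[[e]]
    if (length(ts) && max(ts) >= duration) {
      stop("spike time beyond trace duration")
    }
    x <- with_seed(derive_seed(truth$seed, e), rnorm(n, 0, truth$noise_sd))
    for (t in ts) {
      i0 <- floor(t * fs) + 1
      idx <- i0:min(i0 + length(tmpl) - 1, n)
      x[idx] <- x[idx] + tmpl[seq_along(idx)]
    }
    electrode_recording(sprintf("E%02d", e), fs, x, epoch)
  })
}

#' @rdname simulate_recording
#' @param electrode_id electrode label.
#' @param sampling_rate Hz.
#' @param samples voltage samples, microvolts.
#' @export
electrode_recording <- function(electrode_id, sampling_rate, samples,
                                epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  structure(
    list(electrode_id = electrode_id, sampling_rate = sampling_rate,
         samples = as.numeric(samples), epoch = epoch,
         duration = length(samples) / sampling_rate),
    class = "electrode_recording"
  )
}

#' Write / read recordings as long-format CSV
#'
#' Columns: `electrode_id`, `sampling_rate_hz`, `epoch`, `sample_index`,
#' `voltage_uv`.
#'
#' @param recs list of `electrode_recording` objects.
#' @param path CSV path.
#' @export
write_recordings <- function(recs, path) {
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(electrode_id = r$electrode_id,
               sampling_rate_hz = r$sampling_rate, epoch = r$epoch,
               sample_index = seq_along(r$samples) - 1L,
               voltage_uv = r$samples, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$electrode_id), function(d) {
    d <- d[order(d$sample_index), ]
    electrode_recording(d$electrode_id[1], d$sampling_rate_hz[1],
                        d$voltage_uv, d$epoch[1])
  })
}
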