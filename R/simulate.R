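# Synthetic EmbracePlus-style device data: multi-day, multi-subject chunked
# datasets with gaps, systolic peaks and event tags, written in the Care
# Portal folder layout so the full discovery/reconstitution pipeline can be
# exercised without hardware. Signal models are deliberately simple -- they
# exist to exercise timing, gaps and preprocessing, not to claim
# physiological realism.

#' Simulation specification
#'
#' Defaults follow the device conventions: EDA 4 Hz, BVP 64 Hz, temperature
#' 1 Hz, accelerometry 64 Hz; chunk files of 15 min (a 24-h recording spans
#' 96 files), never more than 30 min.
#'
#' @param subjects list of `c(subject_id, device_sn)` pairs.
#' @param start session start as local wall time `"YYYY-MM-DD HH:MM:SS"`.
#' @param tz IANA zone the session is recorded in.
#' @param duration_h session length in hours.
#' @param fs named sampling frequencies (Hz) per modality.
#' @param chunk_len_min chunk file length in minutes (at most 30).
#' @param gaps list of `c(offset_s, length_s)` dropout intervals relative to
#'   session start; samples inside a gap are absent from the chunk files.
#' @param tag_times_s event-tag times, seconds after session start.
#' @param pulse_bpm mean pulse rate driving the BVP waveform and the
#'   systolic-peak events.
#' @param pulse_jitter relative SD of beat-to-beat interval jitter.
#' @param noise_sd named Gaussian noise SDs per modality (signal units:
#'   uS, a.u., degC, g).
#' @param scr_per_min rate of phasic skin-conductance responses (events per
#'   minute; each response rises instantaneously and decays exponentially).
#' @param seed integer seed; one generator drives all stochastic draws so a
#'   spec reproduces bit-identically.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(subjects = list(c("S001", "3YK31141P6")),
                     start = "2024-01-28 08:00:00",
                     tz = "Asia/Singapore",
                     duration_h = 24,
                     fs = c(EDA = 4, BVP = 64, Temp = 1, ACC = 64),
                     chunk_len_min = 15,
                     gaps = list(),
                     tag_times_s = numeric(0),
                     pulse_bpm = 72,
                     pulse_jitter = 0.05,
                     noise_sd = c(EDA = 0.05, BVP = 0.02, Temp = 0.01,
                                  ACC = 0.05),
                     scr_per_min = 2,
                     seed = 1L) {
  if (chunk_len_min > MAX_CHUNK_MIN)
    stop("chunk_len_min must be <= ", MAX_CHUNK_MIN, call. = FALSE)
  if (any(fs <= 0)) stop("all fs must be > 0", call. = FALSE)
  dur_s <- duration_h * 3600
  for (g in gaps)
    if (g[1] < 0 || g[1] + g[2] > dur_s)
      stop("gap (", g[1], ", ", g[2], ") outside session", call. = FALSE)
  structure(list(subjects = subjects, start = start, tz = tz,
                 duration_h = duration_h, fs = fs,
                 chunk_len_min = chunk_len_min, gaps = gaps,
                 tag_times_s = tag_times_s, pulse_bpm = pulse_bpm,
                 pulse_jitter = pulse_jitter, noise_sd = noise_sd,
                 scr_per_min = scr_per_min, seed = as.integer(seed)),
            class = "sim_spec")
}

in_gap <- function(t_s, gaps) {
  hit <- rep(FALSE, length(t_s))
  for (g in gaps) hit <- hit | (t_s >= g[1] & t_s < g[1] + g[2])
  hit
}

# asymmetric photoplethysmography-like pulse: systolic peak at phase 0.3,
# smaller dicrotic bump at 0.7
bvp_waveform <- function(phase) {
  exp(-(phase - 0.3)^2 / (2 * 0.06^2)) +
    0.35 * exp(-(phase - 0.7)^2 / (2 * 0.1^2))
}
BVP_PEAK_PHASE <- 0.3

#' Simulate one subject's ground-truth recording
#'
#' Deterministic given the spec seed (offset by `subject_index` so subjects
#' differ). Gap samples are `NaN` in the returned ground truth and are
#' absent from chunk files written by [write_dataset()]. Values are
#' pre-quantised through the storage encoding (32-bit float; ADC counts for
#' accelerometry) so that written chunks read back bit-equal to this ground
#' truth.
#'
#' @param spec a [sim_spec()].
#' @param subject_index which entry of `spec$subjects` to simulate.
#' @return object of class `sim_recording`: per-modality
#'   [uniform_series()] ground truth, systolic-peak [event_series()], tag
#'   times, and session metadata.
#' @export
simulate_recording <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  sub <- spec$subjects[[subject_index]]
  set.seed(spec$seed + (subject_index - 1L) * 7919L)
  start_us <- local_to_us(spec$start, spec$tz)
  dur_s <- spec$duration_h * 3600
  series <- list()
  grid <- function(fs) (seq_len(floor(dur_s * fs)) - 1) / fs

  if ("EDA" %in% names(spec$fs)) {
    fs <- spec$fs[["EDA"]]
    t <- grid(fs)
    tonic <- 2 + 0.3 * sin(2 * pi * t / 5400) + 0.2 * t / max(t[length(t)], 1)
    n_scr <- stats::rpois(1, spec$scr_per_min * dur_s / 60)
    v <- tonic + stats::rnorm(length(t), 0, spec$noise_sd[["EDA"]])
    if (n_scr > 0) {
      t0 <- sort(stats::runif(n_scr, 0, dur_s))
      amp <- stats::rlnorm(n_scr, log(0.3), 0.4)
      tau <- 5
      for (k in seq_len(n_scr)) {
        i0 <- ceiling(t0[k] * fs) + 1
        i1 <- min(length(t), i0 + ceiling(10 * tau * fs))
        if (i0 <= length(t))
          v[i0:i1] <- v[i0:i1] + amp[k] * exp(-(t[i0:i1] - t0[k]) / tau)
      }
    }
    v[in_gap(t, spec$gaps)] <- NaN
    series$EDA <- uniform_series("EDA", start_us, fs, float32(v))
  }

  beat_starts <- numeric(0)
  if ("BVP" %in% names(spec$fs) || TRUE) {
    mean_ibi <- 60 / spec$pulse_bpm
    n_beats <- ceiling(dur_s / mean_ibi * 1.2) + 10
    ibi <- mean_ibi * pmax(0.5, 1 + spec$pulse_jitter * stats::rnorm(n_beats))
    beat_starts <- c(0, cumsum(ibi))
    beat_starts <- beat_starts[beat_starts < dur_s + mean_ibi]
  }
  if ("BVP" %in% names(spec$fs)) {
    fs <- spec$fs[["BVP"]]
    t <- grid(fs)
    k <- findInterval(t, beat_starts)
    k[k < 1] <- 1L
    ibi_k <- diff(beat_starts)[pmin(k, length(beat_starts) - 1L)]
    phase <- (t - beat_starts[k]) / ibi_k
    v <- bvp_waveform(pmin(pmax(phase, 0), 1))
    v <- v - mean(v) + stats::rnorm(length(t), 0, spec$noise_sd[["BVP"]])
    v[in_gap(t, spec$gaps)] <- NaN
    series$BVP <- uniform_series("BVP", start_us, fs, float32(v))
  }

  if ("Temp" %in% names(spec$fs)) {
    fs <- spec$fs[["Temp"]]
    t <- grid(fs)
    v <- 33 + 0.5 * sin(2 * pi * (t + stats::runif(1, 0, 86400)) / 86400) +
      stats::rnorm(length(t), 0, spec$noise_sd[["Temp"]])
    v[in_gap(t, spec$gaps)] <- NaN
    series$Temp <- uniform_series("Temp", start_us, fs, float32(v))
  }

  if ("ACC" %in% names(spec$fs)) {
    fs <- spec$fs[["ACC"]]
    t <- grid(fs)
    sd0 <- spec$noise_sd[["ACC"]]
    # alternating 10-min activity bursts carrying a 1 Hz square wave
    active <- (floor(t / 600) %% 2) == 1
    sq <- 0.5 * sign(sin(2 * pi * t)) * active
    m <- cbind(x = stats::rnorm(length(t), 0, sd0) + sq,
               y = stats::rnorm(length(t), 0, sd0) + 0.5 * sq,
               z = 1 + stats::rnorm(length(t), 0, sd0))
    m[] <- quantize_acc(m)
    m[in_gap(t, spec$gaps), ] <- NaN
    series$ACC <- uniform_series("ACC", start_us, fs, m)
  }

  # systolic peak: waveform maximum of each beat
  n_bs <- length(beat_starts)
  peak_t <- beat_starts[-n_bs] + BVP_PEAK_PHASE * diff(beat_starts)
  peak_t <- peak_t[peak_t < dur_s & !in_gap(peak_t, spec$gaps)]
  peaks <- event_series((start_us + round(peak_t * US)) * 1000)

  tags_s <- spec$tag_times_s[!in_gap(spec$tag_times_s, spec$gaps)]
  structure(list(subject = sub[1], device = sub[2], tz = spec$tz,
                 start_us = start_us, duration_s = dur_s,
                 series = series, peaks = peaks,
                 tags_us = start_us + round(sort(tags_s) * US),
                 spec = spec),
            class = "sim_recording")
}

#' Simulate every subject in a spec
#'
#' @param spec a [sim_spec()].
#' @return list of [simulate_recording()] results, one per subject.
#' @export
simulate_dataset <- function(spec) {
  lapply(seq_along(spec$subjects), function(i) simulate_recording(spec, i))
}

# contiguous recorded intervals (seconds, half-open) = session minus gaps
recorded_runs <- function(dur_s, gaps) {
  edges <- c(0, dur_s)
  for (g in gaps) edges <- c(edges, g[1], g[1] + g[2])
  edges <- sort(unique(pmin(pmax(edges, 0), dur_s)))
  runs <- cbind(edges[-length(edges)], edges[-1])
  mid <- (runs[, 1] + runs[, 2]) / 2
  runs[!in_gap(mid, gaps) & runs[, 2] > runs[, 1], , drop = FALSE]
}

#' Write simulated recordings as a participant_data folder tree
#'
#' Produces `participant_data/<YYYY-MM-DD>/<subject>-<device>/raw_data/v6/`
#' chunk files (Avro by default, or the CSV dialect). Chunk boundaries are
#' aligned to the session start; a recording crossing midnight contributes
#' files under each date per the chunks' local start dates; recording gaps
#' shorten or remove the affected chunks.
#'
#' @param recordings list of [simulate_recording()] results (or one).
#' @param root output root; the `participant_data` folder is created below
#'   it.
#' @param chunk_len_min chunk length in minutes; defaults to the simulation
#'   spec's value; never more than 30.
#' @param format `"avro"` or `"csv"`.
#' @return (invisibly) character vector of the chunk files written. A JSON
#'   manifest of the ground truth layout is written beside
#'   `participant_data` for test assertions.
#' @export
write_dataset <- function(recordings, root, chunk_len_min = NULL,
                          format = c("avro", "csv")) {
  format <- match.arg(format)
  if (inherits(recordings, "sim_recording")) recordings <- list(recordings)
  files <- character(0)
  manifest <- list()
  for (rec in recordings) {
    clen <- (chunk_len_min %||% rec$spec$chunk_len_min) * 60
    if (clen > MAX_CHUNK_MIN * 60)
      stop("chunk_len_min must be <= ", MAX_CHUNK_MIN, call. = FALSE)
    runs <- recorded_runs(rec$duration_s, rec$spec$gaps)
    n_chunks <- ceiling(rec$duration_s / clen)
    pieces <- list()
    for (k in seq_len(n_chunks) - 1) {
      c0 <- k * clen; c1 <- min((k + 1) * clen, rec$duration_s)
      for (r in seq_len(nrow(runs))) {
        a <- max(c0, runs[r, 1]); b <- min(c1, runs[r, 2])
        if (b > a) pieces[[length(pieces) + 1L]] <- c(a, b)
      }
    }
    for (pc in pieces) {
      a <- pc[1]; b <- pc[2]
      mods <- list()
      for (m in names(rec$series)) {
        s <- rec$series[[m]]
        i0 <- ceiling(a * s$fs - 1e-9)
        i1 <- ceiling(b * s$fs - 1e-9) - 1
        if (i1 < i0) next
        idx <- (i0:i1) + 1L
        vals <- if (is.matrix(s$values)) s$values[idx, , drop = FALSE]
                else s$values[idx]
        mods[[m]] <- list(start_us = s$start_us + round(i0 * US / s$fs),
                          fs = s$fs, values = vals)
      }
      a_us <- rec$start_us + round(a * US)
      b_us <- rec$start_us + round(b * US)
      pk <- rec$peaks$times_ns
      pk <- pk[pk >= a_us * 1000 & pk < b_us * 1000]
      tg <- rec$tags_us[rec$tags_us >= a_us & rec$tags_us < b_us]
      cr <- chunk_record(rec$subject, rec$device, mods, pk, tg)
      date <- local_date_str(a_us, rec$tz)
      dir <- file.path(root, "participant_data", date,
                       paste0(rec$subject, "-", rec$device), "raw_data", "v6")
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      if (format == "avro") {
        f <- file.path(dir, sprintf("1-1-%s_%.0f.avro", rec$subject,
                                    floor(a_us / US)))
        write_avro_chunk(cr, f)
        files <- c(files, f)
      } else {
        write_csv_chunks(cr, dir)
        files <- c(files, file.path(dir, paste0(csv_stem(cr), "_",
                                                c(names(mods)), ".csv")))
      }
    }
    manifest[[length(manifest) + 1L]] <- list(
      subject = rec$subject, device = rec$device, tz = rec$tz,
      start_us = rec$start_us, duration_s = rec$duration_s,
      seed = rec$spec$seed,
      n_pieces = length(pieces),
      samples = lapply(rec$series, function(s)
        list(fs = s$fs, n_total = n_samples(s),
             n_gap = sum(!stats::complete.cases(value_matrix(s))))),
      n_peaks = length(rec$peaks$times_ns), n_tags = length(rec$tags_us))
  }
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}
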