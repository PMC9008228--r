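#' The 18-channel bipolar 10-20 montage common to CHB-MIT subjects
#' @return Character vector of 18 channel names.
#' @export
chbmit_montage <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ")
}

#' Construct an annotated EEG recording
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param seizures data.frame with columns `onset`, `offset` (seconds);
#'   intervals must lie inside the recording, be sorted and non-overlapping.
#' @param subject_id Identifier string.
#' @param channels Channel names (default: first `nrow(signal)` montage
#'   names).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, seizures = NULL, subject_id = "S01",
                          channels = NULL) {
  if (!is.matrix(signal)) stop("signal must be a channels x samples matrix",
                               call. = FALSE)
  if (is.null(seizures))
    seizures <- data.frame(onset = numeric(0), offset = numeric(0))
  if (is.null(channels))
    channels <- head(c(chbmit_montage(),
                       paste0("CH", seq_len(nrow(signal)))), nrow(signal))
  dur <- ncol(signal) / fs
  if (nrow(seizures)) {
    seizures <- seizures[order(seizures$onset), , drop = FALSE]
    if (any(seizures$onset < 0) || any(seizures$offset > dur) ||
        any(seizures$offset <= seizures$onset))
      stop("seizure intervals must be within [0, ", dur,
           "] and non-empty", call. = FALSE)
    if (nrow(seizures) > 1L &&
        any(seizures$onset[-1L] < seizures$offset[-nrow(seizures)]))
      stop("seizure intervals overlap", call. = FALSE)
  }
  structure(list(signal = signal, fs = fs, seizures = seizures,
                 subject_id = subject_id, channels = channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording", x$subject_id, ":", nrow(x$signal), "channels x",
      sprintf("%.1f s", ncol(x$signal) / x$fs), "at", x$fs, "Hz,",
      nrow(x$seizures), "seizure(s)\n")
  invisible(x)
}

#' Windowing configuration
#'
#' @param Wlen Window length in seconds (default 8).
#' @param Wstep Step between window starts in seconds (default 1).
#' @param label_rule Minimum fraction of a window that must overlap a
#'   seizure interval for the window to be labeled ictal (default 0.5).
#' @return Object of class `windowing_config`.
#' @export
windowing_config <- function(Wlen = 8, Wstep = 1, label_rule = 0.5) {
  if (Wstep > Wlen) stop("Wstep must be <= Wlen", call. = FALSE)
  structure(list(Wlen = Wlen, Wstep = Wstep, label_rule = label_rule),
            class = "windowing_config")
}

#' Segment a recording into labeled windows
#'
#' Windows start at 0, Wstep, 2*Wstep, ...; there are
#' `floor((T/fs - Wlen)/Wstep) + 1` of them. A window is ictal iff at
#' least `label_rule` of its span overlaps a seizure interval.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [windowing_config()].
#' @return data.frame with columns `start` (seconds) and `label`.
#' @export
segment_and_label <- function(rec, cfg = windowing_config()) {
  dur <- ncol(rec$signal) / rec$fs
  if (dur < cfg$Wlen)
    stop("recording shorter than one window", call. = FALSE)
  starts <- seq(0, dur - cfg$Wlen, by = cfg$Wstep)
  overlap <- numeric(length(starts))
  for (i in seq_len(nrow(rec$seizures))) {
    o <- pmin(starts + cfg$Wlen, rec$seizures$offset[i]) -
      pmax(starts, rec$seizures$onset[i])
    overlap <- overlap + pmax(0, o)
  }
  data.frame(start = starts,
             label = ifelse(overlap / cfg$Wlen >= cfg$label_rule,
                            "ictal", "interictal"))
}

#' Extract the samples of one window
#' @param rec An [eeg_recording()].
#' @param start Window start (seconds).
#' @param Wlen Window length (seconds).
#' @return Channels x samples matrix.
#' @export
window_samples <- function(rec, start, Wlen = 8) {
  i0 <- round(start * rec$fs)
  rec$signal[, (i0 + 1L):(i0 + round(Wlen * rec$fs)), drop = FALSE]
}

#' Balancing configuration for per-seizure files
#'
#' @param factor Interictal-to-ictal duration ratio: 1, 5 or 10 (the F1 /
#'   F5 / F10 regimes).
#' @param pre_exclusion Seconds before each seizure onset excluded from
#'   interictal sampling (default 60).
#' @param post_exclusion Seconds after each seizure offset excluded
#'   (default 900): post-ictal EEG may still carry ictal patterns and its
#'   true label is medically uncertain.
#' @param segment_len Target length (seconds) of each contiguous interictal
#'   segment drawn (default 60); contiguous segments keep label smoothing
#'   meaningful.
#' @param seed Integer seed for the random segment draw.
#' @return Object of class `balancing_config`.
#' @export
balancing_config <- function(factor = 1, pre_exclusion = 60,
                             post_exclusion = 900, segment_len = 60,
                             seed = 1L) {
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (pre_exclusion < 0 || post_exclusion < 0)
    stop("exclusion zones must be >= 0", call. = FALSE)
  structure(list(factor = factor, pre_exclusion = pre_exclusion,
                 post_exclusion = post_exclusion,
                 segment_len = segment_len, seed = as.integer(seed)),
            class = "balancing_config")
}

# eligible interictal intervals (seconds) of one recording: everything
# outside every [onset - pre, offset + post] zone
.eligible_intervals <- function(rec, pre, post) {
  dur <- ncol(rec$signal) / rec$fs
  lo <- 0
  out <- list()
  zones <- rec$seizures
  if (nrow(zones)) {
    z <- cbind(pmax(0, zones$onset - pre), pmin(dur, zones$offset + post))
    z <- z[order(z[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(z))) {
      if (z[i, 1L] > lo) out[[length(out) + 1L]] <- c(lo, z[i, 1L])
      lo <- max(lo, z[i, 2L])
    }
  }
  if (lo < dur) out[[length(out) + 1L]] <- c(lo, dur)
  if (length(out)) do.call(rbind, out) else matrix(numeric(0), ncol = 2L)
}

#' Build per-seizure balanced files (F1 / F5 / F10 regimes)
#'
#' One output recording per seizure: the seizure's ictal samples untouched,
#' plus randomly drawn contiguous interictal segments totalling
#' `factor x` the seizure duration. Interictal is drawn only outside every
#' `[onset - pre_exclusion, offset + post_exclusion]` zone of every seizure
#' in the source recording. Segments keep their original temporal order and
#' the seizure is inserted at its chronological position, so each file is a
#' plausible time line with exactly one annotated seizure.
#'
#' @param recs A single [eeg_recording()] or list of them.
#' @param bal A [balancing_config()].
#' @return List of `eeg_recording` objects, one per seizure, each holding
#'   exactly one seizure annotation.
#' @export
build_balanced_files <- function(recs, bal = balancing_config()) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  nseiz <- sum(vapply(recs, function(r) nrow(r$seizures), integer(1)))
  if (nseiz == 0L) stop("no seizures in input recordings", call. = FALSE)
  out <- list()
  fileno <- 0L
  for (rec in recs) {
    elig <- .eligible_intervals(rec, bal$pre_exclusion, bal$post_exclusion)
    for (k in seq_len(nrow(rec$seizures))) {
      fileno <- fileno + 1L
      out[[fileno]] <- withr::with_seed(
        bal$seed + fileno,
        .assemble_balanced_file(rec, k, elig, bal, fileno))
    }
  }
  out
}

.assemble_balanced_file <- function(rec, k, elig, bal, fileno) {
  fs <- rec$fs
  onset <- rec$seizures$onset[k]
  offset <- rec$seizures$offset[k]
  seiz_dur <- offset - onset
  target <- bal$factor * seiz_dur
  avail <- if (nrow(elig)) sum(elig[, 2L] - elig[, 1L]) else 0
  if (avail < target)
    stop(sprintf(
      "insufficient eligible interictal data: need %.1f s, have %.1f s",
      target, avail), call. = FALSE)
  # draw contiguous segments from the eligible intervals until the target
  # duration is met; eligibility shrinks as segments are consumed
  pool <- elig
  segs <- list()
  remaining <- target
  while (remaining > 1 / fs) {
    lens <- pool[, 2L] - pool[, 1L]
    keep <- lens > 1 / fs
    pool <- pool[keep, , drop = FALSE]; lens <- lens[keep]
    i <- sample.int(nrow(pool), 1L, prob = lens)
    take <- min(remaining, bal$segment_len, lens[i])
    s0 <- pool[i, 1L] + runif(1L) * (lens[i] - take)
    s0 <- floor(s0 * fs) / fs
    segs[[length(segs) + 1L]] <- c(s0, s0 + take)
    left <- c(pool[i, 1L], s0)
    right <- c(s0 + take, pool[i, 2L])
    pool <- rbind(pool[-i, , drop = FALSE],
                  if (diff(left) > 0) left, if (diff(right) > 0) right)
    remaining <- remaining - take
  }
  segs[[length(segs) + 1L]] <- c(onset, offset)   # the seizure itself
  segm <- do.call(rbind, segs)
  segm <- segm[order(segm[, 1L]), , drop = FALSE]
  idx <- lapply(seq_len(nrow(segm)), function(i) {
    (round(segm[i, 1L] * fs) + 1L):(round(segm[i, 2L] * fs))
  })
  signal <- rec$signal[, unlist(idx), drop = FALSE]
  # locate the seizure in the assembled time line
  before <- which(segm[, 1L] < onset & segm[, 2L] <= onset)
  t0 <- sum(vapply(idx[before], length, integer(1))) / fs
  eeg_recording(signal, fs,
                seizures = data.frame(onset = t0,
                                      offset = t0 + seiz_dur),
                subject_id = paste0(rec$subject_id, "_seiz",
                                    sprintf("%02d", k)),
                channels = rec$channels)
}

#' Synthetic recording configuration
#'
#' Defines a sub-typed synthetic EEG: interictal background alternates
#' between several "brain-state" sub-types (distinct oscillation frequency,
#' amplitude and noise level over 1/f noise), and each seizure is drawn
#' from one of several seizure sub-types (high-amplitude rhythmic
#' discharges, sinusoidal or spike-train waveform, distinct frequency).
#' Seizures are placed in the tail of the recording so that a long clean
#' interictal stretch survives the pre/post-ictal exclusion zones of the
#' balancing step. The realism is deliberately minimal: enough spectral and
#' amplitude structure for feature separability, not a model of true EEG.
#'
#' @param n_channels Channels (default 18, the bipolar 10-20 montage).
#' @param fs Sampling rate Hz (default 256).
#' @param duration Total record length in seconds (default 1800).
#' @param n_seizures Number of seizure episodes (default 3).
#' @param seizure_duration Min/max seizure length in seconds (default
#'   c(15, 30)).
#' @param n_background_subtypes,n_seizure_subtypes Number of distinct
#'   interictal / seizure sub-types (defaults 3 and 2).
#' @param epoch_duration Min/max background sub-type epoch length (s).
#' @param clean_frac Fraction of the record kept seizure-free at the start
#'   (default 0.6); interictal for balancing is drawn here.
#' @param background_amp,seizure_amp Amplitude ranges (arbitrary units).
#' @param background_noise,seizure_noise Pink-noise SD ranges.
#' @param artifact_rate Expected interictal artifact events per minute
#'   (default 1.5): brief high-amplitude slow transients mimicking blink
#'   and movement artifacts.
#' @param artifact_duration Min/max artifact length in seconds.
#' @param artifact_amp Artifact amplitude range as a multiple of the
#'   epoch's background amplitude.
#' @param burst_rate Expected seizure-like interictal bursts per minute
#'   (default 1): sustained rhythmic runs of a few seconds (amplitude and
#'   rhythm comparable to seizures but short), the non-epileptic activity
#'   that drives false detections in scalp EEG.
#' @param burst_duration Min/max burst length in seconds.
#' @param burst_amp Burst amplitude range (same units as `seizure_amp`).
#' @param burst_freq Burst rhythm frequency range in Hz.
#' @param n_burst_subtypes Number of recurring burst types (default 3);
#'   each type has a fixed frequency/amplitude/waveform signature drawn
#'   from the ranges above, and individual events jitter around it.
#' @param seed Integer seed; the whole recording is reproducible from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 18, fs = 256, duration = 1800,
                         n_seizures = 3, seizure_duration = c(15, 30),
                         n_background_subtypes = 3, n_seizure_subtypes = 2,
                         epoch_duration = c(20, 40), clean_frac = 0.6,
                         background_amp = c(8, 15), seizure_amp = c(35, 70),
                         background_noise = c(6, 10), seizure_noise = c(2, 5),
                         artifact_rate = 1.5, artifact_duration = c(0.5, 2.5),
                         artifact_amp = c(2.5, 5),
                         burst_rate = 1, burst_duration = c(3, 8),
                         burst_amp = c(15, 40), burst_freq = c(3, 9),
                         n_burst_subtypes = 3, seed = 1L) {
  stopifnot(n_background_subtypes >= 1, n_seizure_subtypes >= 1,
            n_seizures >= 0, duration > 0, all(seizure_duration > 0))
  structure(as.list(environment()), class = "synth_config")
}

# 1/f ("pink") noise of length n via spectral shaping of white noise
.pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

# periodic spike-train waveform: sharp Gaussian pulses at rate f
.spike_wave <- function(t, f, phase) .spike_wave_phase(t * f + phase)

.spike_wave_phase <- function(ph) {
  ph <- ph %% 1
  exp(-((ph - 0.5)^2) / (2 * 0.04^2)) * 2 - 0.3
}

#' Generate a synthetic sub-typed EEG recording
#'
#' See [synth_config()] for the generative model. The per-sub-type
#' signatures (oscillation frequency, amplitude, noise SD, waveform) are
#' drawn once from the seed; every channel carries the same rhythm with a
#' channel-specific phase, gain and independent pink noise, mimicking the
#' spatial coherence of scalp EEG. Annotations are sample-exact.
#'
#' @param cfg A [synth_config()].
#' @return An [eeg_recording()] with attribute `subtype_log`: the per-epoch
#'   and per-seizure sub-type assignments.
#' @export
generate_synthetic_recording <- function(cfg = synth_config()) {
  withr::with_seed(cfg$seed, .generate_synthetic(cfg))
}

.generate_synthetic <- function(cfg) {
  fs <- cfg$fs
  N <- cfg$n_channels
  Tn <- round(cfg$duration * fs)
  tgrid <- (seq_len(Tn) - 1) / fs

  # sub-type signatures: frequencies spread over a ladder so sub-types are
  # spectrally distinct within class
  bg_freq <- sample(seq(3, 27, length.out = max(cfg$n_background_subtypes, 2)))[
    seq_len(cfg$n_background_subtypes)]
  bg <- data.frame(
    freq = bg_freq,
    amp = runif(cfg$n_background_subtypes, cfg$background_amp[1],
                cfg$background_amp[2]),
    noise = runif(cfg$n_background_subtypes, cfg$background_noise[1],
                  cfg$background_noise[2]))
  # seizure sub-types: evenly spaced rhythm ladder (2 Hz per step, so
  # sub-types stay separable however many there are), laddered amplitude,
  # alternating morphology
  sz_freq <- sample(2.5 + 2 * (seq_len(cfg$n_seizure_subtypes) - 1L))
  sz <- data.frame(
    freq = sz_freq,
    amp = sample(seq(cfg$seizure_amp[1], cfg$seizure_amp[2],
                     length.out = max(cfg$n_seizure_subtypes, 2L))[
                       seq_len(cfg$n_seizure_subtypes)]),
    noise = runif(cfg$n_seizure_subtypes, cfg$seizure_noise[1],
                  cfg$seizure_noise[2]),
    # waveform morphology: mixture weight of spike-train vs sinusoidal
    # discharge, alternating along the frequency ladder so spectrally
    # adjacent sub-types differ in waveform; individual seizures jitter
    # around the sub-type value
    spikemix = ifelse((rank(sz_freq) %% 2L) == 0L, 0.8, 0.2))

  gain <- runif(N, 0.75, 1.25)
  phase <- runif(N)

  # background: epochs cycling through sub-types in random order
  ep_start <- 0
  ep_log <- list()
  subtype_seq <- integer(0)
  while (ep_start < cfg$duration) {
    st <- if (length(subtype_seq) &&
              cfg$n_background_subtypes > 1L) {
      s <- sample.int(cfg$n_background_subtypes, 1L)
      while (s == tail(subtype_seq, 1L))
        s <- sample.int(cfg$n_background_subtypes, 1L)
      s
    } else sample.int(cfg$n_background_subtypes, 1L)
    len <- runif(1, cfg$epoch_duration[1], cfg$epoch_duration[2])
    ep_log[[length(ep_log) + 1L]] <-
      data.frame(start = ep_start, end = min(ep_start + len, cfg$duration),
                 subtype = st)
    subtype_seq <- c(subtype_seq, st)
    ep_start <- ep_start + len
  }
  epochs <- do.call(rbind, ep_log)

  # one independent 1/f noise stream per channel, amplitude-modulated by
  # the sub-type noise level of each epoch
  noise <- matrix(0, nrow = N, ncol = Tn)
  for (ch in seq_len(N)) noise[ch, ] <- .pink_noise(Tn)

  signal <- matrix(0, nrow = N, ncol = Tn)
  for (e in seq_len(nrow(epochs))) {
    i0 <- round(epochs$start[e] * fs) + 1L
    i1 <- min(Tn, round(epochs$end[e] * fs))
    if (i1 < i0) next
    st <- epochs$subtype[e]
    tt <- tgrid[i0:i1]
    for (ch in seq_len(N)) {
      rhythm <- bg$amp[st] * sin(2 * pi * (bg$freq[st] * tt + phase[ch]))
      signal[ch, i0:i1] <- gain[ch] *
        (rhythm + bg$noise[st] * noise[ch, i0:i1])
    }
  }

  # interictal artifacts: brief high-amplitude slow transients (blink /
  # movement-like), Hann-tapered, shared across channels with per-channel
  # gain; a Poisson process over the whole record
  n_art <- rpois(1L, cfg$artifact_rate * cfg$duration / 60)
  art_log <- data.frame(start = numeric(0), duration = numeric(0))
  if (n_art > 0L) {
    art_start <- sort(runif(n_art, 0, cfg$duration - max(cfg$artifact_duration)))
    art_dur <- runif(n_art, cfg$artifact_duration[1], cfg$artifact_duration[2])
    for (a in seq_len(n_art)) {
      i0 <- round(art_start[a] * fs) + 1L
      i1 <- min(Tn, round((art_start[a] + art_dur[a]) * fs))
      if (i1 <= i0) next
      len <- i1 - i0 + 1L
      ep <- max(which(epochs$start <= art_start[a]))
      amp <- runif(1L, cfg$artifact_amp[1], cfg$artifact_amp[2]) *
        bg$amp[epochs$subtype[ep]]
      f0 <- runif(1L, 0.5, 3)
      taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
      tt <- tgrid[i0:i1]
      for (ch in seq_len(N))
        signal[ch, i0:i1] <- signal[ch, i0:i1] + gain[ch] * amp * taper *
          sin(2 * pi * (f0 * tt + phase[ch]))
      art_log <- rbind(art_log,
                       data.frame(start = art_start[a], duration = art_dur[a]))
    }
  }

  # seizure-like interictal bursts: sustained rhythmic runs, Hann-tapered,
  # each with its own frequency/amplitude/waveform; also a Poisson process
  n_burst <- rpois(1L, cfg$burst_rate * cfg$duration / 60)
  burst_log <- data.frame(start = numeric(0), duration = numeric(0),
                          subtype = integer(0))
  bt <- data.frame(
    freq = runif(cfg$n_burst_subtypes, cfg$burst_freq[1], cfg$burst_freq[2]),
    amp = runif(cfg$n_burst_subtypes, cfg$burst_amp[1], cfg$burst_amp[2]),
    spiky = runif(cfg$n_burst_subtypes) < 0.5)
  if (n_burst > 0L) {
    b_start <- sort(runif(n_burst, 0, cfg$duration - max(cfg$burst_duration)))
    b_dur <- runif(n_burst, cfg$burst_duration[1], cfg$burst_duration[2])
    b_type <- sample.int(cfg$n_burst_subtypes, n_burst, replace = TRUE)
    for (a in seq_len(n_burst)) {
      i0 <- round(b_start[a] * fs) + 1L
      i1 <- min(Tn, round((b_start[a] + b_dur[a]) * fs))
      if (i1 <= i0) next
      len <- i1 - i0 + 1L
      ty <- b_type[a]
      amp <- bt$amp[ty] * runif(1L, 0.6, 1.4)   # per-event jitter
      f0 <- bt$freq[ty]
      taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
      tt <- tgrid[i0:i1]
      for (ch in seq_len(N)) {
        base <- if (bt$spiky[ty]) .spike_wave(tt, f0, phase[ch])
                else sin(2 * pi * (f0 * tt + phase[ch]))
        signal[ch, i0:i1] <- signal[ch, i0:i1] + gain[ch] * amp * taper * base
      }
      burst_log <- rbind(burst_log,
                         data.frame(start = b_start[a], duration = b_dur[a],
                                    subtype = ty))
    }
  }

  # seizures: placed in the tail, non-overlapping, with a gap
  seiz <- data.frame(onset = numeric(0), offset = numeric(0))
  sz_assign <- integer(0)
  if (cfg$n_seizures > 0L) {
    lo <- cfg$clean_frac * cfg$duration
    gap <- 20
    durs <- runif(cfg$n_seizures, cfg$seizure_duration[1],
                  cfg$seizure_duration[2])
    span <- cfg$duration - lo - 5
    if (sum(durs) + gap * cfg$n_seizures > span)
      stop("cannot pack ", cfg$n_seizures, " seizures into the last ",
           round(span), " s of the recording", call. = FALSE)
    slack <- span - sum(durs) - gap * (cfg$n_seizures - 1L)
    cuts <- sort(runif(cfg$n_seizures, 0, slack))
    onsets <- lo + cuts + c(0, cumsum(durs[-cfg$n_seizures] +
                                        gap)[seq_len(cfg$n_seizures - 1L)])
    # round to whole samples
    onsets <- round(onsets * fs) / fs
    durs <- round(durs * fs) / fs
    # every sub-type appears at least once when seizures suffice
    sz_assign <- c(seq_len(min(cfg$n_seizure_subtypes, cfg$n_seizures)),
                   if (cfg$n_seizures > cfg$n_seizure_subtypes)
                     sample.int(cfg$n_seizure_subtypes,
                                cfg$n_seizures - cfg$n_seizure_subtypes,
                                replace = TRUE))
    sz_assign <- sample(sz_assign)
    for (k in seq_len(cfg$n_seizures)) {
      st <- sz_assign[k]
      i0 <- round(onsets[k] * fs) + 1L
      i1 <- min(Tn, round((onsets[k] + durs[k]) * fs))
      tt <- tgrid[i0:i1]
      # ictal evolution: the discharge slows down and grows in amplitude
      # over the episode, with per-event jitter around the sub-type
      # signature -- so one seizure spans a trajectory in feature space
      u <- seq(0, 1, length.out = length(tt))
      f_evo <- sz$freq[st] * runif(1L, 0.92, 1.08) * (1.15 - 0.45 * u)
      a_evo <- sz$amp[st] * runif(1L, 0.85, 1.15) * (0.7 + 0.6 * u)
      wm <- min(1, max(0, sz$spikemix[st] + runif(1L, -0.1, 0.1)))
      ph_evo <- cumsum(f_evo) / fs      # integrated instantaneous frequency
      for (ch in seq_len(N)) {
        base <- wm * .spike_wave_phase(ph_evo + phase[ch]) +
          (1 - wm) * sin(2 * pi * (ph_evo + phase[ch]))
        signal[ch, i0:i1] <- gain[ch] *
          (a_evo * base + sz$noise[st] * noise[ch, i0:i1])
      }
    }
    seiz <- data.frame(onset = onsets, offset = onsets + durs)
  }

  rec <- eeg_recording(signal, fs, seizures = seiz,
                       subject_id = sprintf("SYN%04d", cfg$seed %% 10000L),
                       channels = head(chbmit_montage(), N))
  attr(rec, "subtype_log") <- list(background = epochs,
                                   seizure = sz_assign,
                                   bg_signatures = bg, sz_signatures = sz,
                                   artifacts = art_log, bursts = burst_log)
  rec
}

#' Generate a synthetic multi-subject benchmark cohort
#'
#' A cohort of subjects whose sub-type counts vary from subject to subject
#' (seizure sub-types drawn from `subtype_range`, background sub-types one
#' more than seizures), mirroring the inter-subject variability of real
#' epilepsy cohorts. Each subject is a [synth_config()] derived
#' deterministically from `seed`; the same seizures underlie every
#' balancing variant of a subject.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param seed Cohort seed.
#' @param subtype_range Min/max seizure sub-types per subject (default
#'   c(2, 4)).
#' @param ... Overrides passed to every subject's [synth_config()].
#' @return List of `synth_config` objects, one per subject.
#' @export
cohort_configs <- function(n_subjects = 20, seed = 1L,
                           subtype_range = c(2, 4), ...) {
  ks <- withr::with_seed(seed,
    sample(subtype_range[1]:subtype_range[2], n_subjects, replace = TRUE))
  lapply(seq_len(n_subjects), function(i) {
    synth_config(n_seizure_subtypes = ks[i],
                 n_background_subtypes = ks[i] + 1L,
                 seed = seed * 1000L + i, ...)
  })
}

#' Write a benchmark fixture bundle to disk
#'
#' Generates a cohort ([cohort_configs()]), balances each subject at every
#' requested factor, writes the per-seizure files as EDF with plain-text
#' annotation side-cars, and a JSON manifest (subject, factor, file,
#' window count, seizure duration).
#'
#' @param dir Output directory.
#' @param n_subjects,seed,... Passed to [cohort_configs()].
#' @param factors Balancing factors (default c(1, 5, 10)).
#' @return The manifest data.frame, invisibly; files land in `dir`.
#' @export
make_subject_benchmark <- function(dir, n_subjects = 20, seed = 1L,
                                   factors = c(1, 5, 10), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgs <- cohort_configs(n_subjects, seed, ...)
  rows <- list()
  wcfg <- windowing_config()
  for (i in seq_along(cfgs)) {
    rec <- generate_synthetic_recording(cfgs[[i]])
    for (f in factors) {
      files <- build_balanced_files(
        rec, balancing_config(factor = f, seed = cfgs[[i]]$seed + f))
      for (j in seq_along(files)) {
        path <- file.path(dir, sprintf("sub%02d_F%d_seiz%02d.edf", i, f, j))
        write_edf(files[[j]], path)
        wl <- segment_and_label(files[[j]], wcfg)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, factor = f, file = basename(path),
          n_windows = nrow(wl),
          n_ictal_windows = sum(wl$label == "ictal"),
          seizure_duration = files[[j]]$seizures$offset[1] -
            files[[j]]$seizures$onset[1])
      }
    }
    rm(rec)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
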