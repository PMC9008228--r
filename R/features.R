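#' Default entropy feature grid
#'
#' The 37 entropy features computed per channel and window: six sample
#' entropies (embedding m in \{2, 3\} crossed with coarse-graining scales
#' \{2, 3, 4\}, tolerance r = 0.2 sd of the coarse-grained series), fifteen
#' permutation entropies (order 3..7 crossed with delays \{1, 2, 3\},
#' normalized), four Shannon histogram entropies (8/16/32/64 bins, bits),
#' six Renyi (q in \{0.5, 2, 3\} x \{16, 32\} bins) and six Tsallis
#' (same grid) entropies. The grid is data, not code: pass a modified copy
#' to [feature_config()] to change it.
#'
#' @return data.frame with columns `name`, `family`, `p1`, `p2`.
#' @export
default_entropy_grid <- function() {
  rows <- list()
  for (m in c(2L, 3L)) for (s in c(2L, 3L, 4L))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("sampen_m%d_s%d", m, s), family = "sample",
      p1 = m, p2 = s)
  for (m in 3:7) for (tau in 1:3)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("perm_m%d_t%d", m, tau), family = "permutation",
      p1 = m, p2 = tau)
  for (b in c(8L, 16L, 32L, 64L))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("shannon_b%d", b), family = "shannon", p1 = b, p2 = NA)
  for (q in c(0.5, 2, 3)) for (b in c(16L, 32L))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("renyi_q%s_b%d", sub("\\.", "", q), b),
      family = "renyi", p1 = b, p2 = q)
  for (q in c(0.5, 2, 3)) for (b in c(16L, 32L))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("tsallis_q%s_b%d", sub("\\.", "", q), b),
      family = "tsallis", p1 = b, p2 = q)
  do.call(rbind, rows)
}

#' Default EEG frequency bands (Hz)
#'
#' Low-frequency component plus the five common brain-wave bands.
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
default_bands <- function() {
  data.frame(name = c("lowfreq", "delta", "theta", "alpha", "beta", "gamma"),
             low  = c(0, 0.5, 4, 8, 12, 30),
             high = c(0.5, 4, 8, 12, 30, 45))
}

#' Feature extraction configuration
#'
#' The default configuration yields M = 46 features per channel: 37 entropy
#' features ([default_entropy_grid()]), 8 frequency-domain features (6
#' relative band powers, log10 total power in \[0, 45\] Hz, and peak
#' frequency) and the mean absolute amplitude. Power spectra come from a
#' Welch estimator with 1-s Hann segments at 50% overlap.
#'
#' @param fs Sampling rate in Hz.
#' @param entropy_grid Entropy feature table, see [default_entropy_grid()].
#' @param bands Band table, see [default_bands()].
#' @param include_total_power,include_peak_freq,include_mean_amplitude
#'   Flags for the non-band frequency features and the amplitude feature.
#' @return Object of class `feature_config`; `$M` is the feature count and
#'   `$names` the stable column manifest.
#' @export
feature_config <- function(fs = 256, entropy_grid = default_entropy_grid(),
                           bands = default_bands(),
                           include_total_power = TRUE,
                           include_peak_freq = TRUE,
                           include_mean_amplitude = TRUE) {
  if (fs <= 2 * max(bands$high))
    stop("fs must exceed twice the highest band edge", call. = FALSE)
  nms <- c(entropy_grid$name,
           paste0("relpow_", bands$name),
           if (include_total_power) "total_power_log10",
           if (include_peak_freq) "peak_freq",
           if (include_mean_amplitude) "mean_amplitude")
  structure(list(fs = fs, entropy_grid = entropy_grid, bands = bands,
                 include_total_power = include_total_power,
                 include_peak_freq = include_peak_freq,
                 include_mean_amplitude = include_mean_amplitude,
                 psd = "welch, 1-s hann segments, 50% overlap",
                 M = length(nms), names = nms),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("Feature config: M =", x$M, "features (",
      nrow(x$entropy_grid), "entropy,",
      nrow(x$bands) + x$include_total_power + x$include_peak_freq,
      "frequency,", as.integer(x$include_mean_amplitude), "amplitude ), fs =",
      x$fs, "Hz\n")
  invisible(x)
}

# Welch PSD: mean of Hann-windowed periodograms over `seg`-sample segments
# at 50% overlap. Returns freq (Hz) and power density (arbitrary scale; all
# downstream uses are relative).
welch_psd <- function(x, fs, seg = fs) {
  seg <- as.integer(seg)
  n <- length(x)
  if (n < seg) seg <- n
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  scale <- sum(w^2)
  nf <- seg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    X <- fft(xs * w)
    acc <- acc + (Mod(X[seq_len(nf)])^2) / scale
  }
  list(freq = (seq_len(nf) - 1) * fs / seg, power = acc / length(starts))
}

#' Relative band-power features of one channel window
#'
#' Power spectral density via Welch's method, then band power divided by
#' the total power over \[0, 45\] Hz, so the six default bands sum to 1.
#' An all-zero window cannot be normalized; it falls back to uniform
#' `1/nrow(bands)` with attribute `flat = TRUE`.
#'
#' @param x Numeric vector, one channel of one window (>= 2 s of samples).
#' @param fs Sampling rate (Hz).
#' @param bands Band table, see [default_bands()].
#' @return Numeric vector of relative powers, one per band.
#' @export
compute_band_power_features <- function(x, fs, bands = default_bands()) {
  if (length(x) < 2 * fs)
    stop("window must hold at least 2 s of samples", call. = FALSE)
  if (all(x == 0)) {
    out <- rep(1 / nrow(bands), nrow(bands))
    names(out) <- paste0("relpow_", bands$name)
    attr(out, "flat") <- TRUE
    return(out)
  }
  .band_powers_from_psd(welch_psd(x, fs), bands)
}

.band_powers_from_psd <- function(psd, bands) {
  hi <- max(bands$high)
  tot <- sum(psd$power[psd$freq <= hi])
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- psd$freq >= bands$low[i] & psd$freq < bands$high[i]
    sum(psd$power[sel]) / tot
  }, numeric(1))
  names(out) <- paste0("relpow_", bands$name)
  out
}

# histogram probabilities over `bins` equal-width bins spanning the window
# range; a constant window collapses to a single occupied bin.
.hist_probs <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(1)
  idx <- pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
  tab <- tabulate(idx, nbins = bins)
  tab[tab > 0] / length(x)
}

.shannon <- function(p) -sum(p * log2(p))
.renyi <- function(p, q) if (q == 1) .shannon(p) else log2(sum(p^q)) / (1 - q)
.tsallis <- function(p, q) if (q == 1) .shannon(p) * log(2) else
  (1 - sum(p^q)) / (q - 1)

# non-overlapping coarse-graining at integer scale s (multiscale entropy)
.coarse_grain <- function(x, s) {
  if (s == 1L) return(x)
  n <- length(x) %/% s
  colMeans(matrix(x[seq_len(n * s)], nrow = s))
}

#' Entropy features of one channel window
#'
#' Evaluates every row of an entropy grid (see [default_entropy_grid()]) on
#' the window. Constant windows return each family's analytic floor (0 for
#' histogram and permutation entropies, 0 for sample entropy since all
#' templates match), never NaN.
#'
#' @param x Numeric vector, one channel of one window.
#' @param grid Entropy grid data.frame.
#' @return Named numeric vector, one finite value per grid row.
#' @export
compute_entropy_features <- function(x, grid = default_entropy_grid()) {
  out <- numeric(nrow(grid))
  sampen_cache <- list()
  for (i in seq_len(nrow(grid))) {
    fam <- grid$family[i]
    out[i] <- switch(
      fam,
      sample = {
        s <- as.integer(grid$p2[i])
        key <- as.character(s)
        if (is.null(sampen_cache[[key]])) {
          xc <- .coarse_grain(x, s)
          r <- 0.2 * sd(xc)
          if (!is.finite(r) || r == 0) r <- 1e-12
          sampen_cache[[key]] <- sampen23_cpp(xc, r)
        }
        sampen_cache[[key]][grid$p1[i] - 1L]
      },
      permutation = perm_entropy_cpp(x, as.integer(grid$p1[i]),
                                     as.integer(grid$p2[i]), TRUE),
      shannon = .shannon(.hist_probs(x, as.integer(grid$p1[i]))),
      renyi = .renyi(.hist_probs(x, as.integer(grid$p1[i])), grid$p2[i]),
      tsallis = .tsallis(.hist_probs(x, as.integer(grid$p1[i])), grid$p2[i]),
      stop("unknown entropy family: ", fam, call. = FALSE))
  }
  names(out) <- grid$name
  out
}

#' Mean absolute amplitude of a window
#'
#' Sign-invariant amplitude summary: `mean(abs(x))`.
#' @param x Numeric vector.
#' @return Scalar.
#' @export
compute_mean_amplitude <- function(x) {
  if (length(x) == 0L) stop("empty window", call. = FALSE)
  mean(abs(x))
}

#' Extract the N x M raw feature matrix of one multichannel window
#'
#' Row `n` holds the M features of channel `n` in the fixed manifest order
#' of `cfg$names`. Extraction is deterministic and channel-order
#' equivariant: permuting the rows of `window` permutes the output rows
#' identically.
#'
#' @param window Numeric matrix, channels x samples.
#' @param cfg A [feature_config()].
#' @return N x M numeric matrix with `cfg$names` as column names.
#' @export
extract_window_features <- function(window, cfg) {
  if (!is.matrix(window)) window <- matrix(window, nrow = 1L)
  N <- nrow(window)
  out <- matrix(NA_real_, nrow = N, ncol = cfg$M,
                dimnames = list(NULL, cfg$names))
  hi <- max(cfg$bands$high)
  for (n in seq_len(N)) {
    x <- window[n, ]
    ent <- compute_entropy_features(x, cfg$entropy_grid)
    flat <- all(x == 0)
    psd <- if (!flat) welch_psd(x, cfg$fs)
    bp <- if (flat) compute_band_power_features(x, cfg$fs, cfg$bands)
          else .band_powers_from_psd(psd, cfg$bands)
    extra <- numeric(0)
    if (cfg$include_total_power || cfg$include_peak_freq) {
      if (flat) psd <- welch_psd(x, cfg$fs)
      sel <- psd$freq <= hi
      if (cfg$include_total_power)
        extra <- c(extra, total_power_log10 =
                     log10(sum(psd$power[sel]) + 1e-12))
      if (cfg$include_peak_freq) {
        inband <- psd$freq >= 0.5 & psd$freq <= hi
        pk <- if (any(inband)) psd$freq[inband][which.max(psd$power[inband])]
              else 0
        extra <- c(extra, peak_freq = pk)
      }
    }
    if (cfg$include_mean_amplitude)
      extra <- c(extra, mean_amplitude = compute_mean_amplitude(x))
    out[n, ] <- c(ent, bp, extra)
  }
  out
}

#' Fit the per-feature normalization used before discretization
#'
#' Bounds are the 1st/99th percentiles of each feature pooled across all
#' training windows and all channels, so one value-level memory serves
#' every feature. Fit on the training split only. Degenerate (constant)
#' features are widened by a small epsilon so `lower < upper` always holds.
#'
#' @param feature_list List of N x M raw feature matrices (training
#'   windows).
#' @param L Number of discretization levels (must match the value-level
#'   memory).
#' @param probs Lower/upper percentile pair, default `c(0.01, 0.99)`.
#' @return Object of class `normalization_state` with vectors `lower`,
#'   `upper` of length M.
#' @export
fit_normalization <- function(feature_list, L = 20L, probs = c(0.01, 0.99)) {
  if (length(feature_list) < 2L)
    stop("need at least 2 training windows to fit normalization",
         call. = FALSE)
  M <- ncol(feature_list[[1L]])
  stacked <- do.call(rbind, feature_list)   # (n_windows*N) x M
  lower <- upper <- numeric(M)
  for (m in seq_len(M)) {
    qs <- quantile(stacked[, m], probs = probs, names = FALSE, na.rm = TRUE)
    if (qs[2] <= qs[1]) {
      eps <- max(1e-6 * max(1, abs(qs[1])), 1e-9)
      qs <- c(qs[1] - eps, qs[1] + eps)
    }
    lower[m] <- qs[1]; upper[m] <- qs[2]
  }
  structure(list(lower = lower, upper = upper, L = as.integer(L), M = M,
                 probs = probs, names = colnames(feature_list[[1L]])),
            class = "normalization_state")
}

#' Map raw feature values onto discrete levels
#'
#' Linear map of `[lower, upper]` onto `{0, ..., L-1}` per feature
#' (rounded); values outside the bounds clip to the end levels. Monotone by
#' construction.
#'
#' @param values N x M raw feature matrix.
#' @param state A fitted [fit_normalization()] state.
#' @return N x M integer matrix of level indices in `[0, L)`.
#' @export
discretize <- function(values, state) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  if (ncol(values) != state$M)
    stop("feature count mismatch: ", ncol(values), " vs fitted ", state$M,
         call. = FALSE)
  L <- state$L
  lev <- round(sweep(sweep(values, 2L, state$lower), 2L,
                     state$upper - state$lower, "/") * (L - 1L))
  lev[lev < 0] <- 0
  lev[lev > L - 1L] <- L - 1L
  mode(lev) <- "integer"
  lev
}
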