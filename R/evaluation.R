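#' Label post-processing configuration
#'
#' @param SWlen Smoothing window length in seconds (default 5).
#' @param Wstep Label granularity in seconds (default 1, the prediction
#'   step).
#' @param causal Use a trailing (causal) window instead of the default
#'   centered one. The centered window suits offline evaluation; causal
#'   mode matches a real-time monitor.
#' @return Object of class `postprocess_config`.
#' @export
postprocess_config <- function(SWlen = 5, Wstep = 1, causal = FALSE) {
  if (SWlen < Wstep) stop("SWlen must be >= Wstep", call. = FALSE)
  structure(list(SWlen = SWlen, Wstep = Wstep, causal = causal,
                 size = max(1L, as.integer(round(SWlen / Wstep)))),
            class = "postprocess_config")
}

#' Majority-vote smoothing of a binary label sequence
#'
#' A moving window of `SWlen / Wstep` samples slides over the predicted
#' labels; each output sample is the majority vote inside the window
#' (centered by default; truncated at the edges; exact ties resolve to
#' interictal, i.e. 0). Removes isolated false positives and fills short
#' gaps inside detected seizures.
#'
#' @param labels Integer/logical vector of 0/1 labels at `Wstep`
#'   granularity.
#' @param cfg A [postprocess_config()].
#' @return Smoothed 0/1 integer vector, same length.
#' @export
smooth_labels <- function(labels, cfg = postprocess_config()) {
  n <- length(labels)
  if (n == 0L) stop("empty label sequence", call. = FALSE)
  labels <- as.integer(labels)
  k <- cfg$size
  cs <- c(0L, cumsum(labels))
  if (cfg$causal) {
    lo <- pmax(0L, seq_len(n) - k)
    hi <- seq_len(n)
  } else {
    half <- (k - 1L) %/% 2L
    lo <- pmax(0L, seq_len(n) - 1L - half)
    hi <- pmin(n, seq_len(n) + (k - 1L - half))
  }
  ones <- cs[hi + 1L] - cs[lo + 1L]
  size <- hi - lo
  as.integer(ones * 2L > size)
}

#' Extract seizure episodes from a binary label sequence
#'
#' Maximal runs of 1s, as half-open `[start, end)` index pairs (1-based
#' start, exclusive end).
#'
#' @param labels 0/1 vector.
#' @return Integer matrix with columns `start`, `end`; zero rows if no
#'   episode.
#' @export
extract_episodes <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n == 0L || !any(labels == 1L))
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  d <- diff(c(0L, labels, 0L))
  starts <- which(d == 1L)
  ends <- which(d == -1L)
  cbind(start = starts, end = ends)
}

.rates <- function(TP, FP, FN) {
  flag <- FALSE
  tpr <- if (TP + FN > 0) TP / (TP + FN) else { flag <- TRUE; 0 }
  ppv <- if (TP + FP > 0) TP / (TP + FP) else { flag <- TRUE; 0 }
  f1 <- if (tpr + ppv > 0) 2 * tpr * ppv / (tpr + ppv) else { flag <- TRUE; 0 }
  list(TPR = tpr, PPV = ppv, F1 = f1, flag = flag)
}

#' Duration-level (sample-wise) detection counts
#'
#' Every sample is equally important and scored independently:
#' TP/FP/FN counts over samples.
#'
#' @param pred,truth Equal-length 0/1 vectors.
#' @return List with `TP`, `FP`, `FN`.
#' @export
duration_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length", call. = FALSE)
  pred <- as.integer(pred); truth <- as.integer(truth)
  list(TP = sum(pred == 1L & truth == 1L),
       FP = sum(pred == 1L & truth == 0L),
       FN = sum(pred == 0L & truth == 1L))
}

#' Episode-level detection counts
#'
#' A truth episode counts as one TP if any predicted seizure sample
#' overlaps it (however many predicted episodes touch it), else one FN. A
#' predicted episode that overlaps no truth episode is one FP; a predicted
#' episode spanning several truth episodes detects all of them and incurs
#' no FP. No pre/post tolerance margin is applied by default.
#'
#' @inheritParams duration_counts
#' @return List with `TP`, `FP`, `FN`.
#' @export
episode_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length", call. = FALSE)
  pred <- as.integer(pred); truth <- as.integer(truth)
  te <- extract_episodes(truth)
  pe <- extract_episodes(pred)
  overlaps <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]
  TP <- 0L; FN <- 0L
  for (i in seq_len(nrow(te))) {
    hit <- any(vapply(seq_len(nrow(pe)),
                      function(j) overlaps(te[i, ], pe[j, ]), logical(1)))
    if (hit) TP <- TP + 1L else FN <- FN + 1L
  }
  FP <- 0L
  for (j in seq_len(nrow(pe))) {
    hit <- any(vapply(seq_len(nrow(te)),
                      function(i) overlaps(te[i, ], pe[j, ]), logical(1)))
    if (!hit) FP <- FP + 1L
  }
  list(TP = TP, FP = FP, FN = FN)
}

#' Duration-level TPR/PPV/F1
#' @inheritParams duration_counts
#' @return List with `TPR`, `PPV`, `F1` (zero denominators give 0 with
#'   `flag = TRUE`).
#' @export
duration_metrics <- function(pred, truth) {
  cnt <- duration_counts(pred, truth)
  .rates(cnt$TP, cnt$FP, cnt$FN)
}

#' Episode-level TPR/PPV/F1
#' @inheritParams duration_counts
#' @return List with `TPR`, `PPV`, `F1` (zero denominators give 0 with
#'   `flag = TRUE`).
#' @export
episode_metrics <- function(pred, truth) {
  cnt <- episode_counts(pred, truth)
  .rates(cnt$TP, cnt$FP, cnt$FN)
}

#' Geometric mean of duration- and episode-level F1
#'
#' `F1DEgmean = sqrt(F1D * F1E)` — the single headline figure combining
#' both evaluation views.
#'
#' @param f1d,f1e F1 scores in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
f1_de_gmean <- function(f1d, f1e) {
  stopifnot(f1d >= 0, f1d <= 1, f1e >= 0, f1e <= 1)
  sqrt(f1d * f1e)
}

#' Assemble detection scores from pooled counts
#' @param ep,du Lists with `TP`, `FP`, `FN` at episode and duration level.
#' @return Object of class `detection_scores` with `episode`, `duration`
#'   (each TPR/PPV/F1) and `F1DEgmean`.
#' @export
detection_scores <- function(ep, du) {
  e <- .rates(ep$TP, ep$FP, ep$FN)
  d <- .rates(du$TP, du$FP, du$FN)
  structure(list(episode = e, duration = d,
                 F1DEgmean = f1_de_gmean(d$F1, e$F1),
                 counts = list(episode = ep, duration = du)),
            class = "detection_scores")
}

#' @export
print.detection_scores <- function(x, ...) {
  cat(sprintf(
    "episode  TPR %.3f PPV %.3f F1 %.3f\nduration TPR %.3f PPV %.3f F1 %.3f\nF1DEgmean %.3f\n",
    x$episode$TPR, x$episode$PPV, x$episode$F1,
    x$duration$TPR, x$duration$PPV, x$duration$F1, x$F1DEgmean))
  invisible(x)
}

#' Score predicted labels against truth, per file, raw and smoothed
#'
#' Splits the label streams by file, orders each by window start time,
#' smooths predictions within each file only, pools TP/FP/FN over files at
#' both episode and duration level, and forms the rates.
#'
#' @param pred,truth 0/1 vectors over all windows.
#' @param file_id Per-window file identifier.
#' @param start Per-window start time in seconds (ordering within file).
#' @param cfg A [postprocess_config()].
#' @return List with `raw` and `smoothed` [detection_scores()].
#' @export
score_predictions <- function(pred, truth, file_id, start,
                              cfg = postprocess_config()) {
  ep_r <- du_r <- ep_s <- du_s <- list(TP = 0L, FP = 0L, FN = 0L)
  addc <- function(a, b) list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                              FN = a$FN + b$FN)
  for (f in unique(file_id)) {
    sel <- which(file_id == f)
    sel <- sel[order(start[sel])]
    p <- pred[sel]; t <- truth[sel]
    ps <- smooth_labels(p, cfg)
    ep_r <- addc(ep_r, episode_counts(p, t))
    du_r <- addc(du_r, duration_counts(p, t))
    ep_s <- addc(ep_s, episode_counts(ps, t))
    du_s <- addc(du_s, duration_counts(ps, t))
  }
  list(raw = detection_scores(ep_r, du_r),
       smoothed = detection_scores(ep_s, du_s))
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares per-subject performance of two methods. Uses the exact
#' signed-rank distribution for n <= 25 when differences are free of ties
#' and zeros, the normal approximation otherwise. If every difference is
#' zero the test is degenerate; p = 1 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b Equal-length (>= 5) paired score vectors.
#' @return p-value (two-sided).
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  if (length(a) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz))) && all(d != 0)
  suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = exact)$p.value)
}
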