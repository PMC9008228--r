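# Independent brute-force oracles, deliberately written with plain loops
# and no shared code with the package internals.

oracle_bundle <- function(vecs, tiebreak) {
  # vecs: list of 0/1 vectors
  D <- length(vecs[[1]])
  n <- length(vecs)
  out <- integer(D)
  for (d in seq_len(D)) {
    s <- 0L
    for (v in vecs) s <- s + v[d]
    out[d] <- if (2 * s > n) 1L else if (2 * s < n) 0L else tiebreak[d]
  }
  out
}

oracle_encode <- function(levels, cfm, vlm, tiebreak) {
  # materialize every bound pair, then majority-vote
  N <- nrow(levels); M <- ncol(levels)
  bound <- list()
  for (n in seq_len(N)) for (m in seq_len(M)) {
    item <- cfm$vectors[(n - 1) * M + m, ]
    val <- vlm$levels[levels[n, m] + 1L, ]
    bound[[length(bound) + 1L]] <- as.integer(xor(item, val))
  }
  oracle_bundle(bound, tiebreak)
}

oracle_smooth <- function(labels, k) {
  n <- length(labels)
  out <- integer(n)
  half <- (k - 1) %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + (k - 1 - half))
    w <- labels[lo:hi]
    out[i] <- if (sum(w == 1) * 2 > length(w)) 1L else 0L
  }
  out
}

oracle_episodes <- function(labels) {
  eps <- list()
  inrun <- FALSE
  start <- NA
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && !inrun) { inrun <- TRUE; start <- i }
    if (labels[i] == 0 && inrun) {
      inrun <- FALSE
      eps[[length(eps) + 1L]] <- c(start, i)
    }
  }
  if (inrun) eps[[length(eps) + 1L]] <- c(start, length(labels) + 1L)
  eps
}

oracle_episode_counts <- function(pred, truth) {
  te <- oracle_episodes(truth)
  pe <- oracle_episodes(pred)
  tp <- 0L; fn <- 0L; fp <- 0L
  for (e in te) {
    if (any(pred[e[1]:(e[2] - 1)] == 1)) tp <- tp + 1L else fn <- fn + 1L
  }
  for (e in pe) {
    if (all(truth[e[1]:(e[2] - 1)] == 0)) fp <- fp + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}

oracle_duration_counts <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}

# tiny deterministic encoded dataset built directly from bit patterns
make_bit_dataset <- function(vectors, labels, file_id = NULL,
                             start = NULL) {
  m <- if (length(vectors)) do.call(rbind, vectors) else matrix(0L, 0, 0)
  n <- nrow(m)
  structure(list(vectors = m, label = labels,
                 start = if (is.null(start)) seq_len(n) - 1 else start,
                 file_id = if (is.null(file_id)) rep(1L, n) else file_id),
            class = "encoded_dataset")
}
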