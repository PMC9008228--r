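#' hdseizure: multi-centroid hyperdimensional computing for seizure detection
#'
#' Binary hypervector algebra, EEG feature encoding, single-pass
#' multi-centroid training with sub-class reduction, and episode/duration
#' detection metrics under leave-one-seizure-out cross-validation.
#'
#' @useDynLib hdseizure, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft quantile rnorm rpois runif sd wilcox.test
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

.check_hv <- function(a, arg = "hypervector") {
  if (!is.numeric(a) || length(a) < 1L)
    stop(arg, " must be a non-empty 0/1 vector", call. = FALSE)
  if (any(a != 0L & a != 1L))
    stop(arg, " has elements outside {0,1}", call. = FALSE)
  invisible(TRUE)
}

.check_same_dim <- function(a, b) {
  if (length(a) != length(b))
    stop("hypervector dimension mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  invisible(TRUE)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Generate a random binary hypervector
#'
#' Each bit is drawn i.i.d. uniform from \{0,1\}. Two hypervectors drawn
#' independently at large `D` sit at normalized Hamming distance ~0.5, the
#' quasi-orthogonality that hyperdimensional computing relies on.
#'
#' @param D Dimension (number of bits); default 10,000.
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return Integer vector of `D` bits (0/1).
#' @export
#' @examples
#' v <- hv_random(64, seed = 1)
#' hv_hamming(v, hv_random(64, seed = 2))
hv_random <- function(D = 10000L, seed = NULL) {
  if (length(D) != 1L || is.na(D) || D < 2)
    stop("D must be a single integer >= 2", call. = FALSE)
  .with_seed(seed, sample(c(0L, 1L), as.integer(D), replace = TRUE))
}

#' Bind two hypervectors (XOR)
#'
#' Binding associates two hypervectors into one representing their pair.
#' XOR is self-inverse (`hv_bind(hv_bind(a, b), b) == a`) and an isometry of
#' Hamming space: it moves every vector by the same distance pattern.
#'
#' @param a,b Hypervectors of equal dimension.
#' @return The element-wise XOR.
#' @export
hv_bind <- function(a, b) {
  .check_hv(a, "a"); .check_hv(b, "b"); .check_same_dim(a, b)
  bitwXor(as.integer(a), as.integer(b))
}

#' Bundle hypervectors by per-bit majority vote
#'
#' Per-bit summation followed by thresholding at half the list length. With
#' an even number of inputs a column can tie exactly; tied bits copy the
#' corresponding bit of `tiebreak`, a fixed random vector drawn once per
#' model so bundling stays deterministic and unbiased in expectation.
#'
#' @param vs List of hypervectors (or a matrix with one vector per row).
#' @param tiebreak Hypervector consulted on exact ties.
#' @return Majority-vote hypervector.
#' @export
hv_bundle <- function(vs, tiebreak) {
  if (is.matrix(vs)) {
    m <- vs
  } else {
    if (!is.list(vs) || length(vs) == 0L)
      stop("vs must be a non-empty list of hypervectors", call. = FALSE)
    dims <- lengths(vs)
    if (any(dims != dims[1L]))
      stop("hypervector dimension mismatch in bundle", call. = FALSE)
    m <- do.call(rbind, vs)
  }
  if (nrow(m) == 0L) stop("cannot bundle zero hypervectors", call. = FALSE)
  .check_hv(tiebreak, "tiebreak")
  if (ncol(m) != length(tiebreak))
    stop("tiebreak dimension mismatch", call. = FALSE)
  counts <- colSums(m)
  n <- nrow(m)
  out <- as.integer(counts * 2L > n)
  tie <- counts * 2L == n
  out[tie] <- as.integer(tiebreak[tie])
  out
}

#' Normalized Hamming distance between two hypervectors
#'
#' @param a,b Hypervectors of equal dimension.
#' @return Fraction of differing bit positions, in \[0, 1\].
#' @export
hv_hamming <- function(a, b) {
  .check_same_dim(a, b)
  mean(a != b)
}

#' Initialize the channel-feature item memory
#'
#' One independent random hypervector per (channel, feature) pair: the
#' codebook `HDV_ChFeat` binding gives each measurement its identity. There
#' is no relation between channels or features, so entries are mutually
#' quasi-orthogonal by construction.
#'
#' @param N Number of channels.
#' @param M Number of features per channel.
#' @param D Hypervector dimension.
#' @param seed Integer seed (memories must be reproducible).
#' @return Object of class `channel_feature_memory`: an `(N*M) x D` bit
#'   matrix plus metadata; row for channel `n`, feature `m` is
#'   `(n-1)*M + m`.
#' @export
channel_feature_memory <- function(N, M, D = 10000L, seed = NULL) {
  if (N < 1 || M < 1) stop("N and M must be >= 1", call. = FALSE)
  if (D < 2) stop("D must be >= 2", call. = FALSE)
  vectors <- .with_seed(seed, matrix(
    sample(c(0L, 1L), as.integer(N) * as.integer(M) * as.integer(D),
           replace = TRUE),
    nrow = N * M, ncol = D))
  structure(list(vectors = vectors, N = as.integer(N), M = as.integer(M),
                 D = as.integer(D), seed = seed),
            class = "channel_feature_memory")
}

#' Row index of a (channel, feature) pair in the item memory
#' @param n Channel index (1-based).
#' @param m Feature index (1-based).
#' @param cfm A `channel_feature_memory`.
#' @export
cfm_index <- function(n, m, cfm) {
  stopifnot(n >= 1, n <= cfm$N, m >= 1, m <= cfm$M)
  (as.integer(n) - 1L) * cfm$M + as.integer(m)
}

#' Initialize the value-level memory
#'
#' Codebook `HDV_Val` for discretized feature values. Level 0 is random;
#' level `i+1` equals level `i` except inside the i-th disjoint block of
#' `d = floor(D / (L-1))` bit positions, whose contents are replaced. The
#' blocks are disjoint, so the expected distance between levels grows
#' linearly with their separation: nearby values stay similar, distant
#' values approach quasi-orthogonality.
#'
#' @param L Number of discretization levels (>= 2).
#' @param D Hypervector dimension (>= L).
#' @param seed Integer seed.
#' @param scheme Either `"rerandomize"` (default; block contents replaced by
#'   fresh random bits) or `"shuffle"` (block contents permuted in place).
#' @return Object of class `value_level_memory` with an `L x D` bit matrix
#'   `levels` (row `i` is level `i-1`) and the block size `d`.
#' @export
value_level_memory <- function(L = 20L, D = 10000L, seed = NULL,
                               scheme = c("rerandomize", "shuffle")) {
  scheme <- match.arg(scheme)
  if (L < 2) stop("L must be >= 2", call. = FALSE)
  if (D < L) stop("D must be >= L", call. = FALSE)
  L <- as.integer(L); D <- as.integer(D)
  d <- D %/% (L - 1L)
  levels <- .with_seed(seed, {
    m <- matrix(0L, nrow = L, ncol = D)
    m[1L, ] <- sample(c(0L, 1L), D, replace = TRUE)
    for (i in seq_len(L - 1L)) {
      block <- ((i - 1L) * d + 1L):(i * d)
      m[i + 1L, ] <- m[i, ]
      m[i + 1L, block] <- if (scheme == "rerandomize")
        sample(c(0L, 1L), d, replace = TRUE)
      else
        m[i, block][sample.int(d)]
    }
    m
  })
  structure(list(levels = levels, L = L, D = D, d = d, scheme = scheme,
                 seed = seed),
            class = "value_level_memory")
}

#' Create the full set of HD memories for one model
#'
#' Bundles the channel-feature item memory, the value-level memory and the
#' model's fixed tiebreak vector, all derived deterministically from one
#' seed. Memories are generated once per subject/model and serialized with
#' it; re-encoding with the same memories is bit-exact.
#'
#' @param N Channels.
#' @param M Features per channel.
#' @param D Hypervector dimension (default 10,000).
#' @param L Discretization levels (default 20).
#' @param seed Integer seed.
#' @param scheme Level-memory construction scheme, see
#'   [value_level_memory()].
#' @return Object of class `hd_memories`.
#' @export
hd_memories <- function(N, M, D = 10000L, L = 20L, seed = 1L,
                        scheme = "rerandomize") {
  seed <- as.integer(seed)
  mem <- withr::with_seed(seed, {
    cfm <- channel_feature_memory(N, M, D, seed = NULL)
    vlm <- value_level_memory(L, D, seed = NULL, scheme = scheme)
    tiebreak <- hv_random(D, seed = NULL)
    list(cfm = cfm, vlm = vlm, tiebreak = tiebreak)
  })
  structure(c(mem, list(N = as.integer(N), M = as.integer(M),
                        D = as.integer(D), L = as.integer(L), seed = seed)),
            class = "hd_memories")
}

#' @export
print.hd_memories <- function(x, ...) {
  cat("HD memories: D =", x$D, ", N =", x$N, "channels x M =", x$M,
      "features,", x$L, "value levels (d =", x$vlm$d, "), seed", x$seed, "\n")
  invisible(x)
}
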