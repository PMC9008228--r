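.LAB_LEVELS <- c("interictal", "ictal")   # code 0, 1

.labels_to_code <- function(label) {
  code <- match(label, .LAB_LEVELS) - 1L
  if (anyNA(code)) stop("labels must be 'ictal' or 'interictal'",
                        call. = FALSE)
  code
}

.check_both_labels <- function(label) {
  missing <- setdiff(.LAB_LEVELS, unique(label))
  if (length(missing))
    stop("training data contains no '", missing[1L], "' windows",
         call. = FALSE)
}

.build_model <- function(fit, D, tiebreak, kind) {
  structure(list(
    D = D,
    tiebreak = tiebreak,
    acc = fit$acc,                       # k x D integer bit sums
    proto = fit$proto,                   # k x D binarized prototypes
    count = fit$count,
    label = .LAB_LEVELS[fit$label + 1L],
    kind = kind,
    creation_log = data.frame(
      window = seq_along(fit$log_action),
      action = c("assigned", "created")[fit$log_action + 1L],
      subclass = fit$log_subclass)),
    class = "hd_model")
}

#' Train the classic 2-class HD model
#'
#' All windows of one class are bundled (bit-wise sum, majority-vote
#' binarization) into a single prototype: one ictal, one interictal. This
#' is the baseline against which the multi-centroid model is compared.
#'
#' @param ds An [encode_dataset()] result containing both labels.
#' @param memories The [hd_memories()] the windows were encoded with (only
#'   the tiebreak vector is used).
#' @return An `hd_model` with exactly two sub-classes.
#' @export
train_2class <- function(ds, memories) {
  .check_both_labels(ds$label)
  fit <- hd_train_cpp(ds$vectors, .labels_to_code(ds$label),
                      memories$tiebreak, FALSE)
  .build_model(fit, ncol(ds$vectors), memories$tiebreak, "2class")
}

#' Train the multi-centroid HD model (single pass)
#'
#' Windows are consumed once, in order. The first window of a label opens
#' that label's first sub-class. Every later window is compared with all
#' sub-class prototypes: if the globally nearest prototype carries the
#' correct label, the window is added to the nearest sub-class of its own
#' label and that prototype is refreshed; if the nearest prototype belongs
#' to the wrong class, a new sub-class of the correct label is created,
#' initialized with the window. The number of sub-classes per label is
#' therefore decided by the data, capturing distinct seizure and background
#' sub-types without presetting their count. Training is order-dependent by
#' design (single pass).
#'
#' @inheritParams train_2class
#' @return An `hd_model`; `$creation_log` records, per window, whether it
#'   was assigned to an existing sub-class or created a new one.
#' @export
train_multicentroid <- function(ds, memories) {
  .check_both_labels(ds$label)
  fit <- hd_train_cpp(ds$vectors, .labels_to_code(ds$label),
                      memories$tiebreak, TRUE)
  .build_model(fit, ncol(ds$vectors), memories$tiebreak, "multicentroid")
}

#' @export
print.hd_model <- function(x, ...) {
  cat("HD", x$kind, "model: D =", x$D, ",",
      sum(x$label == "ictal"), "ictal +",
      sum(x$label == "interictal"), "interictal sub-classes,",
      sum(x$count), "training windows\n")
  invisible(x)
}

#' Number of sub-classes per label
#' @param model An `hd_model`.
#' @return Named integer vector with entries `ictal` and `interictal`.
#' @export
n_subclasses <- function(model) {
  c(ictal = sum(model$label == "ictal"),
    interictal = sum(model$label == "interictal"))
}

# normalized Hamming distances between every row of bits (n x D) and every
# prototype (k x D); 0/1 matrices allow d(a,b) = |a| + |b| - 2 a.b
.hamming_to_protos <- function(bits, proto, D) {
  (outer(rowSums(bits), rowSums(proto), "+") -
     2 * tcrossprod(bits, proto)) / D
}

#' Classify hypervectors against a model's sub-class prototypes
#'
#' Nearest-prototype search under normalized Hamming distance; the label of
#' the most similar sub-class wins. Exact distance ties go to the lowest
#' sub-class index, so prediction is deterministic.
#'
#' @param model An `hd_model`.
#' @param v A single hypervector or an n x D bit matrix (or an
#'   `encoded_dataset`).
#' @return data.frame with columns `label`, `subclass`, `distance`, one row
#'   per input vector.
#' @export
hd_predict <- function(model, v) {
  if (inherits(v, "encoded_dataset")) v <- v$vectors
  if (!is.matrix(v)) v <- matrix(as.integer(v), nrow = 1L)
  if (ncol(v) != model$D)
    stop("dimension mismatch: vectors are ", ncol(v), "-bit, model is ",
         model$D, call. = FALSE)
  if (length(model$count) == 0L) stop("model has no sub-classes",
                                      call. = FALSE)
  dmat <- .hamming_to_protos(v, model$proto, model$D)
  best <- max.col(-dmat, ties.method = "first")
  data.frame(label = model$label[best], subclass = best,
             distance = dmat[cbind(seq_len(nrow(v)), best)])
}

#' Score a model on an encoded dataset
#'
#' Predicts every window, smooths the per-file binary label sequences with
#' the moving majority-vote window, and computes episode- and
#' duration-level detection scores. Smoothing never crosses file
#' boundaries; TP/FP/FN counts are pooled over files before rates are
#' formed. Used both for reporting and as the stopping criterion of the
#' sub-class reduction procedures (evaluated on the training set there).
#'
#' @param model An `hd_model`.
#' @param ds An `encoded_dataset` with labels, start times and file ids.
#' @param cfg A [postprocess_config()].
#' @return List with `raw` and `smoothed` [detection_scores()].
#' @export
evaluate_on <- function(model, ds, cfg = postprocess_config()) {
  if (nrow(ds$vectors) == 0L) stop("empty window list", call. = FALSE)
  pred <- as.integer(hd_predict(model, ds)$label == "ictal")
  truth <- as.integer(ds$label == "ictal")
  score_predictions(pred, truth, ds$file_id, ds$start, cfg)
}

# drop sub-classes by index, never emptying a label
.drop_subclasses <- function(model, idx) {
  keep <- setdiff(seq_along(model$count), idx)
  model$acc <- model$acc[keep, , drop = FALSE]
  model$proto <- model$proto[keep, , drop = FALSE]
  model$count <- model$count[keep]
  model$label <- model$label[keep]
  model
}

# least-populated subclasses (pooled over labels), protecting the last
# subclass of each label; returns indices to act on, at most `k`
.least_populated <- function(model, k) {
  ord <- order(model$count, seq_along(model$count))  # stable
  picked <- integer(0)
  remaining <- table(factor(model$label, levels = .LAB_LEVELS))
  for (i in ord) {
    lab <- model$label[i]
    if (remaining[[lab]] <= 1L) next
    picked <- c(picked, i)
    remaining[[lab]] <- remaining[[lab]] - 1L
    if (length(picked) >= k) break
  }
  picked
}

.rebinarize <- function(acc, count, tiebreak) {
  out <- as.integer(2L * acc > count)
  tie <- 2L * acc == count
  out[tie] <- as.integer(tiebreak[tie])
  out
}

# reduction gating monitors the smoothed train F1DEgmean, the same
# headline figure the evaluation reports
.reduce_gmean <- function(model, ds, cfg) {
  evaluate_on(model, ds, cfg)$smoothed$F1DEgmean
}

#' Shrink a multi-centroid model by removing rare sub-classes
#'
#' Sub-classes are sorted by the amount of training data they absorbed;
#' each step removes the `step_fraction` (of the initial count, ceiling, at
#' least 1) least-populated sub-classes, pooled over labels, then
#' re-evaluates the smoothed F1DEgmean on the training windows. The last
#' model whose training F1DEgmean is at least `(1 - tolerance)` times the
#' pre-reduction value is returned. The final sub-class of a label is never
#' removed.
#'
#' @param model A trained `hd_model`.
#' @param ds The training `encoded_dataset` the model was built from.
#' @param step_fraction Fraction of the initial sub-class count removed per
#'   step (default 0.10).
#' @param tolerance Allowed relative drop of training F1DEgmean (default
#'   0.03). Set `relative = FALSE` to read it as an absolute drop.
#' @param cfg [postprocess_config()] used when scoring.
#' @param relative Interpret `tolerance` relatively (default) or
#'   absolutely.
#' @return The reduced `hd_model`, with attribute `reduction_trace` (one
#'   row per step: sub-classes left, train F1DEgmean, accepted).
#' @export
reduce_by_removal <- function(model, ds, step_fraction = 0.10,
                              tolerance = 0.03,
                              cfg = postprocess_config(),
                              relative = TRUE) {
  .reduce_engine(model, ds, step_fraction, tolerance, cfg, relative,
                 merge = FALSE)
}

#' Shrink a multi-centroid model by clustering rare sub-classes
#'
#' As [reduce_by_removal()], but each selected least-populated sub-class is
#' merged into its nearest sub-class of the same label: accumulators and
#' counts are summed, so the merged prototype equals the majority vote over
#' all constituent training windows (bundling and re-normalizing, exact on
#' the accumulator representation). Total training-window count is
#' conserved. A label holding a single sub-class is skipped.
#'
#' @inheritParams reduce_by_removal
#' @return The reduced `hd_model` with attribute `reduction_trace`.
#' @export
reduce_by_clustering <- function(model, ds, step_fraction = 0.10,
                                 tolerance = 0.03,
                                 cfg = postprocess_config(),
                                 relative = TRUE) {
  .reduce_engine(model, ds, step_fraction, tolerance, cfg, relative,
                 merge = TRUE)
}

.reduce_engine <- function(model, ds, step_fraction, tolerance, cfg,
                           relative, merge) {
  initial <- .reduce_gmean(model, ds, cfg)
  floorv <- if (relative) (1 - tolerance) * initial else initial - tolerance
  step_k <- max(1L, ceiling(step_fraction * length(model$count)))
  trace <- data.frame(n_subclasses = length(model$count),
                      train_F1DEgmean = initial, accepted = TRUE)
  best <- model
  current <- model
  repeat {
    idx <- .least_populated(current, step_k)
    if (length(idx) == 0L) break
    if (merge) {
      # merge each selected sub-class into its nearest still-alive
      # same-label sub-class; data is conserved, never discarded
      alive <- rep(TRUE, length(current$count))
      dropped <- integer(0)
      for (i in idx) {
        same <- setdiff(which(alive & current$label == current$label[i]), i)
        if (length(same) == 0L) next
        d <- .hamming_to_protos(current$proto[i, , drop = FALSE],
                                current$proto[same, , drop = FALSE],
                                current$D)
        j <- same[which.min(d)]
        current$acc[j, ] <- current$acc[j, ] + current$acc[i, ]
        current$count[j] <- current$count[j] + current$count[i]
        current$proto[j, ] <- .rebinarize(current$acc[j, ],
                                          current$count[j],
                                          current$tiebreak)
        alive[i] <- FALSE
        dropped <- c(dropped, i)
      }
      if (length(dropped) == 0L) break
      current <- .drop_subclasses(current, dropped)
    } else {
      current <- .drop_subclasses(current, idx)
    }
    g <- .reduce_gmean(current, ds, cfg)
    ok <- g >= floorv
    trace <- rbind(trace, data.frame(n_subclasses = length(current$count),
                                     train_F1DEgmean = g, accepted = ok))
    if (ok) best <- current else break
    if (length(current$count) <= 2L) break
  }
  attr(best, "reduction_trace") <- trace
  best
}
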