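#' Encode one window's level matrix into a hypervector
#'
#' Each (channel n, feature m) cell binds its value hypervector
#' `HDV_Val[level]` to the pair's identity hypervector `HDV_ChFeat[n, m]`
#' (XOR); the N*M bound vectors are then bundled by per-bit majority vote
#' into a single vector representing the window. Channels are weighted
#' equally. With the default 18 x 46 layout the bundle size (828) is even,
#' so exact ties are resolved by the model tiebreak vector.
#'
#' @param levels N x M integer matrix of level indices in `[0, L)`.
#' @param memories An [hd_memories()] object (or `cfm`, `vlm`, `tiebreak`
#'   passed separately).
#' @return A hypervector of dimension D.
#' @export
encode_window <- function(levels, memories) {
  cfm <- memories$cfm; vlm <- memories$vlm; tiebreak <- memories$tiebreak
  if (!is.matrix(levels)) levels <- matrix(as.integer(levels), nrow = 1L)
  if (nrow(levels) != cfm$N || ncol(levels) != cfm$M)
    stop("level matrix is ", nrow(levels), "x", ncol(levels),
         " but memories expect ", cfm$N, "x", cfm$M, call. = FALSE)
  if (any(levels < 0L | levels >= vlm$L))
    stop("level index out of range [0, ", vlm$L, ")", call. = FALSE)
  counts <- hd_encode_counts_cpp(levels, t(cfm$vectors), t(vlm$levels))
  nm <- length(levels)
  out <- as.integer(2L * counts > nm)
  tie <- 2L * counts == nm
  out[tie] <- as.integer(tiebreak[tie])
  out
}

#' Encode a sequence of windows into an encoded dataset
#'
#' Order-preserving batch form of [encode_window()]. Labels, window start
#' times and file identifiers travel with the vectors so downstream
#' training and episode scoring can reconstruct each file's time line.
#'
#' @param level_list List of N x M integer level matrices, one per window.
#' @param memories An [hd_memories()] object.
#' @param label Character vector (`"ictal"` / `"interictal"`), one per
#'   window.
#' @param start Numeric vector of window start times in seconds.
#' @param file_id Character or integer vector of per-window file ids.
#' @return Object of class `encoded_dataset`: list with `vectors`
#'   (n x D bit matrix), `label`, `start`, `file_id`.
#' @export
encode_dataset <- function(level_list, memories, label,
                           start = seq_along(level_list) - 1,
                           file_id = rep(1L, length(level_list))) {
  n <- length(level_list)
  if (length(label) != n || length(start) != n || length(file_id) != n)
    stop("label, start and file_id must match the number of windows",
         call. = FALSE)
  bad <- !label %in% c("ictal", "interictal")
  if (any(bad))
    stop("labels must be 'ictal' or 'interictal'", call. = FALSE)
  if (n == 0L) {
    return(structure(list(vectors = matrix(0L, 0L, memories$D),
                          label = character(0), start = numeric(0),
                          file_id = file_id),
                     class = "encoded_dataset"))
  }
  for (i in seq_len(n)) {
    lv <- level_list[[i]]
    if (nrow(lv) != memories$cfm$N || ncol(lv) != memories$cfm$M)
      stop("window ", i, ": level matrix shape mismatch", call. = FALSE)
    if (any(lv < 0L | lv >= memories$vlm$L))
      stop("window ", i, ": level index out of range", call. = FALSE)
  }
  vectors <- hd_encode_dataset_cpp(level_list, t(memories$cfm$vectors),
                                   t(memories$vlm$levels), memories$tiebreak)
  structure(list(vectors = vectors, label = as.character(label),
                 start = as.numeric(start), file_id = file_id),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("Encoded dataset:", nrow(x$vectors), "windows, D =", ncol(x$vectors),
      "(", sum(x$label == "ictal"), "ictal /",
      sum(x$label == "interictal"), "interictal )\n")
  invisible(x)
}

# subset an encoded dataset by window index, keeping metadata aligned
subset_dataset <- function(ds, idx) {
  structure(list(vectors = ds$vectors[idx, , drop = FALSE],
                 label = ds$label[idx], start = ds$start[idx],
                 file_id = ds$file_id[idx]),
            class = "encoded_dataset")
}

# concatenate encoded datasets (same D)
bind_datasets <- function(dss) {
  structure(list(vectors = do.call(rbind, lapply(dss, `[[`, "vectors")),
                 label = unlist(lapply(dss, `[[`, "label")),
                 start = unlist(lapply(dss, `[[`, "start")),
                 file_id = unlist(lapply(dss, `[[`, "file_id"))),
            class = "encoded_dataset")
}
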