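#' Save a model (with its memories) to disk
#'
#' The container holds the sub-class accumulators, counts and labels, the
#' codebook memories and the tiebreak vector, so encoding and prediction
#' resume bit-exactly; a plain-text JSON side-car records the creation
#' parameters (D, L, d, N, M, seed) for audit.
#'
#' @param model An `hd_model`.
#' @param memories The [hd_memories()] it was trained with.
#' @param path Output path (an `.json` side-car is written next to it).
#' @param creation_log Include the per-window creation log (default TRUE).
#' @return `path`, invisibly.
#' @export
write_hd_model <- function(model, memories, path, creation_log = TRUE) {
  obj <- list(format = "hdseizure-model", version = 1L,
              model = model, memories = memories)
  if (!creation_log) obj$model$creation_log <- NULL
  saveRDS(obj, path)
  meta <- list(format = "hdseizure-model", version = 1L,
               D = memories$D, L = memories$L, d = memories$vlm$d,
               N = memories$N, M = memories$M, seed = memories$seed,
               kind = model$kind, n_subclasses = as.list(n_subclasses(model)),
               n_training_windows = sum(model$count))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [write_hd_model()]
#' @param path Path given to [write_hd_model()].
#' @return List with elements `model` and `memories`.
#' @export
read_hd_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hdseizure-model"))
    stop("not an hdseizure model file: ", path, call. = FALSE)
  obj[c("model", "memories")]
}

#' Save a recording in the internal container format
#'
#' Compressed RDS array plus a JSON side-car with fs, channels, seizures
#' and the originating config echo.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param config Optional config object echoed into the metadata.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path, config = NULL) {
  saveRDS(rec, path, compress = "gzip")
  meta <- list(subject_id = rec$subject_id, fs = rec$fs,
               channels = rec$channels,
               n_samples = ncol(rec$signal),
               seizures = rec$seizures,
               config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Load a recording saved by [save_recording()]
#' @param path Path given to [save_recording()].
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path) readRDS(path)
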