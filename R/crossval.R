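#' Compute windowed features for one recording
#'
#' Segments the recording ([segment_and_label()]) and extracts the N x M
#' raw feature matrix of every window.
#'
#' @param rec An [eeg_recording()].
#' @param fcfg A [feature_config()].
#' @param wcfg A [windowing_config()].
#' @return List with `windows` (data.frame of start/label) and `features`
#'   (list of N x M matrices, one per window).
#' @export
compute_file_features <- function(rec, fcfg = feature_config(),
                                  wcfg = windowing_config()) {
  windows <- segment_and_label(rec, wcfg)
  feats <- lapply(windows$start, function(s)
    extract_window_features(window_samples(rec, s, wcfg$Wlen), fcfg))
  list(windows = windows, features = feats)
}

#' Write windowed features as CSV with a column manifest
#'
#' One row per window: `file_id`, `start`, `label`, then the N x M feature
#' values flattened channel-major (`ch01_<name>`, ...). A side-car
#' `<path>.manifest.txt` names every feature column.
#'
#' @param file_feats List of [compute_file_features()] results.
#' @param path Output CSV path.
#' @param channels Channel names used in the manifest.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(file_feats, path,
                              channels = chbmit_montage()) {
  rows <- list()
  for (f in seq_along(file_feats)) {
    ff <- file_feats[[f]]
    for (i in seq_along(ff$features)) {
      m <- ff$features[[i]]
      rows[[length(rows) + 1L]] <- c(file_id = f,
                                     start = ff$windows$start[i],
                                     label = ff$windows$label[i],
                                     as.vector(t(m)))
    }
  }
  m1 <- file_feats[[1L]]$features[[1L]]
  cols <- as.vector(t(outer(sprintf("ch%02d", seq_len(nrow(m1))),
                            colnames(m1), paste, sep = "_")))
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("file_id", "start", "label", cols)
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  writeLines(cols, paste0(path, ".manifest.txt"))
  invisible(path)
}

.score_row <- function(sc) {
  c(raw_ep_tpr = sc$raw$episode$TPR, raw_ep_ppv = sc$raw$episode$PPV,
    raw_ep_f1 = sc$raw$episode$F1, raw_du_tpr = sc$raw$duration$TPR,
    raw_du_ppv = sc$raw$duration$PPV, raw_du_f1 = sc$raw$duration$F1,
    raw_gmean = sc$raw$F1DEgmean,
    sm_ep_tpr = sc$smoothed$episode$TPR, sm_ep_ppv = sc$smoothed$episode$PPV,
    sm_ep_f1 = sc$smoothed$episode$F1, sm_du_tpr = sc$smoothed$duration$TPR,
    sm_du_ppv = sc$smoothed$duration$PPV, sm_du_f1 = sc$smoothed$duration$F1,
    sm_gmean = sc$smoothed$F1DEgmean)
}

#' Leave-one-seizure-out cross-validation over per-seizure files
#'
#' Each fold holds out one per-seizure file for testing and trains on all
#' others: feature normalization is fit on the training folds only, the
#' discretized windows are encoded against one fixed set of HD memories
#' per subject, and the requested models are trained single-pass in file
#' order. Per-fold scores (raw and smoothed) are averaged into the subject
#' performance.
#'
#' @param files List of per-seizure [eeg_recording()]s (from
#'   [build_balanced_files()]), at least 2.
#' @param fcfg,wcfg,pcfg Feature, windowing and post-processing configs.
#' @param D,L Hypervector dimension and discretization level count.
#' @param memories_seed Seed for the subject's HD memories.
#' @param models Subset of `c("2class", "multicentroid")`.
#' @param reduce Subset of `c("removal", "clustering")`: reduction variants
#'   of the multi-centroid model to evaluate as additional models
#'   (`"mc_removal"`, `"mc_clustering"`).
#' @param step_fraction,tolerance Passed to the reducers.
#' @param file_features Optional precomputed [compute_file_features()]
#'   list (one per file) to skip feature extraction.
#' @return List with `per_fold` (data.frame: fold, model, sub-class counts,
#'   14 metric columns) and `summary` (per-model means over folds).
#' @export
run_crossvalidation <- function(files, fcfg = feature_config(),
                                wcfg = windowing_config(),
                                pcfg = postprocess_config(),
                                D = 10000L, L = 20L, memories_seed = 1L,
                                models = c("2class", "multicentroid"),
                                reduce = character(0),
                                step_fraction = 0.10, tolerance = 0.03,
                                file_features = NULL) {
  if (length(files) < 2L)
    stop("leave-one-seizure-out needs at least 2 files", call. = FALSE)
  if (is.null(file_features))
    file_features <- lapply(files, compute_file_features, fcfg = fcfg,
                            wcfg = wcfg)
  N <- nrow(files[[1L]]$signal)
  mem <- hd_memories(N, fcfg$M, D = D, L = L, seed = memories_seed)

  rows <- list()
  for (fold in seq_along(files)) {
    train_idx <- setdiff(seq_along(files), fold)
    state <- fit_normalization(
      do.call(c, lapply(file_features[train_idx], `[[`, "features")), L = L)
    enc <- lapply(seq_along(files), function(f) {
      ff <- file_features[[f]]
      encode_dataset(lapply(ff$features, discretize, state = state), mem,
                     label = ff$windows$label, start = ff$windows$start,
                     file_id = rep(f, nrow(ff$windows)))
    })
    train_ds <- bind_datasets(enc[train_idx])
    test_ds <- enc[[fold]]

    fitted <- list()
    if ("2class" %in% models)
      fitted[["2class"]] <- train_2class(train_ds, mem)
    if ("multicentroid" %in% models || length(reduce)) {
      mc <- train_multicentroid(train_ds, mem)
      if ("multicentroid" %in% models) fitted[["multicentroid"]] <- mc
      if ("removal" %in% reduce)
        fitted[["mc_removal"]] <- reduce_by_removal(
          mc, train_ds, step_fraction, tolerance, pcfg)
      if ("clustering" %in% reduce)
        fitted[["mc_clustering"]] <- reduce_by_clustering(
          mc, train_ds, step_fraction, tolerance, pcfg)
    }
    for (mname in names(fitted)) {
      mm <- fitted[[mname]]
      sc <- evaluate_on(mm, test_ds, pcfg)
      ns <- n_subclasses(mm)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold, model = mname,
        n_subclasses_seiz = ns[["ictal"]],
        n_subclasses_nonseiz = ns[["interictal"]],
        t(.score_row(sc)))
    }
  }
  per_fold <- do.call(rbind, rows)
  num_cols <- setdiff(names(per_fold), c("fold", "model"))
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$model),
                                   function(d) colMeans(d[num_cols])))
  list(per_fold = per_fold,
       summary = data.frame(model = rownames(summary), summary,
                            row.names = NULL))
}

#' Run the full synthetic-cohort experiment
#'
#' For every subject of a [cohort_configs()] cohort and every balancing
#' factor: generate the recording, build per-seizure balanced files, and
#' run leave-one-seizure-out cross-validation with the requested models
#' (and reductions, applied at the factor given by `reduce_factor`).
#' Feature extraction for the F1 variant reuses nothing across factors;
#' each factor draws its own interictal sample.
#'
#' @param n_subjects,seed,subtype_range,... Cohort definition, see
#'   [cohort_configs()].
#' @param factors Balancing factors to evaluate (default c(1, 10)).
#' @param models,reduce As in [run_crossvalidation()].
#' @param reduce_factor Factor at which the reduction variants are run
#'   (default: the largest factor).
#' @param D,L,fcfg,wcfg,pcfg As in [run_crossvalidation()].
#' @param verbose Print one line per subject.
#' @return data.frame: one row per subject x factor x model with subject
#'   means over folds (sub-class counts and the 14 metric columns).
#' @export
run_cohort_experiment <- function(n_subjects = 20, seed = 1L,
                                  factors = c(1, 10),
                                  models = c("2class", "multicentroid"),
                                  reduce = character(0),
                                  reduce_factor = max(factors),
                                  subtype_range = c(2, 4),
                                  D = 10000L, L = 20L,
                                  fcfg = feature_config(),
                                  wcfg = windowing_config(),
                                  pcfg = postprocess_config(),
                                  verbose = FALSE, ...) {
  cfgs <- cohort_configs(n_subjects, seed, subtype_range, ...)
  rows <- list()
  for (i in seq_along(cfgs)) {
    rec <- generate_synthetic_recording(cfgs[[i]])
    for (f in factors) {
      files <- build_balanced_files(
        rec, balancing_config(factor = f, seed = cfgs[[i]]$seed + f))
      res <- run_crossvalidation(
        files, fcfg = fcfg, wcfg = wcfg, pcfg = pcfg, D = D, L = L,
        memories_seed = cfgs[[i]]$seed,
        models = models,
        reduce = if (f == reduce_factor) reduce else character(0))
      s <- res$summary
      rows[[length(rows) + 1L]] <-
        data.frame(subject = i, factor = f,
                   n_seizure_subtypes = cfgs[[i]]$n_seizure_subtypes, s)
      if (verbose)
        message(sprintf("subject %d factor %d: %s", i, f,
                        paste(sprintf("%s %.3f", s$model, s$sm_gmean),
                              collapse = ", ")))
    }
    rm(rec)
  }
  do.call(rbind, rows)
}
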