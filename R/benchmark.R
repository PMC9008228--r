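#' Study conditions of the packaged synthetic benchmark
#'
#' The fixed generator settings used by the package's benchmark experiments
#' (and by `scripts/acceptance.R`): a cohort of subjects with 2-3 seizure
#' sub-types (one more background sub-type than seizure sub-types), four
#' seizures of 12-20 s in a 30-min recording, moderate-amplitude seizures
#' over a noisy multi-state background, plus artifact and seizure-like
#' burst processes. Channel count and record length are scaled down from
#' the full 18-channel montage so a whole-cohort experiment runs on a
#' single CPU; the methods vignette discusses what this does and does not
#' change.
#'
#' @return Named list of [synth_config()] overrides.
#' @export
benchmark_cohort_args <- function() {
  list(n_channels = 4, duration = 1800, n_seizures = 4,
       seizure_duration = c(12, 20), epoch_duration = c(10, 25),
       background_amp = c(6, 12), background_noise = c(7, 12),
       seizure_amp = c(20, 45), seizure_noise = c(8, 16),
       artifact_rate = 4, artifact_amp = c(2, 4),
       artifact_duration = c(0.5, 3),
       burst_rate = 2, burst_amp = c(15, 35), burst_freq = c(2.5, 12),
       burst_duration = c(1, 6), n_burst_subtypes = 2)
}

#' Train a multi-centroid model on one synthetic subject and count the
#' seizure sub-classes it discovers
#'
#' Generates a subject whose recording holds exactly `k` seizure sub-types
#' (one seizure per sub-type), balances at 1x, trains the multi-centroid
#' model on all files and returns the number of seizure sub-classes
#' created. Used to probe sub-type recovery: with well-separated sub-type
#' signatures the trainer should open at least `k` seizure sub-classes.
#'
#' @param k Number of seizure sub-types generated.
#' @param seed Integer seed for the subject.
#' @return Integer: seizure sub-classes in the trained model.
#' @export
recover_seizure_subtypes <- function(k, seed) {
  base <- benchmark_cohort_args()
  cfg <- do.call(synth_config, utils::modifyList(base, list(
    n_channels = 3, duration = 400, n_seizures = k,
    seizure_duration = c(8, 12), n_seizure_subtypes = k,
    n_background_subtypes = k + 1L, clean_frac = 0.55, seed = seed)))
  rec <- generate_synthetic_recording(cfg)
  files <- build_balanced_files(
    rec, balancing_config(factor = 1, seed = cfg$seed + 1L))
  ffs <- lapply(files, compute_file_features)
  mem <- hd_memories(cfg$n_channels, feature_config()$M, seed = cfg$seed)
  state <- fit_normalization(do.call(c, lapply(ffs, `[[`, "features")))
  enc <- lapply(seq_along(files), function(f)
    encode_dataset(lapply(ffs[[f]]$features, discretize, state = state),
                   mem, ffs[[f]]$windows$label, ffs[[f]]$windows$start,
                   rep(f, nrow(ffs[[f]]$windows))))
  mc <- train_multicentroid(bind_datasets(enc), mem)
  unname(n_subclasses(mc)[["ictal"]])
}

#' Run the packaged cohort benchmark
#'
#' [run_cohort_experiment()] under the frozen [benchmark_cohort_args()]
#' conditions: 2-class and multi-centroid models on the F1 and F10
#' balancing variants, with both reduction procedures applied on F10.
#'
#' @param n_subjects Cohort size (default 20).
#' @param seed Cohort seed.
#' @param verbose Print per-subject progress.
#' @return Per-subject results data.frame, see [run_cohort_experiment()].
#' @export
run_cohort_benchmark <- function(n_subjects = 20, seed = 1L,
                                 verbose = FALSE) {
  args <- c(list(n_subjects = n_subjects, seed = seed,
                 factors = c(1, 10),
                 models = c("2class", "multicentroid"),
                 reduce = c("removal", "clustering"), reduce_factor = 10,
                 subtype_range = c(2, 3), verbose = verbose),
            benchmark_cohort_args())
  do.call(run_cohort_experiment, args)
}
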