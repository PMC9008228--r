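# The 20-subject synthetic cohort experiment is shared by several
# acceptance checks; run it once per test session and cache the result.
cohort_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_cohort_benchmark(n_subjects = 20, seed = 1)
    cache
  }
})

cohort_wide <- function(res, metric = "sm_gmean") {
  w <- reshape(res[, c("subject", "factor", "model", metric)],
               direction = "wide", idvar = c("subject", "factor"),
               timevar = "model")
  names(w) <- sub(paste0(metric, "."), "", names(w), fixed = TRUE)
  w
}
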