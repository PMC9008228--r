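test_that("majority-vote smoothing removes spikes and fills gaps", {
  cfg <- postprocess_config(SWlen = 5, Wstep = 1)
  expect_identical(smooth_labels(c(0, 0, 1, 0, 0), cfg), rep(0L, 5))
  expect_identical(smooth_labels(c(1, 1, 0, 1, 1), cfg), rep(1L, 5))
  expect_identical(smooth_labels(rep(1L, 7), cfg), rep(1L, 7))
  expect_identical(smooth_labels(rep(0L, 7), cfg), rep(0L, 7))
  # ties resolve to interictal (positions 2 and 4 tie; position 1 has a
  # truncated 3-sample window with a genuine majority of ones)
  expect_identical(smooth_labels(c(1, 1, 0, 0), postprocess_config(4, 1)),
                   c(1L, 0L, 0L, 0L))
  expect_error(smooth_labels(integer(0), cfg), "empty")
  expect_error(postprocess_config(SWlen = 0.5, Wstep = 1), "SWlen")
})

test_that("smoothing matches its oracle and is idempotent on smooth input", {
  cfg <- postprocess_config(5, 1)
  set.seed(7)
  for (i in 1:200) {
    x <- sample(0:1, sample(1:30, 1), replace = TRUE)
    expect_identical(smooth_labels(x, cfg), oracle_smooth(x, 5))
  }
  # sequences whose runs are all >= SWlen are fixed points
  for (i in 1:50) {
    runs <- sample(5:9, sample(2:5, 1), replace = TRUE)
    x <- unlist(mapply(rep, rep_len(0:1, length(runs)), runs))
    expect_identical(smooth_labels(x, cfg), as.integer(x))
  }
})

test_that("episode extraction returns maximal half-open runs", {
  expect_equal(nrow(extract_episodes(rep(0, 6))), 0)
  ep <- extract_episodes(c(0, 1, 1, 0, 1))
  expect_equal(nrow(ep), 2)
  expect_equal(ep[, "start"], c(2L, 5L))
  expect_equal(ep[, "end"], c(4L, 6L))
  # concatenation with a separating zero splits cleanly
  s1 <- c(1, 1, 0, 1); s2 <- c(1, 0, 1, 1)
  both <- extract_episodes(c(s1, 0, s2))
  e1 <- extract_episodes(s1); e2 <- extract_episodes(s2)
  shifted <- e2 + length(s1) + 1L
  expect_equal(unname(both), unname(rbind(e1, shifted)))
})

test_that("duration metrics count samples; zero denominators flag and zero", {
  truth <- c(rep(0, 5), rep(1, 10), rep(0, 5))
  pred <- c(rep(1, 5), rep(1, 5), rep(0, 10))
  m <- duration_metrics(pred, truth)
  expect_equal(m$TPR, 0.5)
  expect_equal(m$PPV, 0.5)
  expect_equal(m$F1, 0.5)
  p <- duration_metrics(truth, truth)
  expect_equal(c(p$TPR, p$PPV, p$F1), c(1, 1, 1))
  z <- duration_metrics(rep(0, 20), truth)
  expect_equal(c(z$TPR, z$PPV, z$F1), c(0, 0, 0))
  expect_true(z$flag)
  expect_error(duration_metrics(0:1, 0:2), "length")
})

test_that("episode metrics follow the any-overlap rule", {
  n <- 60
  truth <- integer(n); truth[11:20] <- 1L; truth[41:50] <- 1L
  pred <- integer(n); pred[13:18] <- 1L
  m <- episode_metrics(pred, truth)
  expect_equal(m$TPR, 0.5)
  expect_equal(m$PPV, 1)
  expect_equal(m$F1, 2 / 3)
  # perfect agreement
  p <- episode_metrics(truth, truth)
  expect_equal(c(p$TPR, p$PPV, p$F1), c(1, 1, 1))
  # one long prediction spanning both truth episodes: both detected, no FP
  long <- integer(n); long[5:55] <- 1L
  l <- episode_metrics(long, truth)
  expect_equal(c(l$TPR, l$PPV), c(1, 1))
  # several predictions on one truth episode count once
  multi <- integer(n); multi[11:12] <- 1L; multi[15:16] <- 1L
  mm <- episode_counts(multi, truth)
  expect_equal(mm$TP, 1)
  expect_equal(mm$FP, 0)
  expect_equal(mm$FN, 1)
})

test_that("episode and duration metrics match brute force on 1000 sequences", {
  set.seed(9)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    pred <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    truth <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    expect_identical(episode_counts(pred, truth),
                     oracle_episode_counts(pred, truth))
    expect_identical(duration_counts(pred, truth),
                     oracle_duration_counts(pred, truth))
  }
})

test_that("episode scoring ignores within-episode flips; duration does not", {
  truth <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  full <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  holey <- full; holey[14] <- 0   # still one overlapping episode? no: split
  # splitting the predicted episode keeps episode counts identical under
  # the any-overlap rule (both halves hit the same truth episode)
  expect_identical(episode_counts(holey, truth),
                   episode_counts(full, truth))
  expect_false(identical(duration_counts(holey, truth),
                         duration_counts(full, truth)))
})

test_that("partially covered equal-length episodes rank episode TPR first", {
  set.seed(10)
  for (i in 1:25) {
    len <- 10
    k <- sample(2:5, 1)
    truth <- integer(k * (len + 5) + 5)
    starts <- (seq_len(k) - 1) * (len + 5) + 3
    for (s in starts) truth[s:(s + len - 1)] <- 1L
    pred <- integer(length(truth))
    for (s in starts[sample(c(TRUE, FALSE), k, replace = TRUE)]) {
      cov <- sample(1:(len - 1), 1)          # strictly partial coverage
      pred[s:(s + cov - 1)] <- 1L
    }
    em <- episode_metrics(pred, truth)
    dm <- duration_metrics(pred, truth)
    expect_gte(em$TPR, dm$TPR)
  }
})

test_that("F1DEgmean is the geometric mean with exact anchors", {
  expect_equal(f1_de_gmean(1, 1), 1)
  expect_equal(f1_de_gmean(0, 0.73), 0)
  expect_equal(f1_de_gmean(0.64, 0.25), 0.4)
  expect_error(f1_de_gmean(1.2, 0.5))
})

test_that("per-file scoring smooths within files and pools counts", {
  truth <- c(rep(0, 8), rep(1, 6), rep(0, 8))
  pred_spike <- truth; pred_spike[3] <- 1L       # isolated FP, smoothed away
  two_files <- list(pred = c(pred_spike, pred_spike),
                    truth = c(truth, truth),
                    fid = rep(1:2, each = length(truth)),
                    start = c(seq_along(truth), seq_along(truth)))
  sc <- score_predictions(two_files$pred, two_files$truth, two_files$fid,
                          two_files$start)
  expect_equal(sc$raw$counts$duration$FP, 2)
  expect_equal(sc$smoothed$counts$duration$FP, 0)
  expect_equal(sc$smoothed$counts$episode$TP, 2)
  expect_equal(sc$smoothed$F1DEgmean, 1)
})

test_that("paired Wilcoxon matches the exact distribution and flags zeros", {
  a <- c(5.1, 4.2, 6.3, 5.9, 7.7, 5.5, 6.1, 4.9, 5.3, 6.8)
  b <- a - seq(0.1, 1.0, by = 0.1)   # all-positive distinct differences
  expect_equal(paired_wilcoxon(a, b), 2 / 1024)
  # shift invariance: only differences matter
  expect_equal(paired_wilcoxon(a + 100, b + 100), 2 / 1024)
  z <- paired_wilcoxon(a, a)
  expect_equal(as.numeric(z), 1)
  expect_true(attr(z, "degenerate"))
  expect_error(paired_wilcoxon(a[1:4], b[1:4]), "at least 5")
  expect_error(paired_wilcoxon(a, b[1:5]), "paired")
})
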