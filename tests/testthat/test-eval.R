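test_that("fold plans hold each subject out exactly once with no leakage", {
  cohort <- simulate_cohort(6, n_per_class = c(PT = 3, NT = 3), seed = 13,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  folds <- make_folds(w)
  expect_equal(nrow(folds), 6)
  expect_setequal(folds$test_subject, unique(w$subject_id))
  for (k in seq_len(nrow(folds))) {
    tr_s <- unique(w$subject_id[folds$train_idx[[k]]])
    te_s <- unique(w$subject_id[folds$test_idx[[k]]])
    expect_length(intersect(tr_s, te_s), 0)
    expect_setequal(c(folds$train_idx[[k]], folds$test_idx[[k]]), seq_len(nrow(w)))
  }
  one <- w[w$subject_id == w$subject_id[1], ]
  expect_error(make_folds(one), "two subjects")
})

test_that("voting takes the majority and breaks ties by mean probability", {
  expect_identical(vote_windows(c("PT", "PT", "NT")), "PT")
  expect_identical(vote_windows("PT"), "PT")
  probs <- rbind(c(PT = 0.9, NT = 0.1), c(PT = 0.7, NT = 0.3))
  expect_identical(vote_windows(c("PT", "NT"), probs), "PT")
  probs2 <- rbind(c(PT = 0.2, NT = 0.8), c(PT = 0.6, NT = 0.4))
  expect_identical(vote_windows(c("PT", "NT"), probs2), "NT")
  expect_error(vote_windows(character(0)), "no window")
})

test_that("voting equals brute-force majority counting whenever no tie exists", {
  set.seed(31)
  classes <- c("PT", "ET", "NT")
  for (k in 1:200) {
    labs <- sample(classes, sample(1:9, 1), replace = TRUE)
    counts <- table(labs)
    if (sum(counts == max(counts)) > 1) next
    expect_identical(vote_windows(labs), names(which.max(counts)))
  }
})

test_that("binary metrics match the hand-derived confusion arithmetic", {
  # TP = 3, FP = 1, FN = 1, TN = 5
  truth <- factor(c(rep("PT", 4), rep("non-PT", 6)), levels = c("PT", "non-PT"))
  pred <- factor(c("PT", "PT", "PT", "non-PT", "PT", rep("non-PT", 5)),
                 levels = c("PT", "non-PT"))
  m <- compute_metrics(pred, truth)
  expect_equal(m$accuracy, 80)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 83.3, tolerance = 1e-3)
  expect_equal(m$f1, 75)
  expect_equal(sum(m$confusion), 10)
})

test_that("perfect predictions score 100 on every metric", {
  truth <- factor(sample(c("PT", "ET", "NT"), 30, TRUE))
  m <- compute_metrics(truth, truth)
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$f1, 100)
})

test_that("macro metrics equal the mean of independently computed per-class scores", {
  set.seed(17)
  classes <- c("A", "B", "C")
  truth <- factor(sample(classes, 60, TRUE), levels = classes)
  pred <- factor(sample(classes, 60, TRUE), levels = classes)
  m <- compute_metrics(pred, truth)
  per <- vapply(classes, function(cl) {
    o <- oracle_metrics(pred, truth, cl)
    c(o$sensitivity, o$specificity, o$f1)
  }, numeric(3))
  expect_equal(m$sensitivity, mean(per[1, ]), tolerance = 1e-10)
  expect_equal(m$specificity, mean(per[2, ]), tolerance = 1e-10)
  expect_equal(m$f1, mean(per[3, ]), tolerance = 1e-10)
  expect_error(compute_metrics(factor(c("A", "Z")), factor(c("A", "B"))),
               "outside")
})

test_that("the frequency estimator recovers single tones within 0.3 Hz", {
  fps <- 30
  t <- (0:(10 * fps - 1)) / fps
  set.seed(8)
  for (f in 3:7) {
    x <- 5 * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + rnorm(length(t), 0, 1)
    y <- rnorm(length(t), 0, 1)
    est <- estimate_tremor_frequency(data.frame(x = x, y = y), fps)
    expect_lt(abs(est - f), 0.3)
  }
})

test_that("frequency estimation flags constant trajectories and picks the dominant tone", {
  fps <- 30
  t <- (0:299) / fps
  expect_true(is.na(estimate_tremor_frequency(
    data.frame(x = rep(1, 300), y = rep(2, 300)), fps)))
  two <- data.frame(x = 5 * sin(2 * pi * 5 * t) + 1 * sin(2 * pi * 1.5 * t), y = 0)
  expect_lt(abs(estimate_tremor_frequency(two, fps) - 5), 0.2)
  expect_error(estimate_tremor_frequency(data.frame(x = 1:10, y = 1:10), 30),
               "2 seconds")
})

test_that("a two-subject leave-one-out smoke run is complete and reproducible", {
  cohort <- simulate_cohort(2, n_per_class = c(PT = 1, NT = 1), seed = 23,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  cfg <- model_config(channels = c(4, 8), epochs = 1, batch_size = 2, seed = 1)
  r1 <- run_loocv(w, cfg, attention = TRUE)
  expect_equal(nrow(r1$fold_metrics), 2)
  expect_equal(nrow(r1$video_predictions), 2)
  expect_s3_class(r1$metrics, "tremor_metrics")
  expect_true(all(c("joint", "attention") %in% names(r1$attention)))
  r2 <- run_loocv(w, cfg, attention = TRUE)
  expect_identical(glance(r1), glance(r2))
  # tidiers expose the expected shapes
  expect_equal(nrow(tidy(r1)), 2)
  expect_named(glance(r1)[, 4:7], c("accuracy", "sensitivity", "specificity", "f1"))
})
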