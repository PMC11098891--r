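# Subject-wise leave-one-out evaluation with subclip voting. Each fold holds
# out every window of one subject, so no individual's data ever appears on
# both sides of a split; window predictions are aggregated to video level by
# majority vote.

#' Subject-wise leave-one-out fold plan
#'
#' One fold per distinct subject: that subject's windows form the test set,
#' all other subjects' windows the training set.
#'
#' @param windows A window tibble with a `subject_id` column.
#' @return A tibble with `fold`, `test_subject` and list-columns `train_idx`,
#'   `test_idx` of row indices into `windows`.
#' @export
make_folds <- function(windows) {
  stopifnot("subject_id" %in% names(windows))
  subjects <- sort(unique(windows$subject_id))
  if (length(subjects) < 2) {
    stop("leave-one-subject-out requires at least two subjects", call. = FALSE)
  }
  tibble::tibble(
    fold = seq_along(subjects),
    test_subject = subjects,
    train_idx = lapply(subjects, function(s) which(windows$subject_id != s)),
    test_idx = lapply(subjects, function(s) which(windows$subject_id == s))
  )
}

#' Vote window predictions up to a video label
#'
#' Majority vote over the video's window-level predicted classes; ties are
#' broken by the highest mean class probability across the video's windows.
#'
#' @param labels Character or factor vector of window-level predicted classes.
#' @param probs Optional matrix (windows x classes, named columns) of class
#'   probabilities, used only to break ties.
#' @return The winning class (character scalar).
#' @export
#' @examples
#' vote_windows(c("PT", "PT", "NT"))
vote_windows <- function(labels, probs = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("no window predictions to vote on", call. = FALSE)
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (!is.null(probs)) {
    mp <- colMeans(probs[, top, drop = FALSE])
    return(top[which.max(mp)])
  }
  sort(top)[1]
}

#' Classification metrics with sensitivity/specificity
#'
#' Binary tasks report accuracy, sensitivity, specificity and F1 of the
#' positive class; multiclass tasks compute each one-vs-rest and report the
#' macro average. All rates are percentages.
#'
#' @param pred,truth Aligned factors (or vectors coercible to factors over the
#'   same class set).
#' @param positive Positive class for binary tasks (default the first level).
#' @return An object of class `tremor_metrics`: a list with `accuracy`,
#'   `sensitivity`, `specificity`, `f1` (percentages), a `per_class` tibble
#'   and the `confusion` matrix (truth in rows, prediction in columns).
#' @export
#' @examples
#' compute_metrics(factor(c("PT", "PT", "non-PT")),
#'                 factor(c("PT", "non-PT", "non-PT")))
compute_metrics <- function(pred, truth, positive = NULL) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  lev <- if (is.factor(truth)) levels(truth) else sort(unique(c(as.character(truth))))
  if (any(!as.character(pred) %in% lev)) {
    stop("`pred` contains labels outside the class set of `truth`", call. = FALSE)
  }
  pred <- factor(as.character(pred), levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  cm <- table(truth = truth, pred = pred)
  acc <- 100 * sum(diag(cm)) / sum(cm)

  per <- lapply(lev, function(cl) {
    tp <- sum(cm[cl, cl])
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- sum(cm) - tp - fn - fp
    se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else NA_real_
    tibble::tibble(class = cl, sensitivity = se, specificity = sp, f1 = f1,
                   support = tp + fn)
  })
  per <- dplyr::bind_rows(per)

  if (length(lev) == 2) {
    if (is.null(positive)) positive <- lev[1]
    row <- per[per$class == positive, ]
    out <- list(accuracy = acc, sensitivity = row$sensitivity,
                specificity = row$specificity, f1 = row$f1)
  } else {
    out <- list(accuracy = acc,
                sensitivity = mean(per$sensitivity, na.rm = TRUE),
                specificity = mean(per$specificity, na.rm = TRUE),
                f1 = mean(per$f1, na.rm = TRUE))
  }
  structure(c(out, list(per_class = per, confusion = cm)),
            class = "tremor_metrics")
}

#' @export
print.tremor_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  F1 %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Run a subject-wise leave-one-out experiment
#'
#' Trains one model per fold (all subjects but one), predicts the held-out
#' subject's windows, votes them up to video level, and aggregates metrics
#' over all folds. For attention-bearing variants the held-out subject's
#' attention maps are collected from the fold's model, giving cross-validated
#' interpretability output.
#'
#' @param windows A window tibble from [window_dataset()].
#' @param config A [model_config()]; `config$seed` also seeds each fold
#'   (fold-specific seeds are derived deterministically).
#' @param variant Architecture variant, see [tremor_gnn()].
#' @param graph The skeleton graph.
#' @param attention Collect held-out attention maps (ignored for the
#'   `no_attention` variant).
#' @param verbose Print per-fold progress.
#' @return An object of class `tremor_loocv`: a list with `video_predictions`
#'   (one row per video), `fold_metrics`, pooled `metrics`
#'   ([compute_metrics()] over all videos), `attention` (per window x joint),
#'   `config` and `variant`.
#' @export
run_loocv <- function(windows, config = model_config(), variant = "full",
                      graph = skeleton_graph(), attention = TRUE,
                      verbose = FALSE) {
  folds <- make_folds(windows)
  classes <- levels(windows$label)
  attention <- attention && variant != "no_attention"

  vids <- list()
  atts <- list()
  fold_rows <- list()
  for (k in seq_len(nrow(folds))) {
    tr <- windows[folds$train_idx[[k]], ]
    te <- windows[folds$test_idx[[k]], ]
    if (nrow(te) == 0 || nrow(tr) == 0) {
      warning("fold ", k, " skipped: no windows on one side of the split")
      next
    }
    cfg <- config
    cfg$seed <- (config$seed + 101L * k) %% .Machine$integer.max
    fit <- tremor_gnn(tr, cfg, variant = variant, graph = graph)
    pr <- predict(fit, te)
    pcols <- paste0(".prob_", classes)
    voted <- pr |>
      dplyr::group_by(.data$video_id) |>
      dplyr::group_modify(function(d, g) {
        probs <- as.matrix(d[, pcols])
        colnames(probs) <- classes
        tibble::tibble(
          truth = d$label[1],
          pred = vote_windows(d$.pred, probs),
          n_windows = nrow(d)
        )
      }) |>
      dplyr::ungroup()
    voted$subject_id <- folds$test_subject[k]
    voted$fold <- k
    vids[[k]] <- voted
    fold_rows[[k]] <- tibble::tibble(
      fold = k, test_subject = folds$test_subject[k],
      n_videos = nrow(voted),
      accuracy = 100 * mean(voted$pred == as.character(voted$truth))
    )
    if (attention) {
      att <- extract_attention(fit, te)
      att$fold <- k
      atts[[k]] <- att
    }
    if (verbose) {
      message(sprintf("fold %d/%d (%s): %d/%d videos correct", k, nrow(folds),
                      folds$test_subject[k],
                      sum(voted$pred == as.character(voted$truth)), nrow(voted)))
    }
  }
  video_predictions <- dplyr::bind_rows(vids)
  video_predictions$pred <- factor(video_predictions$pred, levels = classes)
  metrics <- compute_metrics(video_predictions$pred, video_predictions$truth)
  structure(list(
    video_predictions = video_predictions,
    fold_metrics = dplyr::bind_rows(fold_rows),
    metrics = metrics,
    attention = if (attention) dplyr::bind_rows(atts) else NULL,
    config = config, variant = variant, classes = classes
  ), class = "tremor_loocv")
}

#' @export
print.tremor_loocv <- function(x, ...) {
  cat("<tremor_loocv> ", x$variant, " variant, ", nrow(x$fold_metrics),
      " folds, ", nrow(x$video_predictions), " videos\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Estimate the dominant tremor frequency of a trajectory
#'
#' Spectral peak of a 2D joint trajectory: both axes are linearly detrended,
#' Hann-windowed and Fourier transformed; the per-axis power spectra are
#' summed and the dominant peak within `band` is refined by quadratic
#' interpolation. Used to verify that extracted (or synthesized) wrist motion
#' carries the expected tremor frequency.
#'
#' @param traj A tibble/data.frame with `x` and `y` columns (pixels), or a
#'   two-column matrix, sampled at `fps` Hz.
#' @param fps Sampling rate in Hz.
#' @param band Frequency search band in Hz; the upper edge is capped below
#'   the Nyquist frequency.
#' @param min_sd Displacement threshold (pixels): below it the trajectory is
#'   considered tremor-free and `NA` is returned.
#' @return Dominant frequency in Hz, or `NA_real_` for a tremor-free
#'   trajectory.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 30)
#' estimate_tremor_frequency(data.frame(x = sin(2 * pi * 5 * t), y = 0), 30)
estimate_tremor_frequency <- function(traj, fps, band = c(1, Inf),
                                      min_sd = 1e-6) {
  M <- as.matrix(as.data.frame(traj)[, c("x", "y")])
  n <- nrow(M)
  if (n < 2 * fps) {
    stop("need at least 2 seconds of samples to estimate tremor frequency",
         call. = FALSE)
  }
  t <- seq_len(n)
  D <- apply(M, 2, function(col) stats::residuals(stats::lm(col ~ t)))
  if (max(apply(D, 2, stats::sd)) < min_sd) return(NA_real_)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # Hann
  nfft <- 2^ceiling(log2(n * 8)) # zero-pad for a fine frequency grid
  S <- 0
  for (k in 1:2) {
    xw <- c(D[, k] * w, numeric(nfft - n))
    S <- S + Mod(stats::fft(xw))^2
  }
  freq <- (seq_len(nfft) - 1) * fps / nfft
  lo <- max(band[1], fps / n) # exclude sub-resolution bins
  hi <- min(band[2], fps / 2 * 0.999)
  cand <- which(freq >= lo & freq <= hi)
  i <- cand[which.max(S[cand])]
  # quadratic interpolation around the peak
  if (i > 1 && i < nfft / 2) {
    y1 <- S[i - 1]; y2 <- S[i]; y3 <- S[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    return((i - 1 + delta) * fps / nfft)
  }
  freq[i]
}

#' Wrist trajectory of a pose sequence
#'
#' Convenience accessor: the (x, y) trajectory of one joint from a pose
#' tibble, ordered by frame.
#'
#' @param pose A pose tibble.
#' @param joint Joint name (default `"left_wrist"`).
#' @return A tibble with `frame`, `x`, `y`.
#' @export
joint_trajectory <- function(pose, joint = "left_wrist") {
  .pose_check(pose)
  out <- pose[pose$joint == joint, c("frame", "x", "y")]
  if (nrow(out) == 0) stop("joint not found: ", joint, call. = FALSE)
  dplyr::arrange(tibble::as_tibble(out), .data$frame)
}
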