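# Synthetic tremor cohorts: seated upper-body pose sequences with band-limited
# (3-7 Hz) oscillatory wrist/arm motion, class-dependent laterality,
# severity-dependent amplitude, keypoint jitter and occlusion gaps. These are
# statistical fixtures with the structure the method assumes, not
# biomechanically realistic human motion.

.template_pose <- function() {
  tibble::tribble(
    ~joint, ~x, ~y,
    "nose", 320, 120,
    "left_eye", 310, 112,
    "right_eye", 330, 112,
    "left_ear", 295, 118,
    "right_ear", 345, 118,
    "left_shoulder", 245, 180,
    "right_shoulder", 395, 180,
    "left_elbow", 230, 250,
    "right_elbow", 410, 250,
    "left_wrist", 225, 320,
    "right_wrist", 415, 320,
    "left_hip", 270, 330,
    "right_hip", 370, 330,
    "left_knee", 265, 420,
    "right_knee", 375, 420,
    "left_ankle", 260, 472,
    "right_ankle", 375, 472
  )
}

# severity rating (Bain-Findley 0-7) -> tremor amplitude in pixels
.amplitude_for_rating <- function(rating) {
  stopifnot(all(rating >= 0), all(rating <= 7))
  amp <- c(0, 2, 5, 10, 16, 16, 16, 16)
  amp[pmin(rating, 7) + 1]
}

.tremor_arms <- function(class, rng_side) {
  switch(class,
    PT = rng_side, # unilateral
    DT = rng_side,
    FT = rng_side,
    ET = c("left", "right"), # bilateral
    NT = character(0),
    stop("unknown tremor class: ", class, call. = FALSE)
  )
}

#' Simulate one subject's pose sequence
#'
#' Generates a seated-subject COCO-17 keypoint sequence at `fps` Hz. The
#' affected wrist(s) oscillate as `A * sin(2*pi*f*t + phi)` with `f` drawn
#' from `freq_range` (class-dependent, see Details), the elbow co-displaced at
#' 40% amplitude; all joints carry Gaussian estimator jitter, confidences sit
#' near 1 and dip below the visibility threshold during occlusion gaps, and a
#' slow (0.25 Hz) out-of-band postural sway moves the whole body. Per-subject
#' nuisance variation (limb lengths +/-10%, global position offset) keeps
#' leave-one-subject-out folds from being trivially memorizable.
#'
#' @details Class signatures: `PT` -- unilateral oscillation at a frequency
#'   drawn from `freq_range` (default 3-7 Hz); `ET` -- bilateral oscillation
#'   (independent phases per arm); `DT` -- slower (2-4 Hz) unilateral
#'   oscillation with phase jitter and postural drift; `FT` -- intermittent
#'   on/off bursts of in-band oscillation; `NT` -- no tremor. Non-PT
#'   signatures are fixtures that make multiclass code paths testable, not
#'   clinical kinematics.
#'
#' @param class Tremor class, one of `"PT"`, `"ET"`, `"DT"`, `"FT"`, `"NT"`.
#' @param severity Bain-Findley rating 0-7 of the affected hand(s); mapped to
#'   amplitude in pixels as 1 -> 2, 2 -> 5, 3 -> 10, >= 4 -> 16.
#' @param subject_id,video_id Identifiers carried through the pipeline.
#' @param fps Frame rate in Hz (default 30, satisfying the Nyquist requirement
#'   for the 3-7 Hz band).
#' @param duration Clip length in seconds.
#' @param freq_range Tremor frequency range in Hz for PT/ET/FT.
#' @param jitter_sd Keypoint estimator noise (pixels, per joint per frame).
#' @param occlusion_rate Per-frame probability that an occlusion gap starts.
#' @param sway_px Amplitude of the slow global postural sway (pixels).
#' @param side For unilateral classes, which arm is affected (`"left"` or
#'   `"right"`); drawn at random when `NULL`.
#' @param seed Integer seed; the sequence is reproducible from it.
#' @return A one-row tibble with subject metadata, per-hand ratings, the drawn
#'   tremor frequency, and a `pose` list-column holding a tibble with columns
#'   `frame`, `joint`, `x`, `y`, `c` (confidence).
#' @export
#' @examples
#' subj <- simulate_subject("PT", severity = 2, seed = 42)
#' subj$tremor_freq
simulate_subject <- function(class = c("PT", "ET", "DT", "FT", "NT"),
                             severity = 2L,
                             subject_id = "S01", video_id = paste0(subject_id, "_V1"),
                             fps = 30, duration = 7,
                             freq_range = c(3, 7),
                             jitter_sd = 1, occlusion_rate = 0.002,
                             sway_px = 1, side = NULL, seed = 1L) {
  class <- match.arg(class)
  stopifnot(fps > 0, duration > 0, severity %in% 0:7)
  if (fps < 2 * freq_range[2]) {
    stop("fps = ", fps, " violates the Nyquist requirement for tremor up to ",
         freq_range[2], " Hz", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  n_frames <- round(fps * duration)
  t <- (seq_len(n_frames) - 1) / fps
  template <- .template_pose()

  # subject nuisance: limb scale and global offset
  scale <- runif(1, 0.9, 1.1)
  offset <- runif(2, -30, 30)
  center <- c(320, 250)
  base <- template
  base$x <- center[1] + (base$x - center[1]) * scale + offset[1]
  base$y <- center[2] + (base$y - center[2]) * scale + offset[2]

  if (is.null(side)) side <- sample(c("left", "right"), 1)
  side <- match.arg(side, c("left", "right"))
  arms <- .tremor_arms(class, side)
  freq <- switch(class,
    DT = runif(1, 2, 4),
    NT = NA_real_,
    runif(1, freq_range[1], freq_range[2])
  )

  J <- nrow(base)
  X <- matrix(rep(base$x, each = n_frames), n_frames, J)
  Y <- matrix(rep(base$y, each = n_frames), n_frames, J)
  colnames(X) <- colnames(Y) <- base$joint

  # slow coherent postural sway (out of the tremor band)
  if (sway_px > 0) {
    sway_phase <- runif(2, 0, 2 * pi)
    X <- X + sway_px * sin(2 * pi * 0.25 * t + sway_phase[1])
    Y <- Y + 0.5 * sway_px * sin(2 * pi * 0.2 * t + sway_phase[2])
  }

  amp <- .amplitude_for_rating(severity)
  for (arm in arms) {
    phi <- runif(1, 0, 2 * pi)
    theta <- runif(1, -pi / 9, pi / 9) # oscillation direction, near-horizontal
    phase <- 2 * pi * freq * t + phi
    if (class == "DT") {
      # irregular: jittered phase plus a slow postural drift
      phase <- phase + cumsum(rnorm(n_frames, 0, 0.15))
      drift <- seq(0, runif(1, -5, 5), length.out = n_frames)
    } else {
      drift <- 0
    }
    env <- 1
    if (class == "FT") {
      # intermittent bursts: smoothed on/off envelope, ~50% duty cycle
      burst <- rep(rbinom(ceiling(n_frames / round(fps)), 1, 0.5),
                   each = round(fps))[seq_len(n_frames)]
      env <- stats::filter(burst, rep(1 / 5, 5), sides = 2)
      env[is.na(env)] <- burst[is.na(env)]
    }
    osc <- amp * env * sin(phase)
    wrist <- paste0(arm, "_wrist")
    elbow <- paste0(arm, "_elbow")
    X[, wrist] <- X[, wrist] + osc * cos(theta) + drift
    Y[, wrist] <- Y[, wrist] + osc * sin(theta)
    X[, elbow] <- X[, elbow] + 0.4 * osc * cos(theta) + 0.4 * drift
    Y[, elbow] <- Y[, elbow] + 0.4 * osc * sin(theta)
  }

  if (jitter_sd > 0) {
    X <- X + matrix(rnorm(n_frames * J, 0, jitter_sd), n_frames, J)
    Y <- Y + matrix(rnorm(n_frames * J, 0, jitter_sd), n_frames, J)
  }

  # confidences near 1, collapsing during occlusion gaps
  conf <- matrix(pmin(1, pmax(0, 1 - abs(rnorm(n_frames * J, 0, 0.02)))),
                 n_frames, J)
  occluded <- rep(FALSE, n_frames)
  f <- 1
  while (f <= n_frames) {
    if (runif(1) < occlusion_rate) {
      gap <- 3 + stats::rgeom(1, 0.3)
      occluded[f:min(n_frames, f + gap - 1)] <- TRUE
      f <- f + gap
    } else {
      f <- f + 1
    }
  }
  if (any(occluded)) {
    conf[occluded, ] <- runif(sum(occluded) * J, 0, 0.04)
  }

  pose <- tibble::tibble(
    frame = rep(seq_len(n_frames), times = J),
    joint = rep(base$joint, each = n_frames),
    x = as.vector(X),
    y = as.vector(Y),
    c = as.vector(conf)
  )
  pose <- dplyr::arrange(pose, .data$frame, match(.data$joint, coco17_joints()))

  left_rating <- if ("left" %in% arms) severity else 0L
  right_rating <- if ("right" %in% arms) severity else 0L
  tibble::tibble(
    subject_id = subject_id, video_id = video_id, class = class,
    severity = as.integer(severity),
    affected_side = if (length(arms) == 2) "both" else if (length(arms) == 1) arms else "none",
    left_rating = as.integer(left_rating), right_rating = as.integer(right_rating),
    tremor_freq = freq, fps = fps, n_frames = n_frames,
    pose = list(pose)
  )
}

# save/restore RNG state so generators do not disturb the caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a tremor cohort
#'
#' Draws `n_subjects` subjects with class labels from `class_mix` (or exact
#' per-class counts via `n_per_class`), severities from `severity_probs`, and
#' generates each subject's videos with [simulate_subject()]. The whole cohort
#' is reproducible from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param class_mix Named probability vector over classes, e.g.
#'   `c(PT = 0.5, NT = 0.5)`; ignored when `n_per_class` is given.
#' @param n_per_class Named integer vector of exact per-class subject counts
#'   (must sum to `n_subjects`); classes are interleaved deterministically.
#' @param severity_probs Named probability vector over ratings for tremulous
#'   subjects (default uniform over 1-3).
#' @param videos_per_subject Videos generated per subject.
#' @param seed Integer seed for the whole cohort.
#' @param ... Passed to [simulate_subject()] (`fps`, `duration`, `jitter_sd`,
#'   `occlusion_rate`, `sway_px`, `freq_range`).
#' @return A tibble with one row per video (see [simulate_subject()]).
#' @export
#' @examples
#' cohort <- simulate_cohort(4, n_per_class = c(PT = 2, NT = 2), seed = 7)
#' cohort[, c("subject_id", "class", "severity", "affected_side")]
simulate_cohort <- function(n_subjects,
                            class_mix = c(PT = 0.5, NT = 0.5),
                            n_per_class = NULL,
                            severity_probs = c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3),
                            videos_per_subject = 1,
                            seed = 1L, ...) {
  stopifnot(n_subjects >= 2)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  if (is.null(n_per_class)) {
    if (abs(sum(class_mix) - 1) > 1e-8) stop("`class_mix` must sum to 1", call. = FALSE)
    classes <- sample(names(class_mix), n_subjects, replace = TRUE, prob = class_mix)
  } else {
    if (any(n_per_class < 0) || sum(n_per_class) != n_subjects) {
      stop("`n_per_class` must be non-negative and sum to `n_subjects`", call. = FALSE)
    }
    if (any(n_per_class[setdiff(names(n_per_class), c("PT", "ET", "DT", "FT", "NT"))] > 0)) {
      stop("`n_per_class` contains an unknown class", call. = FALSE)
    }
    classes <- sample(rep(names(n_per_class), times = n_per_class))
  }
  severities <- ifelse(
    classes == "NT", 0L,
    as.integer(sample(names(severity_probs), n_subjects, replace = TRUE,
                      prob = severity_probs))
  )
  sides <- sample(c("left", "right"), n_subjects, replace = TRUE)
  subj_seeds <- sample.int(.Machine$integer.max - 1, n_subjects * videos_per_subject)

  rows <- vector("list", n_subjects * videos_per_subject)
  k <- 0
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    for (v in seq_len(videos_per_subject)) {
      k <- k + 1
      rows[[k]] <- simulate_subject(
        class = classes[s], severity = severities[s],
        subject_id = sid, video_id = sprintf("%s_V%d", sid, v),
        side = sides[s], seed = subj_seeds[k], ...
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate an oscillating-dot test video
#'
#' A Gaussian bright blob on a dark background oscillating horizontally --
#' the standard fixture for checking motion magnification: the ground-truth
#' trajectory is returned alongside the frames.
#'
#' @param freq Oscillation frequency (Hz).
#' @param amp Oscillation amplitude (pixels).
#' @param fps Frame rate (Hz); must be at least `2 * freq`.
#' @param duration Clip length (seconds).
#' @param size Frame side length (pixels).
#' @param sigma Blob standard deviation (pixels). For motion-magnification
#'   experiments the blob must stay in the linear regime: `sigma` should be
#'   at least about twice the *magnified* displacement `(1 + alpha) * amp`,
#'   otherwise the first-order approximation behind Eulerian magnification
#'   breaks down and the measured amplification falls short.
#' @return A list with `video` (a [video_clip()]) and `trajectory`, a tibble
#'   of the analytic blob center per frame.
#' @export
#' @examples
#' dot <- simulate_dot_video(freq = 5, amp = 1, duration = 1)
#' dim(dot$video$frames)
simulate_dot_video <- function(freq = 5, amp = 1, fps = 30, duration = 3,
                               size = 160, sigma = 24) {
  if (fps < 2 * freq) {
    stop("fps = ", fps, " violates the Nyquist requirement for a ", freq,
         " Hz oscillation", call. = FALSE)
  }
  if (amp >= size / 4) stop("`amp` must be below size/4", call. = FALSE)
  n_frames <- round(fps * duration)
  t <- (seq_len(n_frames) - 1) / fps
  cx <- size / 2 + amp * sin(2 * pi * freq * t)
  cy <- rep(size / 2, n_frames)
  xs <- seq_len(size)
  frames <- array(0, c(size, size, n_frames))
  for (f in seq_len(n_frames)) {
    gx <- exp(-((xs - cx[f])^2) / (2 * sigma^2))
    gy <- exp(-((xs - cy[f])^2) / (2 * sigma^2))
    frames[, , f] <- 0.05 + 0.9 * outer(gy, gx)
  }
  list(
    video = video_clip(frames, fps),
    trajectory = tibble::tibble(frame = seq_len(n_frames), t = t, x = cx, y = cy)
  )
}
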