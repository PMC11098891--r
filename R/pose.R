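# Pose-stream ingestion and preprocessing. A pose sequence is a tidy tibble
# with one row per (frame, joint): columns `frame`, `joint`, `x`, `y`, `c`
# (confidence in [0, 1]) and optionally `visible` (per-frame flag).

.pose_check <- function(pose) {
  need <- c("frame", "joint", "x", "y", "c")
  miss <- setdiff(need, names(pose))
  if (length(miss)) {
    stop("pose tibble is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(pose)
}

#' Parse a pose-estimator JSON stream
#'
#' Reads per-frame COCO-17 keypoint records as produced by 2D pose estimators
#' (and by [write_pose_json()]). The schema is a JSON object with optional
#' `fps` and a `frames` array; each frame holds `frame` (index) and `people`,
#' a list of detections with a `score` and 51 `keypoints` floats
#' (x, y, confidence per joint). When several people are detected the
#' highest-score detection is kept; frames with no detection are marked not
#' visible (confidence 0, coordinates `NA`).
#'
#' @param file Path to the JSON file.
#' @return A pose tibble with a `visible` column and an `fps` attribute (if
#'   present in the file).
#' @export
parse_pose_json <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = FALSE)
  frames <- if (!is.null(doc$frames)) doc$frames else doc
  if (length(frames) == 0) stop("pose stream contains zero frames", call. = FALSE)
  joints <- coco17_joints()
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    idx <- if (!is.null(fr$frame)) fr$frame else k
    people <- fr$people
    if (is.null(people) || length(people) == 0) {
      rows[[k]] <- tibble::tibble(
        frame = as.integer(idx), joint = joints,
        x = NA_real_, y = NA_real_, c = 0, visible = FALSE
      )
      next
    }
    scores <- vapply(people, function(p) {
      if (is.null(p$score)) NA_real_ else as.numeric(p$score)
    }, numeric(1))
    best <- people[[which.max(ifelse(is.na(scores), -Inf, scores))]]
    kp <- unlist(best$keypoints)
    if (length(kp) != 3 * length(joints) || anyNA(suppressWarnings(as.numeric(kp)))) {
      stop("malformed keypoint record at frame ", idx,
           ": expected ", 3 * length(joints), " numeric values", call. = FALSE)
    }
    kp <- matrix(as.numeric(kp), ncol = 3, byrow = TRUE)
    rows[[k]] <- tibble::tibble(
      frame = as.integer(idx), joint = joints,
      x = kp[, 1], y = kp[, 2], c = pmin(1, pmax(0, kp[, 3])), visible = TRUE
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$frame)
  if (!is.null(doc$fps)) attr(out, "fps") <- as.numeric(doc$fps)
  out
}

#' Write a pose sequence to the pose-JSON schema
#'
#' Inverse of [parse_pose_json()] for single-person COCO-17 sequences; used to
#' serialize synthetic cohorts in the same format real pose estimators emit.
#'
#' @param pose A COCO-17 pose tibble.
#' @param file Output path.
#' @param fps Frame rate stored in the file.
#' @return Invisibly, `file`.
#' @export
write_pose_json <- function(pose, file, fps = attr(pose, "fps")) {
  .pose_check(pose)
  joints <- coco17_joints()
  frames <- lapply(split(pose, pose$frame), function(fr) {
    fr <- fr[match(joints, fr$joint), ]
    list(
      frame = fr$frame[1],
      people = list(list(
        score = mean(fr$c),
        keypoints = as.vector(t(as.matrix(fr[, c("x", "y", "c")])))
      ))
    )
  })
  doc <- list(fps = fps, frames = unname(frames))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Select the upper-body joint subset
#'
#' Restricts a COCO-17 pose sequence to the 9 upper-body joints used for
#' tremor analysis (see [upper_body_joints()]) and synthesizes the neck
#' keypoint as the shoulder midpoint with confidence equal to the smaller
#' shoulder confidence (COCO-17 itself has no neck). Face and leg keypoints
#' are dropped.
#'
#' @param pose A COCO-17 pose tibble.
#' @return A pose tibble restricted to the 9-joint upper-body set, ordered
#'   frame-major.
#' @export
select_upper_body <- function(pose) {
  .pose_check(pose)
  if (!all(c("left_shoulder", "right_shoulder") %in% pose$joint)) {
    stop("both shoulders are required to synthesize the neck keypoint",
         call. = FALSE)
  }
  keep <- setdiff(upper_body_joints(), "neck")
  miss <- setdiff(keep, unique(pose$joint))
  if (length(miss)) {
    stop("pose sequence lacks upper-body joint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  body <- dplyr::filter(pose, .data$joint %in% keep)
  sh <- pose |>
    dplyr::filter(.data$joint %in% c("left_shoulder", "right_shoulder")) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("frame", "visible")))) |>
    dplyr::summarise(
      joint = "neck", x = mean(.data$x), y = mean(.data$y), c = min(.data$c),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(body, sh)
  out <- dplyr::arrange(out, .data$frame, match(.data$joint, upper_body_joints()))
  for (a in c("fps")) attr(out, a) <- attr(pose, a)
  out
}

#' Normalize a pose sequence to a body-centric origin
#'
#' Per frame, the origin is the mean position of the neck and the two hips;
#' all joint coordinates are re-expressed relative to it, which removes global
#' translation of the subject in the image. Confidences are unchanged. Frames
#' in which any anchor joint (neck or hip) has zero confidence are flagged not
#' visible and left unnormalized.
#'
#' Optionally (`scale = "torso"`), coordinates are additionally divided by
#' the video's torso length -- the median over frames of the distance from
#' the neck to the hip midpoint -- which removes inter-subject body-scale
#' variation (opt-in; plain origin alignment is the default).
#'
#' @param pose An upper-body pose tibble (see [select_upper_body()]).
#' @param scale `"none"` (origin subtraction only) or `"torso"`.
#' @return The normalized pose tibble with a `visible` column.
#' @export
normalize_pose <- function(pose, scale = c("none", "torso")) {
  scale <- match.arg(scale)
  .pose_check(pose)
  anchors <- c("neck", "left_hip", "right_hip")
  miss <- setdiff(anchors, unique(pose$joint))
  if (length(miss)) {
    stop("normalization requires joint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  origin <- pose |>
    dplyr::filter(.data$joint %in% anchors) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      .ox = mean(.data$x), .oy = mean(.data$y), .anchor_ok = min(.data$c) > 0,
      .groups = "drop"
    )
  out <- dplyr::left_join(pose, origin, by = "frame")
  if (!"visible" %in% names(out)) out$visible <- TRUE
  out <- out |>
    dplyr::mutate(
      x = ifelse(.data$.anchor_ok, .data$x - .data$.ox, .data$x),
      y = ifelse(.data$.anchor_ok, .data$y - .data$.oy, .data$y),
      visible = .data$visible & .data$.anchor_ok
    ) |>
    dplyr::select(-".ox", -".oy", -".anchor_ok")
  if (scale == "torso") {
    hips <- out |>
      dplyr::filter(.data$joint %in% c("left_hip", "right_hip"), .data$visible) |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(hx = mean(.data$x), hy = mean(.data$y), .groups = "drop")
    neck <- out |>
      dplyr::filter(.data$joint == "neck", .data$visible) |>
      dplyr::select("frame", nx = "x", ny = "y")
    tor <- dplyr::inner_join(hips, neck, by = "frame")
    L <- stats::median(sqrt((tor$hx - tor$nx)^2 + (tor$hy - tor$ny)^2))
    if (!is.finite(L) || L <= 0) {
      stop("cannot estimate torso length for scale normalization", call. = FALSE)
    }
    out$x <- out$x / L
    out$y <- out$y / L
  }
  for (a in c("fps")) attr(out, a) <- attr(pose, a)
  out
}

#' Cut fixed-length sample windows from visible runs
#'
#' Windows are the network's training/inference unit: `window` consecutive
#' frames in which the subject is visible. A frame is visible when its
#' `visible` flag (if present) is `TRUE` and every retained joint has
#' confidence at least `conf_threshold`. Windows are cut from each maximal
#' visible run, non-overlapping and left-aligned; a remainder shorter than
#' `window` is discarded.
#'
#' @param pose An upper-body, normalized pose tibble.
#' @param window Window length in frames (default 100).
#' @param conf_threshold Minimum per-joint confidence for a visible frame.
#' @return A tibble with `window_index`, `start_frame` and a `features`
#'   list-column of `window x 9 x 3` arrays (channels x, y, confidence; joints
#'   in [upper_body_joints()] order).
#' @export
clip_windows <- function(pose, window = 100, conf_threshold = 0.05) {
  .pose_check(pose)
  stopifnot(window >= 1)
  joints <- upper_body_joints()
  if (!setequal(unique(pose$joint), joints)) {
    stop("`pose` must contain exactly the 9 upper-body joints; run ",
         "select_upper_body() first", call. = FALSE)
  }
  frames <- sort(unique(pose$frame))
  wide <- dplyr::arrange(pose, .data$frame, match(.data$joint, joints))
  J <- length(joints)
  n <- length(frames)
  X <- matrix(wide$x, n, J, byrow = TRUE)
  Y <- matrix(wide$y, n, J, byrow = TRUE)
  C <- matrix(wide$c, n, J, byrow = TRUE)
  vis_flag <- if ("visible" %in% names(wide)) {
    matrix(wide$visible, n, J, byrow = TRUE)[, 1]
  } else {
    rep(TRUE, n)
  }
  visible <- vis_flag & !apply(is.na(X) | is.na(Y), 1, any) &
    apply(C >= conf_threshold, 1, all)

  runs <- rle(visible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  wi <- 0
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    n_win <- runs$lengths[r] %/% window
    for (w in seq_len(n_win)) {
      wi <- wi + 1
      i0 <- starts[r] + (w - 1) * window
      idx <- i0:(i0 + window - 1)
      feat <- array(c(X[idx, ], Y[idx, ], C[idx, ]), c(window, J, 3),
                    dimnames = list(NULL, joints, c("x", "y", "c")))
      out[[wi]] <- tibble::tibble(
        window_index = wi, start_frame = frames[i0], features = list(feat)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(window_index = integer(), start_frame = integer(),
                          features = list()))
  }
  dplyr::bind_rows(out)
}

#' Combine per-hand severity ratings into a video rating
#'
#' A video gets one severity label: the maximum of the left- and right-hand
#' Bain-Findley ratings.
#'
#' @param left,right Integer ratings in 0-7; vectorized.
#' @return Integer vector of video-level ratings.
#' @export
#' @examples
#' combine_hand_labels(2, 3)
combine_hand_labels <- function(left, right) {
  if (any(c(left, right) < 0) || any(c(left, right) > 7)) {
    stop("hand ratings must lie in 0..7", call. = FALSE)
  }
  as.integer(pmax(left, right))
}

#' Map a severity rating to a classification label
#'
#' Rating tasks classify levels `[1, 2, 3]` (higher ratings excluded) or
#' `[1, 2, 3+]` (ratings of 3 and above grouped); rating 0 is excluded from
#' both.
#'
#' @param rating Integer rating(s) in 0-7.
#' @param mode `"rating-123"` or `"rating-123plus"`.
#' @return Character label, or `NA` for excluded ratings.
#' @export
#' @examples
#' map_rating_label(5, "rating-123plus") # "3+"
#' map_rating_label(0, "rating-123") # NA: not classified
map_rating_label <- function(rating, mode = c("rating-123", "rating-123plus")) {
  mode <- match.arg(mode)
  if (mode == "rating-123") {
    ifelse(rating %in% 1:3, as.character(rating), NA_character_)
  } else {
    ifelse(rating >= 3, "3+", ifelse(rating %in% 1:2, as.character(rating),
                                     NA_character_))
  }
}

#' Label spaces for the classification tasks
#'
#' @param mode One of `"type-binary"` (Parkinsonian vs non-Parkinsonian
#'   tremor), `"type-multiclass"` (five tremor types), `"rating-123"` or
#'   `"rating-123plus"` (severity levels).
#' @return Ordered character vector of class names.
#' @export
label_space <- function(mode = c("type-binary", "type-multiclass",
                                 "rating-123", "rating-123plus")) {
  mode <- match.arg(mode)
  switch(mode,
    "type-binary" = c("PT", "non-PT"),
    "type-multiclass" = c("PT", "ET", "DT", "FT", "NT"),
    "rating-123" = c("1", "2", "3"),
    "rating-123plus" = c("1", "2", "3+")
  )
}

#' Build a windowed, labeled dataset from a cohort
#'
#' Runs every video through upper-body selection, body-centric normalization
#' and window clipping, then attaches the task label: tremor type (binary or
#' multiclass; videos labeled "Other" are removed from type tasks) or severity
#' rating (videos outside the rating space are removed). Each window inherits
#' its video's label.
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()] (columns
#'   `subject_id`, `video_id`, `class`, `left_rating`, `right_rating`, `pose`).
#' @param mode Task mode, see [label_space()].
#' @param window Window length in frames.
#' @param conf_threshold Visibility threshold, see [clip_windows()].
#' @param scale Coordinate normalization passed to [normalize_pose()].
#' @return A window tibble: `subject_id`, `video_id`, `window_index`, `label`
#'   (factor over the label space) and `features` list-column.
#' @export
window_dataset <- function(cohort, mode = "type-binary", window = 100,
                           conf_threshold = 0.05, scale = "none") {
  classes <- label_space(mode)
  rows <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    row <- cohort[k, ]
    label <- if (mode == "type-binary") {
      if (row$class == "Other") NA_character_
      else if (row$class == "PT") "PT" else "non-PT"
    } else if (mode == "type-multiclass") {
      if (row$class %in% classes) row$class else NA_character_
    } else {
      map_rating_label(combine_hand_labels(row$left_rating, row$right_rating),
                       mode)
    }
    if (is.na(label)) next
    win <- row$pose[[1]] |>
      select_upper_body() |>
      normalize_pose(scale = scale) |>
      clip_windows(window = window, conf_threshold = conf_threshold)
    if (nrow(win) == 0) next
    win$subject_id <- row$subject_id
    win$video_id <- row$video_id
    win$label <- label
    rows[[k]] <- win
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop("no windows survived preprocessing; clips may be shorter than the ",
         "window length", call. = FALSE)
  }
  out$label <- factor(out$label, levels = classes)
  dplyr::select(out, "subject_id", "video_id", "window_index", "start_frame",
                "label", "features")
}
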