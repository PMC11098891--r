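write_toy_json <- function(frames, file = tempfile(fileext = ".json")) {
  jsonlite::write_json(list(fps = 30, frames = frames), file,
                       auto_unbox = TRUE, digits = NA)
  file
}

kp_flat <- function(x0 = 0) as.vector(t(cbind(x0 + 1:17, 100 + 1:17, 0.9)))

test_that("parse_pose_json ingests frames and keeps the best detection", {
  frames <- list(
    list(frame = 1, people = list(list(score = 0.8, keypoints = kp_flat()))),
    list(frame = 2, people = list()), # no detection
    list(frame = 3, people = list(
      list(score = 0.9, keypoints = kp_flat(1000)),
      list(score = 0.4, keypoints = kp_flat(0))
    ))
  )
  pose <- parse_pose_json(write_toy_json(frames))
  expect_equal(nrow(pose), 3 * 17)
  expect_equal(attr(pose, "fps"), 30)
  f2 <- pose[pose$frame == 2, ]
  expect_false(any(f2$visible))
  expect_true(all(f2$c == 0))
  # frame 3 keeps the 0.9-score detection (x offset 1000)
  expect_true(all(pose$x[pose$frame == 3] > 1000))
})

test_that("parse_pose_json rejects malformed and empty streams", {
  bad <- list(list(frame = 1, people = list(list(score = 1, keypoints = 1:10))))
  expect_error(parse_pose_json(write_toy_json(bad)), "frame 1")
  expect_error(parse_pose_json(write_toy_json(list())), "zero frames")
})

test_that("pose json round-trips through write_pose_json", {
  subj <- simulate_subject("PT", severity = 2, seed = 5, duration = 1)
  f <- tempfile(fileext = ".json")
  write_pose_json(subj$pose[[1]], f, fps = 30)
  back <- parse_pose_json(f)
  orig <- dplyr::arrange(subj$pose[[1]], frame, match(joint, coco17_joints()))
  expect_equal(back$x, orig$x, tolerance = 1e-12)
  expect_equal(back$y, orig$y, tolerance = 1e-12)
  expect_equal(back$c, orig$c, tolerance = 1e-12)
})

test_that("select_upper_body keeps 9 joints and synthesizes the neck", {
  pose <- toy_pose(2)
  pose$x[pose$joint == "left_shoulder"] <- -2
  pose$x[pose$joint == "right_shoulder"] <- 2
  pose$y[pose$joint %in% c("left_shoulder", "right_shoulder")] <- 0
  pose$c[pose$joint == "left_shoulder"] <- 0.8
  pose$c[pose$joint == "right_shoulder"] <- 0.6
  ub <- select_upper_body(pose)
  expect_setequal(unique(ub$joint), upper_body_joints())
  expect_false(any(c("nose", "left_knee", "left_eye") %in% ub$joint))
  neck <- ub[ub$joint == "neck", ]
  expect_equal(neck$x, c(0, 0))
  expect_equal(neck$y, c(0, 0))
  expect_equal(neck$c, c(0.6, 0.6)) # min of the shoulder confidences
})

test_that("select_upper_body requires shoulders", {
  pose <- toy_pose(1)
  pose <- pose[pose$joint != "left_shoulder", ]
  expect_error(select_upper_body(pose), "shoulder")
})

test_that("normalize_pose subtracts the neck/hip centroid per frame", {
  pose <- toy_pose(1) |> select_upper_body()
  pose$x[pose$joint == "neck"] <- 0; pose$y[pose$joint == "neck"] <- 0
  pose$x[pose$joint == "left_hip"] <- -1; pose$y[pose$joint == "left_hip"] <- 2
  pose$x[pose$joint == "right_hip"] <- 1; pose$y[pose$joint == "right_hip"] <- 2
  pose$x[pose$joint == "left_wrist"] <- 2; pose$y[pose$joint == "left_wrist"] <- 2
  norm <- normalize_pose(pose)
  # origin is (0, 4/3); the wrist at (2,2) maps to (2, 2/3)
  expect_equal(norm$x[norm$joint == "left_wrist"], 2)
  expect_equal(norm$y[norm$joint == "left_wrist"], 2 - 4 / 3)
  expect_equal(norm$x[norm$joint == "neck"], 0)
  expect_equal(norm$y[norm$joint == "neck"], -4 / 3)
})

test_that("normalization is exactly invariant to global translation", {
  base <- simulate_subject("PT", seed = 2, duration = 1)$pose[[1]] |>
    select_upper_body()
  ref <- normalize_pose(base)
  set.seed(42)
  for (k in 1:100) {
    shift <- runif(2, -500, 500)
    moved <- dplyr::mutate(base, x = x + shift[1], y = y + shift[2])
    expect_equal(normalize_pose(moved)$x, ref$x, tolerance = 1e-12)
    expect_equal(normalize_pose(moved)$y, ref$y, tolerance = 1e-12)
  }
})

test_that("frames with zero-confidence anchors are flagged not visible", {
  pose <- toy_pose(2) |> select_upper_body()
  pose$c[pose$joint == "left_hip" & pose$frame == 2] <- 0
  norm <- normalize_pose(pose)
  expect_true(all(norm$visible[norm$frame == 1]))
  expect_false(any(norm$visible[norm$frame == 2]))
  # unnormalized coordinates retained for the flagged frame
  expect_equal(norm$x[norm$frame == 2], pose$x[pose$frame == 2])
})

test_that("clip_windows cuts non-overlapping left-aligned windows per visible run", {
  w <- clip_windows(visible_pattern_pose(rep(TRUE, 250)), window = 100)
  expect_equal(nrow(w), 2)
  expect_equal(w$start_frame, c(1, 101))
  expect_equal(dim(w$features[[1]]), c(100, 9, 3))

  expect_equal(nrow(clip_windows(visible_pattern_pose(rep(TRUE, 99)), 100)), 0)

  pat <- c(rep(TRUE, 120), rep(FALSE, 5), rep(TRUE, 130))
  w2 <- clip_windows(visible_pattern_pose(pat), window = 100)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$start_frame, c(1, 126))
})

test_that("window count equals the sum of per-run floor divisions", {
  set.seed(7)
  for (k in 1:25) {
    pat <- runif(sample(50:400, 1)) > 0.3
    w <- clip_windows(visible_pattern_pose(pat), window = 30)
    runs <- rle(pat)
    want <- sum(runs$lengths[runs$values] %/% 30)
    expect_equal(nrow(w), want)
  }
})

test_that("hand labels combine by maximum and validate their range", {
  expect_identical(combine_hand_labels(2, 3), 3L)
  expect_identical(combine_hand_labels(0, 0), 0L)
  expect_identical(combine_hand_labels(7, 1), 7L)
  expect_error(combine_hand_labels(8, 1), "0..7")
  # symmetric and idempotent
  set.seed(1)
  l <- sample(0:7, 20, TRUE); r <- sample(0:7, 20, TRUE)
  expect_identical(combine_hand_labels(l, r), combine_hand_labels(r, l))
  expect_identical(combine_hand_labels(l, l), l)
})

test_that("rating labels map and exclude as configured", {
  expect_identical(map_rating_label(5, "rating-123plus"), "3+")
  expect_identical(map_rating_label(3, "rating-123"), "3")
  expect_true(is.na(map_rating_label(0, "rating-123")))
  expect_true(is.na(map_rating_label(4, "rating-123")))
  expect_true(is.na(map_rating_label(0, "rating-123plus")))
  expect_identical(map_rating_label(1:3, "rating-123"), c("1", "2", "3"))
})

test_that("window_dataset assigns the video label to every window", {
  cohort <- simulate_cohort(4, n_per_class = c(PT = 2, NT = 2), seed = 3,
                            occlusion_rate = 0)
  w <- window_dataset(cohort, mode = "type-binary")
  expect_setequal(levels(w$label), c("PT", "non-PT"))
  merged <- dplyr::left_join(w, cohort[, c("video_id", "class")], by = "video_id")
  expect_true(all((merged$class == "PT") == (merged$label == "PT")))
  # rating mode drops NT (rating 0) videos
  wr <- window_dataset(cohort[cohort$class == "PT", ], mode = "rating-123")
  expect_true(all(wr$label %in% c("1", "2", "3")))
})
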