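#' Keypoint layouts
#'
#' `coco17_joints()` returns the standard 17-keypoint COCO layout produced by
#' common 2D pose estimators. `upper_body_joints()` returns the 9-joint
#' upper-body subset the tremor network operates on: the synthesized neck,
#' both shoulders, elbows, wrists and hips. Head/face and leg keypoints are
#' excluded -- faces are typically blurred in clinical video and tremor is an
#' upper-limb phenomenon.
#'
#' @return A character vector of joint names.
#' @export
#' @examples
#' upper_body_joints()
coco17_joints <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

#' @rdname coco17_joints
#' @export
upper_body_joints <- function() {
  c("neck", "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip")
}
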