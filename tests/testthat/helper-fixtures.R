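# Shared fixtures built in code.

# minimal COCO-17 pose tibble: one row per (frame, joint) with constant
# template coordinates unless overridden
toy_pose <- function(n_frames = 3, conf = 0.9) {
  joints <- coco17_joints()
  tibble::tibble(
    frame = rep(seq_len(n_frames), each = length(joints)),
    joint = rep(joints, times = n_frames),
    x = rep(seq_along(joints) * 10, times = n_frames),
    y = rep(100 + seq_along(joints), times = n_frames),
    c = conf
  )
}

# upper-body pose with given per-frame visibility pattern (confidence-driven)
visible_pattern_pose <- function(visible) {
  joints <- upper_body_joints()
  n <- length(visible)
  tibble::tibble(
    frame = rep(seq_len(n), each = length(joints)),
    joint = rep(joints, times = n),
    x = 0, y = 0,
    c = rep(ifelse(visible, 0.9, 0.01), each = length(joints))
  )
}

# independent Floyd-Warshall shortest paths (oracle for hop distances)
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  dimnames(D) <- dimnames(A)
  D
}

# independent confusion-matrix metrics (oracle for compute_metrics)
oracle_metrics <- function(pred, truth, positive) {
  pred <- as.character(pred); truth <- as.character(truth)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  list(
    accuracy = 100 * mean(pred == truth),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    f1 = 100 * 2 * tp / (2 * tp + fp + fn)
  )
}

# amplitude of the dominant in-band component via the FFT (oracle)
fft_band_amplitude <- function(x, fps, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2))] * 2 / n
  freq <- (seq_len(floor(n / 2)) - 1) * fps / n
  max(sp[freq >= f_lo & freq <= f_hi])
}
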