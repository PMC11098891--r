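# Eulerian video magnification: amplify subtle band-limited motion before pose
# extraction. Parkinsonian rest tremor sits at 3-7 Hz, so the default band is
# [3, 7] Hz and a 30 Hz consumer camera satisfies the Nyquist requirement.

#' Video clip container
#'
#' A lightweight container for an ordered stack of frames with a frame rate.
#' Frames are stored as an array: `H x W x T` for grayscale or
#' `H x W x 3 x T` for color, with intensities in \[0, 1\].
#'
#' @param frames Numeric array of frames (see above).
#' @param fps Frame rate in Hz.
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, fps) {
  stopifnot(is.numeric(fps), length(fps) == 1, fps > 0)
  nd <- length(dim(frames))
  if (!nd %in% c(3, 4)) {
    stop("`frames` must be an H x W x T or H x W x 3 x T array", call. = FALSE)
  }
  if (nd == 4 && dim(frames)[3] != 3) {
    stop("color clips must have 3 channels", call. = FALSE)
  }
  if (min(frames) < -1e-9 || max(frames) > 1 + 1e-9) {
    stop("frame intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(frames = frames, fps = fps), class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  nt <- d[length(d)]
  cat("<video_clip> ", d[1], "x", d[2], ", ",
      if (length(d) == 4) "color" else "grayscale", ", ",
      nt, " frames @ ", x$fps, " fps (", round(nt / x$fps, 2), " s)\n", sep = "")
  invisible(x)
}

.n_frames <- function(video) {
  d <- dim(video$frames)
  d[length(d)]
}

#' Check the Nyquist sampling requirement
#'
#' A video can only carry motion up to half its frame rate: to analyze tremor
#' up to `f_max` Hz the frame rate must be at least `2 * f_max`.
#'
#' @param fps Frame rate in Hz.
#' @param f_max Highest motion frequency of interest in Hz.
#' @return A list of class `nyquist_check` with elements `valid` (logical) and
#'   `message`.
#' @export
#' @examples
#' check_nyquist(30, 7)$valid # TRUE: 30 Hz covers tremor up to 15 Hz
#' check_nyquist(10, 7)$valid # FALSE
check_nyquist <- function(fps, f_max) {
  if (!is.numeric(fps) || !is.numeric(f_max) || fps <= 0 || f_max <= 0) {
    stop("`fps` and `f_max` must be positive", call. = FALSE)
  }
  valid <- fps >= 2 * f_max
  msg <- if (valid) {
    sprintf("frame rate %g Hz resolves motion up to %g Hz (need >= %g Hz)",
            fps, f_max, 2 * f_max)
  } else {
    sprintf("frame rate %g Hz cannot resolve %g Hz motion (need >= %g Hz)",
            fps, f_max, 2 * f_max)
  }
  structure(list(valid = valid, message = msg), class = "nyquist_check")
}

#' @export
print.nyquist_check <- function(x, ...) {
  cat(if (x$valid) "valid: " else "invalid: ", x$message, "\n", sep = "")
  invisible(x)
}

#' Temporal ideal band-pass filter
#'
#' Filters each time series to the band \[`f_lo`, `f_hi`\] Hz with an ideal
#' (frequency-domain) filter. Series are reflect-padded before the FFT to
#' suppress edge ringing on short clips. The DC component is outside any valid
#' band, so a constant series filters to zero.
#'
#' @param x Numeric vector, or a matrix whose columns are time series.
#' @param fps Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz; `0 < f_lo < f_hi < fps/2`.
#' @return Filtered series, same shape as `x`.
#' @export
#' @examples
#' t <- seq(0, 3, by = 1 / 30)
#' y <- sin(2 * pi * 5 * t) + sin(2 * pi * 0.5 * t)
#' yf <- temporal_bandpass(y, 30, 3, 7) # keeps the 5 Hz component
temporal_bandpass <- function(x, fps, f_lo, f_hi) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (n < 4) stop("need at least 4 time samples", call. = FALSE)
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= fps / 2) {
    stop("band edge f_hi = ", f_hi, " Hz exceeds the Nyquist frequency ",
         fps / 2, " Hz", call. = FALSE)
  }
  # even (reflect) extension: [x1..xn, x(n-1)..x2]
  Xp <- rbind(X, X[(n - 1):2, , drop = FALSE])
  m <- nrow(Xp)
  freq <- (seq_len(m) - 1) * fps / m
  freq <- pmin(freq, fps - freq) # two-sided
  keep <- freq >= f_lo & freq <= f_hi
  Xf <- stats::mvfft(Xp)
  Xf[!keep, ] <- 0
  out <- Re(stats::mvfft(Xf, inverse = TRUE)) / m
  out <- out[seq_len(n), , drop = FALSE]
  if (vec) drop(out) else out
}

# --- spatial pyramid helpers -------------------------------------------------

# banded convolution matrix for the [1,4,6,4,1]/16 binomial kernel with
# reflect boundary handling
.conv_mat <- function(n) {
  k <- c(1, 4, 6, 4, 1) / 16
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -2:2) {
      j <- i + o
      if (j < 1) j <- 2 - j
      if (j > n) j <- 2 * n - j
      C[i, j] <- C[i, j] + k[o + 3]
    }
  }
  C
}

.blur_stack <- function(V) {
  d <- dim(V)
  Ch <- .conv_mat(d[1])
  Cw <- .conv_mat(d[2])
  out <- array(Ch %*% matrix(V, d[1]), d)
  out <- aperm(out, c(2, 1, 3))
  out <- array(Cw %*% matrix(out, d[2]), dim(out))
  aperm(out, c(2, 1, 3))
}

.down_stack <- function(V) {
  B <- .blur_stack(V)
  B[seq(1, dim(B)[1], by = 2), seq(1, dim(B)[2], by = 2), , drop = FALSE]
}

.up_stack <- function(V, h, w) {
  d <- dim(V)
  Z <- array(0, c(h, w, d[3]))
  Z[seq(1, h, by = 2)[seq_len(d[1])], seq(1, w, by = 2)[seq_len(d[2])], ] <- 4 * V
  .blur_stack(Z)
}

#' Eulerian motion magnification
#'
#' Amplifies motion within a temporal frequency band. Each frame stack is
#' decomposed into a band-limited spatial pyramid (Laplacian bands of a
#' Gaussian pyramid, which reconstructs exactly); every band below the finest
#' scale is temporally band-pass filtered, scaled by `alpha` and added back,
#' so in-band motion at coarse scales is amplified by approximately
#' `1 + alpha`. Color clips are processed on the luminance channel only; the
#' result is clipped to \[0, 1\].
#'
#' @param video A [video_clip()].
#' @param f_lo,f_hi Temporal band in Hz (default 3-7 Hz, the Parkinsonian
#'   tremor range).
#' @param alpha Amplification factor (`alpha = 0` returns the input up to
#'   numerical round-off).
#' @param levels Pyramid depth (number of downsampling steps).
#' @return A magnified [video_clip()] with identical dimensions and fps.
#' @export
#' @examples
#' dot <- simulate_dot_video(freq = 5, amp = 1, duration = 2)
#' mag <- evm_magnify(dot$video, alpha = 5)
evm_magnify <- function(video, f_lo = 3, f_hi = 7, alpha = 10, levels = 4) {
  stopifnot(inherits(video, "video_clip"))
  if (.n_frames(video) < 2) stop("need at least 2 frames", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  if (levels < 1) stop("`levels` must be at least 1", call. = FALSE)
  ny <- check_nyquist(video$fps, f_hi)
  if (!ny$valid) {
    stop("refusing to magnify: ", ny$message, call. = FALSE)
  }

  color <- length(dim(video$frames)) == 4
  if (color) {
    lum <- 0.299 * video$frames[, , 1, ] + 0.587 * video$frames[, , 2, ] +
      0.114 * video$frames[, , 3, ]
    mag <- .magnify_gray(lum, video$fps, f_lo, f_hi, alpha, levels)
    delta <- mag - lum
    out <- video$frames
    for (ch in 1:3) out[, , ch, ] <- out[, , ch, ] + delta
  } else {
    out <- .magnify_gray(video$frames, video$fps, f_lo, f_hi, alpha, levels)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  video_clip(out, video$fps)
}

.magnify_gray <- function(V, fps, f_lo, f_hi, alpha, levels) {
  # Gaussian pyramid
  G <- vector("list", levels + 1)
  G[[1]] <- V
  for (l in seq_len(levels)) {
    if (min(dim(G[[l]])[1:2]) < 8) {
      levels <- l - 1
      G <- G[seq_len(levels + 1)]
      break
    }
    G[[l + 1]] <- .down_stack(G[[l]])
  }
  # Laplacian bands; amplify all bands below the finest scale
  out <- G[[levels + 1]]
  out <- out + alpha * .bandpass_stack(out, fps, f_lo, f_hi)
  for (l in rev(seq_len(levels))) {
    d <- dim(G[[l]])
    L <- G[[l]] - .up_stack(G[[l + 1]], d[1], d[2])
    if (l > 1) L <- L + alpha * .bandpass_stack(L, fps, f_lo, f_hi)
    out <- .up_stack(out, d[1], d[2]) + L
  }
  out
}

.bandpass_stack <- function(V, fps, f_lo, f_hi) {
  d <- dim(V)
  M <- t(matrix(V, d[1] * d[2], d[3])) # time x pixels
  array(t(temporal_bandpass(M, fps, f_lo, f_hi)), d)
}

#' Read and write PNG frame stacks
#'
#' Videos are exchanged as directories of numbered PNG frames; the frame rate
#' is not stored in the images and must be supplied.
#'
#' @param path Directory of PNG frames (read) or target directory (write).
#' @param fps Frame rate in Hz.
#' @param video A [video_clip()] to write.
#' @param prefix Filename prefix for written frames.
#' @return `read_video_frames()` returns a [video_clip()];
#'   `write_video_frames()` invisibly returns the written file paths.
#' @export
read_video_frames <- function(path, fps) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", path, call. = FALSE)
  imgs <- lapply(files, png::readPNG)
  d <- dim(imgs[[1]])
  if (length(d) == 3 && d[3] >= 3) {
    frames <- array(0, c(d[1], d[2], 3, length(imgs)))
    for (f in seq_along(imgs)) frames[, , , f] <- imgs[[f]][, , 1:3]
  } else {
    frames <- array(0, c(d[1], d[2], length(imgs)))
    for (f in seq_along(imgs)) frames[, , f] <- if (length(d) == 3) imgs[[f]][, , 1] else imgs[[f]]
  }
  video_clip(frames, fps)
}

#' @rdname read_video_frames
#' @export
write_video_frames <- function(video, path, prefix = "frame") {
  stopifnot(inherits(video, "video_clip"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nt <- .n_frames(video)
  color <- length(dim(video$frames)) == 4
  paths <- character(nt)
  for (f in seq_len(nt)) {
    img <- if (color) video$frames[, , , f] else video$frames[, , f]
    paths[f] <- file.path(path, sprintf("%s_%05d.png", prefix, f))
    png::writePNG(img, paths[f])
  }
  invisible(paths)
}

#' Track the bright-blob centroid across frames
#'
#' Intensity-weighted centroid of above-threshold pixels per frame; the
#' independent measurement used to verify motion magnification on synthetic
#' dot videos.
#'
#' @param video A [video_clip()] (color clips are tracked on luminance).
#' @return A tibble with `frame`, `x`, `y` centroid coordinates (pixels).
#' @export
track_centroid <- function(video) {
  stopifnot(inherits(video, "video_clip"))
  V <- video$frames
  if (length(dim(V)) == 4) {
    V <- 0.299 * V[, , 1, ] + 0.587 * V[, , 2, ] + 0.114 * V[, , 3, ]
  }
  d <- dim(V)
  xs <- seq_len(d[2])
  ys <- seq_len(d[1])
  out <- tibble::tibble(frame = seq_len(d[3]), x = NA_real_, y = NA_real_)
  for (f in seq_len(d[3])) {
    M <- V[, , f]
    thr <- 0.5 * (max(M) + min(M))
    W <- pmax(M - thr, 0)
    s <- sum(W)
    out$x[f] <- sum(W %*% xs) / s
    out$y[f] <- sum(ys %*% W) / s
  }
  out
}

#' Amplitude of an oscillating series
#'
#' Root-mean-square-based amplitude estimate: for `A * sin(...)` plus a slow
#' trend this returns approximately `A`.
#'
#' @param x Numeric series.
#' @return Estimated amplitude (same units as `x`).
#' @export
oscillation_amplitude <- function(x) {
  t <- seq_along(x)
  sqrt(2) * stats::sd(stats::residuals(stats::lm(x ~ t)))
}
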