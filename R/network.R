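# The spatial-attention graph network. Two graph blocks with locally
# connected (per-joint-pair) attention weights, each followed by batch
# normalization, LeakyReLU and dropout; a pyramidal channel-squeezing-fusion
# block; global average pooling over frames and joints; and a fully connected
# classifier. The compiled core (src/net.cpp) evaluates the forward and
# backward passes; this file owns configuration, parameter state and the
# optimization loop.

#' Model and training configuration
#'
#' Defaults follow the reference training recipe for clinical-scale data:
#' graph-block output channels 64 and 128, LeakyReLU slope 0.2, dropout 0.2,
#' Adam with learning rate 0.01 decayed by 0.1 (halfway through training by
#' default), batch size 8, 500 epochs; cross-entropy loss for binary tasks
#' and focal loss (gamma = 2, inverse-class-frequency alpha) for multiclass
#' tasks. `p` and `q` are the short- and long-range channel-squeezing ratios.
#'
#' @param channels Output channel sizes of the two graph blocks.
#' @param p,q Channel-squeezing ratios (see [squeeze_channels()]).
#' @param dropout Dropout rate in both blocks.
#' @param leaky Negative slope of the LeakyReLU activation.
#' @param lr,lr_decay,decay_at Adam learning rate, multiplicative decay
#'   factor, and the epoch at which it is applied (`NULL` = half of `epochs`).
#' @param weight_decay Decoupled (AdamW-style) weight decay coefficient
#'   applied to the linear weights (not to batch-norm parameters or biases).
#' @param batch_size,epochs Minibatch size and number of training epochs.
#' @param loss `"auto"` (cross-entropy when binary, focal otherwise),
#'   `"ce"` or `"focal"`.
#' @param focal_gamma Focusing parameter of the focal loss.
#' @param augment_mirror During training, reflect each window left-right with
#'   probability 1/2 (negate body-centric x, swap left/right joints). The
#'   standard skeleton-data augmentation; appropriate here because tremor
#'   laterality is arbitrary.
#' @param swa_epochs Number of final epochs whose weights are averaged
#'   (stochastic weight averaging) before the batch-norm refresh; stabilizes
#'   the decision boundary learned from small cohorts. `0` disables.
#' @param augment_jitter Coordinate-noise augmentation: fresh Gaussian noise
#'   added to every feature at each training step, expressed as a fraction of
#'   each feature column's standard deviation. Emulates drawing a new
#'   pose-estimator noise realization per epoch so the network cannot
#'   memorize the fixed jitter of its training windows; `0` disables.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param window Window length in frames the model expects.
#' @return A list of class `tremor_config`.
#' @export
model_config <- function(channels = c(64, 128), p = 0.5, q = 0.25,
                         dropout = 0.2, leaky = 0.2,
                         lr = 0.01, lr_decay = 0.1, decay_at = NULL,
                         weight_decay = 0,
                         batch_size = 8, epochs = 500,
                         loss = c("auto", "ce", "focal"), focal_gamma = 2,
                         augment_mirror = FALSE, augment_jitter = 0,
                         swa_epochs = 10, seed = 1L, window = 100) {
  stopifnot(length(channels) == 2, all(channels >= 1), epochs >= 1,
            batch_size >= 1, dropout >= 0, dropout < 1, lr > 0)
  structure(list(
    channels = as.integer(channels), p = p, q = q,
    dropout = dropout, leaky = leaky,
    lr = lr, lr_decay = lr_decay, decay_at = decay_at,
    weight_decay = weight_decay,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    loss = match.arg(loss), focal_gamma = focal_gamma,
    augment_mirror = isTRUE(augment_mirror),
    augment_jitter = augment_jitter,
    swa_epochs = as.integer(swa_epochs),
    bn_momentum = 0.1, bn_eps = 1e-5,
    seed = as.integer(seed), window = as.integer(window)
  ), class = "tremor_config")
}

#' Desk-scale benchmark configuration
#'
#' A scaled-down configuration for synthetic-cohort experiments on a single
#' CPU: narrower blocks (8/16 channels), 50 epochs, batch size 8. The
#' architecture and training recipe are otherwise identical to
#' [model_config()].
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [model_config()].
#' @return A `tremor_config`.
#' @export
benchmark_config <- function(seed = 1L, ...) {
  model_config(channels = c(8, 16), epochs = 50, batch_size = 8,
               seed = seed, ...)
}

# architecture descriptor consumed by the compiled core (0-based indices)
.build_arch <- function(graph, n_classes, config, variant = "full") {
  variant <- match.arg(variant, c("full", "no_pcsf", "no_attention"))
  J <- length(graph$joints)
  A <- graph$adjacency
  hops <- graph$hops
  nb <- av <- slot_src <- slot_w <- vector("list", J)
  for (i in seq_len(J)) {
    js <- which(A[i, ] > 0)
    nb[[i]] <- as.integer(js - 1)
    av[[i]] <- unname(A[i, js])
    ord <- order(hops[i, ], seq_len(J))
    slot_src[[i]] <- as.integer(ord - 1)
    slot_w[[i]] <- squeeze_channels(hops[i, ord], config$channels[2],
                                    config$p, config$q)
  }
  list(
    J = J, C0 = 3L, C1 = config$channels[1], C2 = config$channels[2],
    K = as.integer(n_classes), Fw = config$window,
    nb = nb, av = av, slot_src = slot_src, slot_w = slot_w,
    use_attention = variant != "no_attention",
    use_pcsf = variant == "full",
    joints = graph$joints, variant = variant
  )
}

.glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

.init_params <- function(arch) {
  J <- arch$J
  p <- list()
  if (arch$use_attention) {
    p$W1 <- lapply(seq_len(J), function(i)
      .glorot(length(arch$nb[[i]]) * arch$C0, arch$C1))
    p$W2 <- lapply(seq_len(J), function(i)
      .glorot(length(arch$nb[[i]]) * arch$C1, arch$C2))
  } else {
    p$W1 <- .glorot(arch$C0, arch$C1)
    p$W2 <- .glorot(arch$C1, arch$C2)
  }
  p$g1 <- rep(1, J * arch$C1); p$b1 <- rep(0, J * arch$C1)
  p$g2 <- rep(1, J * arch$C2); p$b2 <- rep(0, J * arch$C2)
  if (arch$use_pcsf) {
    p$S <- lapply(seq_len(J), function(i)
      lapply(arch$slot_w[[i]], function(w) .glorot(arch$C2, w)))
    p$Fm <- lapply(seq_len(J), function(i)
      .glorot(sum(arch$slot_w[[i]]), arch$C2))
  }
  p$Wfc <- .glorot(arch$J * arch$C2, arch$K)
  p$bfc <- rep(0, arch$K)
  p
}

.init_state <- function(arch) {
  list(rm1 = rep(0, arch$J * arch$C1), rv1 = rep(1, arch$J * arch$C1),
       rm2 = rep(0, arch$J * arch$C2), rv2 = rep(1, arch$J * arch$C2))
}

.hyper <- function(config, arch, training, backward = FALSE,
                   attention = FALSE, alpha = NULL) {
  loss <- config$loss
  if (loss == "auto") loss <- if (arch$K == 2) "ce" else "focal"
  list(
    training = training, backward = backward, attention = attention,
    dropout = config$dropout, leaky = config$leaky,
    bn_momentum = config$bn_momentum, bn_eps = config$bn_eps,
    loss_type = if (loss == "ce") 0L else 1L,
    focal_gamma = config$focal_gamma,
    alpha = if (is.null(alpha)) rep(1, arch$K) else alpha
  )
}

# left-right mirror of the feature columns: swap each joint with its
# contralateral partner and negate the body-centric x coordinate
.mirror_map <- function() {
  joints <- upper_body_joints()
  partner <- gsub("^left_", "tmp_", joints)
  partner <- gsub("^right_", "left_", partner)
  partner <- gsub("^tmp_", "right_", partner)
  cols <- as.vector(vapply(match(partner, joints), function(j) (j - 1) * 3 + 1:3,
                           numeric(3)))
  sign <- rep(c(-1, 1, 1), length(joints))
  list(cols = cols, sign = sign)
}

# windows (list of Fw x J x 3 arrays) -> row-stacked feature matrix with
# joint-major columns: column (j-1)*3 + c holds channel c of joint j
.stack_features <- function(features) {
  do.call(rbind, lapply(features, function(a) {
    matrix(aperm(a, c(1, 3, 2)), nrow = dim(a)[1])
  }))
}

#' Focal loss
#'
#' Reference implementation of the focal loss
#' `FL(p_y) = -alpha_y * (1 - p_y)^gamma * log(p_y)` used for imbalanced
#' multiclass training; with `gamma = 0` and uniform `alpha` it reduces to
#' cross-entropy.
#'
#' @param probs Matrix of class probabilities (rows = samples).
#' @param y Integer class indices (1-based) or a factor aligned with the
#'   columns of `probs`.
#' @param gamma Focusing parameter (>= 0).
#' @param alpha Optional per-class weight vector (default uniform).
#' @return Mean loss (non-negative scalar).
#' @export
#' @examples
#' focal_loss(matrix(c(0.7, 0.2, 0.1), 1), 1, gamma = 2) # (1-0.7)^2 * -log(0.7)
focal_loss <- function(probs, y, gamma = 2, alpha = NULL) {
  probs <- as.matrix(probs)
  y <- if (is.factor(y)) as.integer(y) else as.integer(y)
  stopifnot(all(y >= 1), all(y <= ncol(probs)))
  if (is.null(alpha)) alpha <- rep(1, ncol(probs))
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  mean(-alpha[y] * (1 - p)^gamma * log(p))
}

#' Fit the spatial-attention graph network
#'
#' Trains the network on a window dataset (all rows; use [run_loocv()] for
#' subject-wise cross-validated evaluation). Three architecture variants are
#' available: `"full"` (attention + channel-squeezing-fusion), `"no_pcsf"`
#' (attention blocks only) and `"no_attention"` (shared-weight graph
#' convolution), matching the standard ablation axes.
#'
#' @param windows A window tibble from [window_dataset()] (columns `label`,
#'   `features`).
#' @param config A [model_config()].
#' @param variant `"full"`, `"no_pcsf"` or `"no_attention"`.
#' @param graph The [skeleton_graph()] to operate on.
#' @return A fitted model of class `tremor_gnn`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(4, n_per_class = c(PT = 2, NT = 2), seed = 1)
#' windows <- window_dataset(cohort)
#' fit <- tremor_gnn(windows, benchmark_config(), variant = "full")
#' predict(fit, windows)
#' }
tremor_gnn <- function(windows, config = model_config(), variant = "full",
                       graph = skeleton_graph()) {
  stopifnot(is.data.frame(windows), all(c("label", "features") %in% names(windows)))
  if (anyNA(windows$label)) stop("windows contain NA labels", call. = FALSE)
  classes <- levels(windows$label)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  y <- as.integer(windows$label) - 1L
  present <- sort(unique(y))
  X <- .stack_features(windows$features)

  arch <- .build_arch(graph, length(classes), config, variant)
  if (ncol(X) != arch$J * arch$C0) {
    stop("window features do not match the ", arch$J, "-joint graph", call. = FALSE)
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)

  params <- .init_params(arch)
  state <- .init_state(arch)
  skel <- params
  theta <- unlist(params, use.names = FALSE)
  m <- v <- numeric(length(theta))
  # weight decay acts on the linear maps only, not on BN parameters/biases
  wd_mask <- unlist(lapply(names(skel), function(nm) {
    rep(as.numeric(!nm %in% c("g1", "b1", "g2", "b2", "bfc")),
        length(unlist(skel[[nm]])))
  }))

  n_cls <- tabulate(y + 1L, nbins = arch$K)
  alpha <- ifelse(n_cls > 0, sum(n_cls) / (arch$K * pmax(n_cls, 1)), 1)
  hy <- .hyper(config, arch, training = TRUE, backward = TRUE, alpha = alpha)

  n <- nrow(windows)
  Fw <- arch$Fw
  lr <- config$lr
  decay_at <- if (is.null(config$decay_at)) ceiling(config$epochs / 2) else config$decay_at
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  mir <- .mirror_map()
  aug_sd <- if (config$augment_jitter > 0) {
    config$augment_jitter * apply(X, 2, stats::sd)
  } else NULL
  swa_sum <- NULL
  swa_k <- 0
  loss_hist <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    if (epoch == decay_at + 1) lr <- lr * config$lr_decay
    perm <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      rows <- as.vector(outer(seq_len(Fw), (idx - 1) * Fw, `+`))
      Xb <- X[rows, , drop = FALSE]
      if (!is.null(aug_sd)) {
        Xb <- Xb + matrix(rnorm(length(Xb)), nrow(Xb), ncol(Xb)) *
          rep(aug_sd, each = nrow(Xb))
      }
      if (config$augment_mirror) {
        flip <- runif(length(idx)) < 0.5
        if (any(flip)) {
          frows <- as.vector(outer(seq_len(Fw), (which(flip) - 1) * Fw, `+`))
          Xb[frows, ] <- Xb[frows, mir$cols, drop = FALSE] *
            rep(mir$sign, each = length(frows))
        }
      }
      res <- net_run(Xb, y[idx], arch, params, state, hy)
      ep_loss <- ep_loss + res$loss * length(idx)
      state <- list(rm1 = res$rm1, rv1 = res$rv1, rm2 = res$rm2, rv2 = res$rv2)
      g <- unlist(res$grads[names(skel)], use.names = FALSE)
      step <- step + 1
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- unlist(params, use.names = FALSE)
      theta <- theta - lr * (mhat / (sqrt(vhat) + eps) +
                               config$weight_decay * wd_mask * theta)
      params <- utils::relist(theta, skel)
    }
    loss_hist[epoch] <- ep_loss / n
    if (config$swa_epochs > 0 && epoch > config$epochs - config$swa_epochs) {
      theta <- unlist(params, use.names = FALSE)
      if (is.null(swa_sum)) swa_sum <- theta * 0
      swa_sum <- swa_sum + theta
      swa_k <- swa_k + 1
    }
  }
  if (!is.null(swa_sum)) params <- utils::relist(swa_sum / swa_k, skel)

  # batch-norm recalibration: the running statistics tracked during training
  # lag behind the final weights, so refresh them with one full pass over the
  # training set (dropout off, momentum 1 = exact population statistics)
  hy_ref <- hy
  hy_ref$backward <- FALSE
  hy_ref$dropout <- 0
  hy_ref$bn_momentum <- 1
  res <- net_run(X, y, arch, params, state, hy_ref)
  state <- list(rm1 = res$rm1, rv1 = res$rv1, rm2 = res$rm2, rv2 = res$rv2)

  structure(list(
    params = params, state = state, arch = arch, config = config,
    classes = classes, variant = variant, loss_history = loss_hist,
    n_windows = n
  ), class = "tremor_gnn")
}

#' @export
print.tremor_gnn <- function(x, ...) {
  cat("<tremor_gnn> ", x$variant, " variant, channels ",
      paste(x$config$channels, collapse = "/"), ", classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("trained ", x$config$epochs, " epochs on ", x$n_windows,
      " windows; final loss ", signif(utils::tail(x$loss_history, 1), 4),
      "\n", sep = "")
  invisible(x)
}

#' Predict window-level class probabilities
#'
#' @param object A fitted [tremor_gnn()] model.
#' @param windows A window tibble with a `features` list-column.
#' @param ... Unused.
#' @return The `windows` tibble (minus `features`) with one probability
#'   column per class (`.prob_<class>`) and the predicted class `.pred`.
#' @export
predict.tremor_gnn <- function(object, windows, ...) {
  X <- .stack_features(windows$features)
  hy <- .hyper(object$config, object$arch, training = FALSE)
  res <- net_run(X, integer(0), object$arch, object$params, object$state, hy)
  logits <- res$logits
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  colnames(P) <- paste0(".prob_", object$classes)
  out <- dplyr::select(tibble::as_tibble(windows), -dplyr::any_of("features"))
  out <- dplyr::bind_cols(out, tibble::as_tibble(P))
  out$.pred <- factor(object$classes[max.col(P, ties.method = "first")],
                      levels = object$classes)
  out
}

#' Extract spatial attention maps
#'
#' The attention value of joint j at frame t is the adjacency-weighted norm of
#' that joint's transformed contribution in the deepest attention layer; the
#' per-window aggregate is its temporal mean. This is the interpretability
#' output: on tremor recordings, attention concentrates on the tremulous
#' wrist(s).
#'
#' @param model A fitted `tremor_gnn` with attention weights (not the
#'   `"no_attention"` variant).
#' @param windows A window tibble.
#' @param per_frame If `TRUE`, also return frame-level values.
#' @return A tibble with one row per window and joint: identifying columns,
#'   `joint` and `attention` (temporal mean); with `per_frame = TRUE`,
#'   instead one row per window, frame and joint.
#' @export
extract_attention <- function(model, windows, per_frame = FALSE) {
  stopifnot(inherits(model, "tremor_gnn"))
  if (!model$arch$use_attention) {
    stop("the shared-weight (no_attention) variant has no attention maps",
         call. = FALSE)
  }
  X <- .stack_features(windows$features)
  hy <- .hyper(model$config, model$arch, training = FALSE, attention = TRUE)
  res <- net_run(X, integer(0), model$arch, model$params, model$state, hy)
  att <- res$attention
  Fw <- model$arch$Fw
  ids <- dplyr::select(
    tibble::as_tibble(windows),
    dplyr::any_of(c("subject_id", "video_id", "window_index", "label"))
  )
  J <- model$arch$J
  if (per_frame) {
    out <- ids[rep(seq_len(nrow(ids)), each = Fw * J), ]
    out$frame <- rep(rep(seq_len(Fw), times = J), times = nrow(ids))
    out$joint <- rep(rep(model$arch$joints, each = Fw), times = nrow(ids))
    out$attention <- as.vector(vapply(seq_len(nrow(ids)), function(w)
      att[(w - 1) * Fw + seq_len(Fw), ], matrix(0, Fw, J)))
    return(tibble::as_tibble(out))
  }
  agg <- vapply(seq_len(nrow(ids)), function(w)
    colMeans(att[(w - 1) * Fw + seq_len(Fw), , drop = FALSE]), numeric(J))
  out <- ids[rep(seq_len(nrow(ids)), each = J), ]
  out$joint <- rep(model$arch$joints, times = nrow(ids))
  out$attention <- as.vector(agg)
  tibble::as_tibble(out)
}
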