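# Helpers to exercise the compiled layers directly.
lcn_layer <- function(X, W, nb, av, c_in, c_out, shared = FALSE) {
  tremornet:::cpp_lcn_layer(X, W, lapply(nb, function(v) as.integer(v)),
                            av, c_in, c_out, shared)
}

test_that("the attention layer evaluates h_i = sum_j a_ij W_j^i x_j", {
  # 3-node path graph 1-2-3, 2 input/output channels, hand-set weights
  nb <- list(c(0, 1), c(0, 1, 2), c(1, 2))
  av <- list(c(0.5, 0.5), c(1 / 3, 1 / 3, 1 / 3), c(0.5, 0.5))
  set.seed(11)
  W <- lapply(nb, function(n) matrix(rnorm(length(n) * 2 * 2), length(n) * 2, 2))
  X <- matrix(rnorm(4 * 6), 4, 6)
  Z <- lcn_layer(X, W, nb, av, 2, 2)
  # independent dense evaluation
  for (i in 1:3) {
    want <- matrix(0, 4, 2)
    for (s in seq_along(nb[[i]])) {
      j <- nb[[i]][s] + 1
      Wb <- W[[i]][(s - 1) * 2 + 1:2, ]
      want <- want + av[[i]][s] * (X[, (j - 1) * 2 + 1:2] %*% Wb)
    }
    expect_equal(Z[, (i - 1) * 2 + 1:2], want, tolerance = 1e-12)
  }
})

test_that("degenerate attention-layer cases behave linearly", {
  # single node, identity weight, unit self-loop: layer is the identity
  X <- matrix(runif(10, 0, 1), 5, 2)
  Z <- lcn_layer(X, list(diag(2)), list(0), list(1), 2, 2)
  expect_equal(Z, X, ignore_attr = TRUE)
  # zero input features give zero output
  Z0 <- lcn_layer(matrix(0, 5, 2), list(diag(2)), list(0), list(1), 2, 2)
  expect_true(all(Z0 == 0))
})

test_that("PCSF fuses squeezed contributions as concatenation times W_i", {
  # 4-node path graph, C_in = 4, p = 0.5, q = 0.25
  hops <- floyd_warshall(rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                               c(0, 1, 0, 1), c(0, 0, 1, 0)))
  c_in <- 4
  set.seed(21)
  slot_src <- list(); S <- list(); Fm <- list()
  for (i in 1:4) {
    ord <- order(hops[i, ], 1:4)
    w <- squeeze_channels(hops[i, ord], c_in, 0.5, 0.25)
    slot_src[[i]] <- as.integer(ord - 1)
    S[[i]] <- lapply(w, function(wi) matrix(rnorm(c_in * wi), c_in, wi))
    Fm[[i]] <- matrix(rnorm(sum(w) * c_in), sum(w), c_in)
  }
  X <- matrix(rnorm(3 * 16), 3, 16)
  Y <- tremornet:::cpp_pcsf_layer(X, S, Fm, slot_src, c_in)
  # independent arithmetic: concatenate squeezed features, multiply by W_i
  for (i in 1:4) {
    parts <- lapply(seq_along(slot_src[[i]]), function(s) {
      j <- slot_src[[i]][s] + 1
      X[, (j - 1) * c_in + 1:c_in] %*% S[[i]][[s]]
    })
    want <- do.call(cbind, parts) %*% Fm[[i]]
    expect_equal(Y[, (i - 1) * c_in + 1:c_in], want, tolerance = 1e-12)
  }
  # zero input gives zero output (pure linearity, no bias)
  Y0 <- tremornet:::cpp_pcsf_layer(matrix(0, 2, 16), S, Fm, slot_src, c_in)
  expect_true(all(Y0 == 0))
})

test_that("PCSF weight shapes conserve the total squeezed width", {
  g <- skeleton_graph()
  cfg <- model_config(channels = c(8, 16))
  arch <- tremornet:::.build_arch(g, 2, cfg, "full")
  set.seed(1)
  params <- tremornet:::.init_params(arch)
  h <- hop_distances(g)
  for (i in seq_len(9)) {
    widths <- squeeze_channels(h[i, arch$slot_src[[i]] + 1], 16, cfg$p, cfg$q)
    expect_equal(vapply(params$S[[i]], ncol, integer(1)), widths)
    expect_equal(nrow(params$Fm[[i]]), sum(widths))
    expect_true(all(vapply(params$S[[i]], nrow, integer(1)) == 16))
  }
})

test_that("focal loss reduces to cross-entropy at gamma 0 and is exact on a toy", {
  probs <- matrix(c(0.7, 0.2, 0.1), 1)
  expect_equal(focal_loss(probs, 1, gamma = 2), (1 - 0.7)^2 * -log(0.7))
  set.seed(3)
  P <- matrix(runif(30), 10, 3); P <- P / rowSums(P)
  y <- sample(1:3, 10, TRUE)
  ce <- mean(-log(P[cbind(1:10, y)]))
  expect_equal(focal_loss(P, y, gamma = 0), ce, tolerance = 1e-12)
  # perfect prediction drives the loss to zero
  expect_lt(focal_loss(matrix(c(1 - 1e-9, 1e-9), 1), 1, gamma = 2), 1e-12)
})

test_that("the compiled focal loss agrees with the reference implementation", {
  g <- skeleton_graph()
  cfg <- model_config(channels = c(4, 6), window = 5, dropout = 0,
                      loss = "focal", focal_gamma = 2)
  arch <- tremornet:::.build_arch(g, 3, cfg, "full")
  set.seed(5)
  params <- tremornet:::.init_params(arch)
  state <- tremornet:::.init_state(arch)
  alpha <- c(1.2, 0.7, 1.1)
  hy <- tremornet:::.hyper(cfg, arch, training = FALSE, backward = FALSE,
                           alpha = alpha)
  X <- matrix(rnorm(3 * 5 * 27), 15, 27)
  y <- c(0L, 2L, 1L)
  res <- tremornet:::net_run(X, y, arch, params, state, hy)
  expect_equal(res$loss, focal_loss(res$prob, y + 1L, gamma = 2, alpha = alpha),
               tolerance = 1e-10)
})

test_that("compiled gradients match finite differences", {
  g <- skeleton_graph()
  cfg <- model_config(channels = c(3, 4), window = 4, dropout = 0)
  arch <- tremornet:::.build_arch(g, 2, cfg, "full")
  set.seed(7)
  params <- tremornet:::.init_params(arch)
  state <- tremornet:::.init_state(arch)
  hy <- tremornet:::.hyper(cfg, arch, training = TRUE, backward = TRUE)
  X <- matrix(rnorm(2 * 4 * 27), 8, 27)
  y <- c(0L, 1L)
  res <- tremornet:::net_run(X, y, arch, params, state, hy)
  skel <- params
  g_an <- unlist(res$grads[names(skel)], use.names = FALSE)
  theta <- unlist(params, use.names = FALSE)
  eps <- 1e-5
  idx <- sort(sample(length(theta), 40))
  g_num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    lp <- tremornet:::net_run(X, y, arch, utils::relist(tp, skel), state, hy)$loss
    tm <- theta; tm[i] <- tm[i] - eps
    lm <- tremornet:::net_run(X, y, arch, utils::relist(tm, skel), state, hy)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  rel <- abs(g_num - g_an[idx]) / pmax(1e-6, abs(g_num) + abs(g_an[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("evaluation is deterministic and batch-order independent", {
  cohort <- simulate_cohort(4, n_per_class = c(PT = 2, NT = 2), seed = 6,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  cfg <- model_config(channels = c(4, 8), epochs = 3, batch_size = 4, seed = 2)
  fit <- tremor_gnn(w, cfg)
  p1 <- predict(fit, w)
  # two identical windows produce identical logits
  dup <- w[c(1, 1), ]
  pd <- predict(fit, dup)
  expect_identical(pd[1, paste0(".prob_", fit$classes)],
                   pd[2, paste0(".prob_", fit$classes)])
  # permuting the batch leaves per-window probabilities unchanged
  perm <- rev(seq_len(nrow(w)))
  p2 <- predict(fit, w[perm, ])
  expect_equal(p2$.prob_PT, p1$.prob_PT[perm], tolerance = 1e-12)
  # logits dimension equals the number of classes
  expect_length(grep("^\\.prob_", names(p1)), 2)
})

test_that("refitting with the same seed reproduces the model exactly", {
  cohort <- simulate_cohort(4, n_per_class = c(PT = 2, NT = 2), seed = 6,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  cfg <- model_config(channels = c(4, 8), epochs = 3, batch_size = 4, seed = 5)
  f1 <- tremor_gnn(w, cfg)
  f2 <- tremor_gnn(w, cfg)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$loss_history, f2$loss_history)
})

test_that("training loss decreases on an easy separable cohort", {
  cohort <- simulate_cohort(8, n_per_class = c(PT = 4, NT = 4), seed = 9,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  fit <- tremor_gnn(w, model_config(channels = c(8, 16), epochs = 30,
                                    batch_size = 8, seed = 1))
  expect_lt(mean(tail(fit$loss_history, 5)), mean(head(fit$loss_history, 5)))
})

test_that("the forward pass validates input shape and joint count", {
  cohort <- simulate_cohort(2, n_per_class = c(PT = 1, NT = 1), seed = 3,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  fit <- tremor_gnn(w, model_config(channels = c(4, 8), epochs = 1,
                                    batch_size = 2, seed = 1))
  bad <- w
  bad$features <- lapply(bad$features, function(a) a[, 1:5, ])
  expect_error(predict(fit, bad), "columns|features")
  expect_error(extract_attention(tremor_gnn(w, model_config(channels = c(4, 8),
    epochs = 1, batch_size = 2, seed = 1), variant = "no_attention"), w),
    "no_attention|shared-weight")
})

test_that("attention aggregates are the temporal mean of per-frame values", {
  cohort <- simulate_cohort(2, n_per_class = c(PT = 1, NT = 1), seed = 12,
                            duration = 4, occlusion_rate = 0)
  w <- window_dataset(cohort)
  fit <- tremor_gnn(w, model_config(channels = c(4, 8), epochs = 2,
                                    batch_size = 2, seed = 1))
  agg <- extract_attention(fit, w)
  pf <- extract_attention(fit, w, per_frame = TRUE)
  chk <- dplyr::summarise(
    dplyr::group_by(pf, .data$video_id, .data$window_index, .data$joint),
    attention = mean(attention), .groups = "drop"
  )
  merged <- dplyr::left_join(
    agg, chk, by = c("video_id", "window_index", "joint"),
    suffix = c("", ".pf")
  )
  expect_equal(merged$attention, merged$attention.pf, tolerance = 1e-12)
})
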