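# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @export
tidy.tremor_loocv <- function(x, ...) {
  x$video_predictions
}

#' @export
glance.tremor_loocv <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_folds = nrow(x$fold_metrics),
    n_videos = nrow(x$video_predictions),
    accuracy = x$metrics$accuracy,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    f1 = x$metrics$f1
  )
}

#' @export
tidy.tremor_gnn <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @export
glance.tremor_gnn <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    channels = paste(x$config$channels, collapse = "/"),
    epochs = x$config$epochs,
    n_windows = x$n_windows,
    final_loss = utils::tail(x$loss_history, 1)
  )
}

#' @export
tidy.tremor_metrics <- function(x, ...) {
  x$per_class
}

#' @export
glance.tremor_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, f1 = x$f1)
}

#' @export
autoplot.tremor_gnn <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = paste("training loss,", object$variant, "variant")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tremor_loocv <- function(object, ...) {
  cm <- as.data.frame(object$metrics$confusion)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = "video-level confusion (leave-one-subject-out)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot aggregate joint attention
#'
#' Bar chart of mean attention per joint, the cohort-level interpretability
#' view: on tremor cohorts the tremulous wrist(s) dominate.
#'
#' @param attention An attention tibble from [extract_attention()] or the
#'   `attention` element of [run_loocv()].
#' @return A ggplot object.
#' @export
plot_attention <- function(attention) {
  agg <- attention |>
    dplyr::group_by(.data$joint) |>
    dplyr::summarise(attention = mean(.data$attention), .groups = "drop") |>
    dplyr::mutate(joint = factor(.data$joint, levels = upper_body_joints()))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$joint, y = .data$attention)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean attention",
                  title = "aggregate skeleton-joint attention") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
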