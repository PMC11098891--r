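# The synthetic recovery benchmark: a balanced PT/NT cohort run end-to-end
# through preprocessing, subject-wise leave-one-out training and voting.
# This is the package's desk-scale validation experiment; the methods
# vignette documents the problem sizes.

#' Run the synthetic tremor-recovery benchmark
#'
#' Generates a balanced cohort of unilateral-PT and tremor-free subjects with
#' [simulate_cohort()] (generator defaults), builds torso-scaled windows and
#' evaluates the network by subject-wise leave-one-out cross-validation. For
#' attention-bearing variants the held-out attention maps are scored for
#' wrist localization: the fraction of PT folds in which the affected wrist
#' ranks among the top-2 joints by aggregate attention.
#'
#' @param seed Integer seed; controls both the cohort (derived seed) and the
#'   training runs.
#' @param variant Architecture variant, see [tremor_gnn()].
#' @param n_subjects Cohort size (half PT, half NT).
#' @param config A [model_config()]; defaults to [benchmark_config()].
#' @return A list of class `tremor_benchmark`: the `loocv` result, the
#'   `cohort` metadata (without poses), `metrics` (glance row) and
#'   `wrist_top2` (proportion in \[0, 1\], `NA` for the no-attention variant).
#' @export
run_tremor_benchmark <- function(seed = 1L, variant = "full", n_subjects = 30,
                                 config = benchmark_config(seed = seed)) {
  half <- n_subjects %/% 2
  cohort <- simulate_cohort(
    n_subjects, n_per_class = c(PT = half, NT = n_subjects - half),
    seed = 100L + as.integer(seed)
  )
  windows <- window_dataset(cohort, mode = "type-binary", scale = "torso")
  res <- run_loocv(windows, config, variant = variant)

  wrist_top2 <- NA_real_
  if (!is.null(res$attention)) {
    meta <- dplyr::distinct(
      cohort[, c("subject_id", "class", "affected_side")]
    )
    agg <- res$attention |>
      dplyr::group_by(.data$subject_id, .data$joint) |>
      dplyr::summarise(attention = mean(.data$attention), .groups = "drop")
    top2 <- agg |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_max(.data$attention, n = 2, with_ties = FALSE) |>
      dplyr::summarise(top = list(.data$joint), .groups = "drop") |>
      dplyr::left_join(meta, by = "subject_id") |>
      dplyr::filter(.data$class == "PT")
    hits <- mapply(function(top, side) paste0(side, "_wrist") %in% top,
                   top2$top, top2$affected_side)
    wrist_top2 <- mean(hits)
  }

  structure(list(
    loocv = res,
    cohort = dplyr::select(cohort, -"pose"),
    metrics = glance(res),
    wrist_top2 = wrist_top2,
    seed = seed, variant = variant
  ), class = "tremor_benchmark")
}

#' @export
print.tremor_benchmark <- function(x, ...) {
  cat("<tremor_benchmark> seed ", x$seed, ", ", x$variant, " variant\n", sep = "")
  print(x$loocv$metrics)
  if (!is.na(x$wrist_top2)) {
    cat(sprintf("affected wrist in top-2 attention joints: %.0f%% of PT folds\n",
                100 * x$wrist_top2))
  }
  invisible(x)
}
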