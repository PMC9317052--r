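#' Pixel confusion counts between a predicted and a true mask
#'
#' @param pred_mask,truth_mask Binary matrices of identical shape.
#' @return Named numeric `(TP, FP, FN, TN)`; the four counts sum to the pixel
#'   count.
#' @examples
#' confusion_counts(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
#' @export
confusion_counts <- function(pred_mask, truth_mask) {
  p <- check_mask(pred_mask, "pred_mask")
  t <- check_mask(truth_mask, "truth_mask")
  if (!all(dim(p) == dim(t))) abort_input("mask shapes differ")
  c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
    FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0))
}

#' Tumor accuracy (sensitivity on tumor pixels), in percent
#'
#' `100 * TP / (TP + FN)`: the fraction of true tumor pixels that the
#' segmentation recovers.
#'
#' @param counts Named counts from [confusion_counts()] (or a list of masks
#'   `(pred, truth)`).
#' @return Percentage in `[0, 100]`.
#' @export
tumor_accuracy <- function(counts) {
  if (counts[["TP"]] + counts[["FN"]] == 0)
    abort_metric("no tumor pixels in the truth: tumor accuracy is undefined")
  100 * counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
}

#' Dice score between predicted and true tumor masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)` over tumor pixels.
#'
#' @param pred_mask,truth_mask Binary masks.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(pred_mask, truth_mask) {
  cts <- confusion_counts(pred_mask, truth_mask)
  if (cts[["TP"]] + cts[["FP"]] + cts[["FN"]] == 0)
    abort_metric("both masks are empty: dice is undefined")
  unname(2 * cts[["TP"]] / (2 * cts[["TP"]] + cts[["FP"]] + cts[["FN"]]))
}

#' Jaccard index between predicted and true tumor masks
#'
#' `|X intersect Y| / |X union Y|`; related to dice by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return Fraction in `[0, 1]`.
#' @export
jaccard <- function(pred_mask, truth_mask) {
  cts <- confusion_counts(pred_mask, truth_mask)
  u <- cts[["TP"]] + cts[["FP"]] + cts[["FN"]]
  if (u == 0) abort_metric("both masks are empty: Jaccard is undefined")
  unname(cts[["TP"]] / u)
}

metrics_from_counts <- function(cts) {
  tp <- cts[["TP"]]; fp <- cts[["FP"]]; fn <- cts[["FN"]]; tn <- cts[["TN"]]
  tibble::tibble(
    tumor_accuracy = 100 * tp / (tp + fn),
    dice = 2 * tp / (2 * tp + fp + fn),
    jaccard = tp / (tp + fp + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    false_positive_rate = 100 * fp / (fp + tn))
}

# column-normalized (predicted x true) confusion percentages
confusion_percent <- function(cts) {
  m <- matrix(c(cts[["TP"]], cts[["FN"]], cts[["FP"]], cts[["TN"]]), 2, 2,
              dimnames = list(predicted = c("tumor", "non_tumor"),
                              true = c("tumor", "non_tumor")))
  sweep(m, 2, colSums(m), "/") * 100
}

#' Evaluate one trained model on a patient-separated test set
#'
#' Counts are pooled over every test pixel (micro-average); `per_slice = TRUE`
#' instead averages per-slice metrics, excluding slices whose truth mask is
#' empty from tumor accuracy, dice and Jaccard (they are undefined there)
#' while keeping them in specificity and false-positive rate.
#'
#' @param net A trained `msunet`.
#' @param test_set Slice tibble with ground-truth `mask`s; must not share
#'   patients with the model's training set.
#' @param per_slice Macro-average over slices instead of pixel pooling.
#' @return One-row tibble of metrics plus the pooled counts.
#' @export
evaluate_model <- function(net, test_set, per_slice = FALSE) {
  train_pat <- net$provenance$train_patients
  leak <- intersect(unique(test_set$patient_id),
                    c(train_pat, net$provenance$transfer_patients))
  if (length(leak) > 0)
    abort_input(sprintf("test set shares patients with training: %s",
                        paste(leak, collapse = ", ")))
  preds <- predict_slices(net, test_set)
  counts <- purrr::map(seq_len(nrow(preds)),
                       ~ confusion_counts(preds$pred_mask[[.x]],
                                          preds$mask[[.x]]))
  pooled <- Reduce(`+`, counts)
  if (!per_slice) {
    out <- metrics_from_counts(pooled)
  } else {
    per <- purrr::map(counts, function(ct) {
      m <- metrics_from_counts(ct)
      if (ct[["TP"]] + ct[["FN"]] == 0)
        m$tumor_accuracy <- m$dice <- m$jaccard <- m$sensitivity <- NA_real_
      m
    }) |> dplyr::bind_rows()
    out <- dplyr::summarise(per, dplyr::across(dplyr::everything(),
                                               ~ mean(.x, na.rm = TRUE)))
  }
  out$TP <- pooled[["TP"]]; out$FP <- pooled[["FP"]]
  out$FN <- pooled[["FN"]]; out$TN <- pooled[["TN"]]
  out
}

#' Aggregate per-run metrics into a report with across-run mean and spread
#'
#' @param runs Tibble of per-run metric rows (from [evaluate_model()]), or a
#'   list of trained models evaluated against `test_set`.
#' @param test_set Optional slice tibble; required when `runs` is a model
#'   list.
#' @param per_slice Passed to [evaluate_model()].
#' @return A `metrics_report`: per-metric mean and population standard
#'   deviation across runs, the pooled column-normalized confusion matrix of
#'   the first run, and `n_runs`.
#' @export
evaluate_runs <- function(runs, test_set = NULL, per_slice = FALSE) {
  if (!is.data.frame(runs)) {
    stopifnot(!is.null(test_set))
    runs <- purrr::map(runs, evaluate_model, test_set = test_set,
                       per_slice = per_slice) |> dplyr::bind_rows()
  }
  if (nrow(runs) == 0) abort_input("no runs to aggregate")
  metric_cols <- setdiff(names(runs), c("TP", "FP", "FN", "TN", "run"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summ <- tidyr::pivot_longer(runs[metric_cols], dplyr::everything(),
                              names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = pop_sd(.data$value)) |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_cols)) |>
    dplyr::arrange(.data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
  conf <- if (all(c("TP", "FP", "FN", "TN") %in% names(runs))) {
    confusion_percent(c(TP = mean(runs$TP), FP = mean(runs$FP),
                        FN = mean(runs$FN), TN = mean(runs$TN)))
  } else NULL
  structure(list(summary = summ, confusion = conf, n_runs = nrow(runs),
                 per_run = runs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d run(s)\n", x$n_runs))
  print(as.data.frame(x$summary), row.names = FALSE)
  if (!is.null(x$confusion)) {
    cat("column-normalized confusion (%), predicted x true:\n")
    print(round(x$confusion, 2))
  }
  invisible(x)
}

#' @rdname evaluate_runs
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$summary

#' @rdname evaluate_runs
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary[, c("metric", "mean")],
                             names_from = "metric", values_from = "mean")
  dplyr::mutate(wide, n_runs = x$n_runs)
}

#' Weak-versus-full supervision degradation report
#'
#' Signed per-metric differences (weak minus fully supervised), with the
#' across-run standard deviations combined in quadrature (an approximation
#' that treats the two protocols' runs as independent).
#'
#' @param weak,full `metrics_report`s obtained under the same test protocol.
#' @return Tibble with one row per metric: weak and full means, `degradation`
#'   (weak - full) and `degradation_sd`.
#' @export
degradation_report <- function(weak, full) {
  stopifnot(inherits(weak, "metrics_report"), inherits(full, "metrics_report"))
  if (!identical(weak$summary$metric, full$summary$metric))
    abort_input("the two reports measure different metric sets")
  lead <- c("tumor_accuracy", "dice")
  ord <- c(intersect(lead, weak$summary$metric),
           setdiff(weak$summary$metric, lead))
  tibble::tibble(metric = weak$summary$metric,
                 weak_mean = weak$summary$mean, weak_sd = weak$summary$sd,
                 full_mean = full$summary$mean, full_sd = full$summary$sd,
                 degradation = weak$summary$mean - full$summary$mean,
                 degradation_sd = sqrt(weak$summary$sd^2 + full$summary$sd^2)) |>
    dplyr::arrange(match(.data$metric, ord))
}
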