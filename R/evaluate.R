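# k-fold evaluation harness and accuracy reporting.

#' Per-subject evaluation report
#'
#' Holds per-fold accuracies (percent) with their mean and sample standard
#' deviation. Can be built directly from fold accuracies (e.g. published
#' values) or via [evaluate_kfold()].
#'
#' @param per_fold_accuracy Numeric vector of fold accuracies in `[0, 100]`.
#' @param subject_id Label for the report.
#' @return An `eval_report`.
#' @examples
#' r <- eval_report(c(95, 100, 90), subject_id = "demo")
#' glance(r)
#' @export
eval_report <- function(per_fold_accuracy, subject_id = "subject") {
  mp_assert(length(per_fold_accuracy) >= 1 && all(is.finite(per_fold_accuracy)),
            "fold accuracies must be finite", "parameter")
  mp_assert(all(per_fold_accuracy >= 0 & per_fold_accuracy <= 100),
            "fold accuracies must be percentages in [0, 100]", "parameter")
  acc <- as.numeric(per_fold_accuracy)
  structure(list(per_fold_accuracy = acc,
                 mean = mean(acc),
                 std = if (length(acc) > 1) sd(acc) else 0,
                 subject_id = subject_id),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: %d folds, mean %.2f%%, std %.2f\n", x$subject_id,
              length(x$per_fold_accuracy), x$mean, x$std))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id,
                 fold = seq_along(x$per_fold_accuracy),
                 accuracy = x$per_fold_accuracy)
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, mean = x$mean, std = x$std,
                 k = length(x$per_fold_accuracy))
}

#' k-fold evaluation of a trained CNN
#'
#' Partitions the test set into `k` contiguous, nearly equal parts (any
#' remainder goes to the first parts). For each part, the model's accuracy
#' is computed under every stored per-epoch checkpoint and, in `"max"`
#' mode, the maximum over epochs is reported (the optimistic protocol of
#' picking the best epoch per fold); `"plain"` mode scores the final
#' parameters only.
#'
#' @param model A trained `cnn_model`.
#' @param test_set An [image_set()] with at least `k` samples.
#' @param k Number of folds (>= 2).
#' @param mode `"max"` or `"plain"`.
#' @param subject_id Label carried into the report.
#' @return An [eval_report()] with accuracies in percent.
#' @export
evaluate_kfold <- function(model, test_set, k = 10, mode = c("max", "plain"),
                           subject_id = "synthetic") {
  mode <- match.arg(mode)
  mp_assert(inherits(model, "cnn_model"), "model must be a cnn_model", "parameter")
  mp_assert(inherits(test_set, "image_set"), "test_set must be an image_set", "parameter")
  if (!is_count(k) || k < 2) mp_abort("k must be an integer >= 2", "parameter")
  n <- ncol(test_set$x)
  if (n < k) mp_abort(sprintf("test set has %d samples but k = %d", n, k), "parameter")
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  bounds <- cumsum(sizes)
  starts <- c(1L, head(bounds, -1) + 1L)
  param_sets <- if (mode == "max" && length(model$checkpoints)) model$checkpoints
                else list(model$params)
  correct <- vapply(param_sets, function(p) {
    predict(model, test_set, type = "class", params = p) == test_set$y
  }, logical(n))
  per_fold <- vapply(seq_len(k), function(f) {
    idx <- starts[f]:bounds[f]
    accs <- colMeans(correct[idx, , drop = FALSE])
    if (mode == "max") max(accs) else accs[length(accs)]
  }, numeric(1))
  eval_report(per_fold * 100, subject_id = subject_id)
}

#' Pool evaluation reports
#'
#' The overall mean is the mean of all per-fold accuracies pooled across
#' reports; the overall standard deviation is the mean of the per-report
#' sample standard deviations. Values are kept at full precision; the print
#' method displays two decimals.
#'
#' @param reports A list of [eval_report()] objects (or a single one).
#' @return An `eval_summary`: `mean`, `std`, `n_reports`, `n_folds`, plus
#'   two-decimal display strings `display_mean` / `display_std`.
#' @export
summarize_report <- function(reports) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  if (!length(reports) || !all(vapply(reports, inherits, logical(1), "eval_report"))) {
    mp_abort("reports must be a nonempty list of eval_report objects", "parameter")
  }
  pooled <- unlist(lapply(reports, `[[`, "per_fold_accuracy"))
  stds <- vapply(reports, `[[`, numeric(1), "std")
  m <- mean(pooled); s <- mean(stds)
  structure(list(mean = m, std = s,
                 display_mean = formatC(round(m, 2), format = "f", digits = 2),
                 display_std = formatC(round(s, 2), format = "f", digits = 2),
                 n_reports = length(reports), n_folds = length(pooled)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %d reports, %d folds: mean %s%%, std %s\n",
              x$n_reports, x$n_folds, x$display_mean, x$display_std))
  invisible(x)
}

#' @export
glance.eval_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, std = x$std, n_reports = x$n_reports,
                 n_folds = x$n_folds)
}

#' Write reports as a cross-validation table
#'
#' One row per report with fold columns `k=1..k`, then `Average` and `Std`,
#' plus a final pooled `Average` row. All accuracies are printed with two
#' decimals, so identical reports always produce byte-identical files.
#'
#' @param reports List of [eval_report()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_reports <- function(reports, path) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  mp_assert(length(reports) >= 1, "need at least one report", "parameter")
  kmax <- max(vapply(reports, function(r) length(r$per_fold_accuracy), integer(1)))
  fmt <- function(x) formatC(round(x, 2), format = "f", digits = 2)
  rows <- lapply(reports, function(r) {
    folds <- rep(NA_character_, kmax)
    folds[seq_along(r$per_fold_accuracy)] <- fmt(r$per_fold_accuracy)
    c(Subject = r$subject_id, stats::setNames(folds, paste0("k=", seq_len(kmax))),
      Average = fmt(r$mean), Std = fmt(r$std))
  })
  s <- summarize_report(reports)
  rows <- c(rows, list(c(Subject = "Average",
                         stats::setNames(rep("", kmax), paste0("k=", seq_len(kmax))),
                         Average = s$display_mean, Std = s$display_std)))
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
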