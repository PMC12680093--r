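#' Prediction sets from patient-level cross-validation
#'
#' A prediction set is a tibble with one row per patient: `patient_id`,
#' `true` and `pred` labels in `{0, 1, 2}` (normal, benign, malignant) and
#' optionally `fold`. It is the input to every statistic in the package.
#'
#' @param patient_id Character vector of unique patient ids.
#' @param true,pred Integer labels in `0..(n_classes - 1)`.
#' @param fold Optional fold identifiers.
#' @param n_classes Number of classes (default 3).
#' @return A `prediction_set` tibble.
#' @export
prediction_set <- function(patient_id, true, pred, fold = NULL,
                           n_classes = 3L) {
  patient_id <- as.character(patient_id)
  true <- as.integer(true); pred <- as.integer(pred)
  if (anyDuplicated(patient_id))
    stop("patient_ids must be unique", call. = FALSE)
  if (any(true < 0 | true >= n_classes) || any(pred < 0 | pred >= n_classes))
    stop("labels must be in 0..", n_classes - 1, call. = FALSE)
  out <- tibble::tibble(patient_id = patient_id, true = true, pred = pred)
  if (!is.null(fold)) out$fold <- fold
  attr(out, "n_classes") <- as.integer(n_classes)
  class(out) <- c("prediction_set", class(out))
  out
}

pred_n_classes <- function(preds) {
  nc <- attr(preds, "n_classes")
  if (is.null(nc)) 3L else nc
}

#' Read / write prediction CSV files
#'
#' The on-disk format is a plain CSV with columns
#' `patient_id,true,pred` (plus optional `fold`), so predictions from
#' external models can be compared without re-running them here.
#'
#' @param path CSV path.
#' @return `read_predictions()` returns a `prediction_set`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "true", "pred")
  if (!all(req %in% names(df)))
    stop("prediction file needs columns patient_id,true,pred", call. = FALSE)
  prediction_set(df$patient_id, df$true, df$pred,
                 fold = if ("fold" %in% names(df)) df$fold else NULL)
}

#' @param preds A `prediction_set`.
#' @rdname read_predictions
#' @export
write_predictions <- function(preds, path) {
  utils::write.csv(as.data.frame(preds), path, row.names = FALSE)
  invisible(path)
}

confusion_from_labels <- function(true, pred, n_classes) {
  m <- matrix(tabulate(n_classes * true + pred + 1L, n_classes * n_classes),
              n_classes, n_classes, byrow = TRUE)
  m
}

#' Confusion matrix of a prediction set
#'
#' @param preds A [prediction_set()].
#' @return A `confusion_matrix`: integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(preds) {
  if (nrow(preds) == 0L) stop("empty prediction set", call. = FALSE)
  nc <- pred_n_classes(preds)
  m <- confusion_from_labels(preds$true, preds$pred, nc)
  lab <- if (nc == 3L) c("normal", "benign", "malignant")
         else as.character(seq_len(nc) - 1L)
  dimnames(m) <- list(true = lab, predicted = lab)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

as_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  cm
}

per_class_stats <- function(cm) {
  cm <- as_confusion(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sen <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spe <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  f1 <- ifelse(tp + fn > 0, 2 * tp / pmax(2 * tp + fp + fn, 1), NA_real_)
  tibble::tibble(class = if (!is.null(rownames(cm))) rownames(cm)
                 else as.character(seq_along(tp) - 1L),
                 support = as.integer(tp + fn),
                 sensitivity = 100 * sen, specificity = 100 * spe,
                 f1 = 100 * f1)
}

#' Accuracy and macro-averaged one-vs-rest metrics
#'
#' Computes overall accuracy plus per-class one-vs-rest sensitivity,
#' specificity and F1, aggregated as unweighted macro averages (all in
#' percent). A class absent from the truth has undefined sensitivity/F1 and
#' is excluded from the macro mean, with `flags` recording the exclusion.
#'
#' @param cm A [confusion()] matrix (or any square count matrix).
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `f1`
#'   (macro, percent), `per_class` (tibble) and `flags` (character).
#' @export
macro_metrics <- function(cm) {
  cm <- as_confusion(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations", call. = FALSE)
  pc <- per_class_stats(cm)
  flags <- character()
  if (anyNA(pc$sensitivity))
    flags <- c(flags, paste0("class(es) absent from truth excluded from ",
                             "macro sensitivity/F1: ",
                             paste(pc$class[is.na(pc$sensitivity)],
                                   collapse = ", ")))
  if (anyNA(pc$specificity))
    flags <- c(flags, "class covering all truth excluded from specificity")
  structure(list(accuracy = 100 * sum(diag(cm)) / total,
                 sensitivity = mean(pc$sensitivity, na.rm = TRUE),
                 specificity = mean(pc$specificity, na.rm = TRUE),
                 f1 = mean(pc$f1, na.rm = TRUE),
                 per_class = pc, flags = flags),
            class = "macro_metrics")
}

#' Cohen's kappa of a confusion matrix, in percent
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with
#' `po = trace / total` and `pe = sum(row_i * col_i) / total^2`. The
#' degenerate case `pe = 1` (all mass in one row/column pattern) is defined
#' as 0 and flagged via the `"flag"` attribute.
#'
#' @param cm A [confusion()] matrix.
#' @return Numeric scalar (percent).
#' @export
cohen_kappa <- function(cm) {
  cm <- as_confusion(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations", call. = FALSE)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) return(structure(0, flag = "pe = 1; kappa defined as 0"))
  100 * (po - pe) / (1 - pe)
}

stat_fun <- function(statistic, n_classes) {
  switch(statistic,
         macro_f1 = function(true, pred) {
           cm <- confusion_from_labels(true, pred, n_classes)
           tp <- diag(cm); fn <- rowSums(cm) - tp; fp <- colSums(cm) - tp
           f1 <- ifelse(tp + fn > 0, 2 * tp / pmax(2 * tp + fp + fn, 1),
                        NA_real_)
           100 * mean(f1, na.rm = TRUE)
         },
         kappa = function(true, pred) {
           cm <- confusion_from_labels(true, pred, n_classes)
           total <- sum(cm)
           po <- sum(diag(cm)) / total
           pe <- sum(rowSums(cm) * colSums(cm)) / total^2
           if (pe >= 1) 0 else 100 * (po - pe) / (1 - pe)
         },
         stop("statistic must be 'macro_f1' or 'kappa'", call. = FALSE))
}

new_bootstrap_summary <- function(statistic, stats, full_sample, B, seed,
                                  paired = FALSE) {
  ci <- unname(stats::quantile(stats, c(0.025, 0.975)))
  structure(list(statistic = statistic,
                 point = mean(stats),
                 full_sample = full_sample,
                 ci_low = ci[1], ci_high = ci[2],
                 resample_min = min(stats), resample_max = max(stats),
                 n_resamples = B, seed = seed,
                 excludes_zero = if (paired) ci[1] > 0 || ci[2] < 0 else NA),
            class = "bootstrap_summary")
}

#' Percentile bootstrap confidence interval for a prediction statistic
#'
#' Draws `B` resamples (with replacement, size `n`) of the patient records,
#' computes the statistic on each, and reports the mean of the bootstrap
#' distribution as the point estimate with the 2.5th/97.5th percentiles as
#' the 95% interval. The resampling unit is the patient record (one
#' prediction per patient under leave-one-out cross-validation).
#'
#' @param preds A [prediction_set()].
#' @param statistic `"macro_f1"` or `"kappa"`.
#' @param B Number of resamples; default 10000.
#' @param seed Integer seed (bit-for-bit reproducible).
#' @return A `bootstrap_summary` (see [tidy.bootstrap_summary()]).
#' @export
bootstrap_ci <- function(preds, statistic = c("macro_f1", "kappa"),
                         B = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  n <- nrow(preds)
  f <- stat_fun(statistic, pred_n_classes(preds))
  true <- preds$true; pred <- preds$pred
  stats <- with_local_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      f(true[idx], pred[idx])
    }, numeric(1))
  })
  new_bootstrap_summary(statistic, stats, f(true, pred), B, seed)
}

#' Paired bootstrap CI for the difference between two models
#'
#' Each resample draws one index multiset and applies it to both prediction
#' sets, so the statistic difference is computed on matched resamples; the
#' interval excluding zero is evidence that model `a` genuinely outperforms
#' model `b`. Both sets must cover the same patients.
#'
#' @param preds_a,preds_b [prediction_set()]s over identical `patient_id`s
#'   (`preds_b` is aligned to `preds_a`'s order).
#' @inheritParams bootstrap_ci
#' @return A `bootstrap_summary` with `excludes_zero` set.
#' @export
paired_diff_ci <- function(preds_a, preds_b,
                           statistic = c("macro_f1", "kappa"),
                           B = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (!setequal(preds_a$patient_id, preds_b$patient_id) ||
      nrow(preds_a) != nrow(preds_b))
    stop("prediction sets must cover the same patient_ids", call. = FALSE)
  ord <- match(preds_a$patient_id, preds_b$patient_id)
  true_a <- preds_a$true; pred_a <- preds_a$pred
  true_b <- preds_b$true[ord]; pred_b <- preds_b$pred[ord]
  n <- nrow(preds_a)
  f <- stat_fun(statistic, pred_n_classes(preds_a))
  stats <- with_local_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      f(true_a[idx], pred_a[idx]) - f(true_b[idx], pred_b[idx])
    }, numeric(1))
  })
  new_bootstrap_summary(statistic, stats,
                        f(true_a, pred_a) - f(true_b, pred_b), B, seed,
                        paired = TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for evaluation objects
#'
#' `tidy()` returns one row per reported quantity; `glance()` a one-row
#' summary.
#'
#' @param x A `bootstrap_summary` or `macro_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bootstrap_summary <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, point = x$point,
                 full_sample = x$full_sample,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_resamples = x$n_resamples, seed = x$seed,
                 excludes_zero = x$excludes_zero)
}

#' @rdname tidy.bootstrap_summary
#' @export
tidy.macro_metrics <- function(x, ...) x$per_class

#' @rdname tidy.bootstrap_summary
#' @export
glance.macro_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, f1 = x$f1)
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("%s: %.2f%% (95%% CI %.2f, %.2f), B = %d\n", x$statistic,
              x$point, x$ci_low, x$ci_high, x$n_resamples))
  if (!is.na(x$excludes_zero))
    cat("difference CI excludes zero:", x$excludes_zero, "\n")
  invisible(x)
}

#' @export
print.macro_metrics <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  F1 %.2f%% (macro)\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  print(x$per_class)
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}

#' Full evaluation report of a prediction set
#'
#' Bundles the confusion matrix, per-class and macro metrics, Cohen's kappa
#' and bootstrap summaries for macro F1 and kappa; optionally the paired
#' differences against a second model's predictions. `write_report()`
#' serializes it to JSON.
#'
#' @param preds A [prediction_set()].
#' @param against Optional second `prediction_set` for paired differences.
#' @param B,seed Bootstrap settings.
#' @return A named list (report).
#' @export
eval_report <- function(preds, against = NULL, B = 10000L, seed = 1L) {
  cm <- confusion(preds)
  mm <- macro_metrics(cm)
  rep <- list(
    n = nrow(preds),
    confusion = unclass(cm),
    accuracy = mm$accuracy, sensitivity = mm$sensitivity,
    specificity = mm$specificity, f1 = mm$f1,
    per_class = mm$per_class,
    kappa = as.numeric(cohen_kappa(cm)),
    bootstrap = list(macro_f1 = tidy(bootstrap_ci(preds, "macro_f1", B, seed)),
                     kappa = tidy(bootstrap_ci(preds, "kappa", B, seed)))
  )
  if (!is.null(against)) {
    rep$paired_diff <- list(
      macro_f1 = tidy(paired_diff_ci(preds, against, "macro_f1", B, seed)),
      kappa = tidy(paired_diff_ci(preds, against, "kappa", B, seed)))
  }
  rep
}

#' @param report An [eval_report()] result.
#' @param path Output JSON path.
#' @rdname eval_report
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = true, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true")
}
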