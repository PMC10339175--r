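prob_cols <- function(preds) {
  grep("^prob_", names(preds), value = TRUE)
}

#' Average-pooling slide-level aggregation
#'
#' Pools a slide's patch-level class-probability vectors by their
#' unweighted arithmetic mean and predicts the argmax class (ties broken
#' by lowest class index, deterministically).
#'
#' @param patch_preds data.frame of one slide's rows from
#'   [predict_patches()] (all sharing one slide_id).
#' @return one-row data.frame with slide_id, true_label, pooled
#'   probability columns and \code{predicted_label}.
#' @export
aggregate_slide <- function(patch_preds) {
  if (nrow(patch_preds) == 0) stop("no patches to aggregate",
                                   call. = FALSE)
  if (length(unique(patch_preds$slide_id)) != 1) {
    stop("aggregate_slide expects patches from a single slide",
         call. = FALSE)
  }
  pc <- prob_cols(patch_preds)
  pooled <- colMeans(patch_preds[, pc, drop = FALSE])
  classes <- sub("^prob_", "", pc)
  out <- data.frame(slide_id = patch_preds$slide_id[1],
                    true_label = patch_preds$true_label[1],
                    stringsAsFactors = FALSE)
  out[pc] <- as.list(pooled)
  out$predicted_label <- classes[which.max(pooled)]
  out
}

#' Aggregate patch predictions for every slide
#'
#' @param preds full prediction data.frame from [predict_patches()].
#' @return data.frame with one row per slide (see [aggregate_slide()]).
#' @export
aggregate_slides <- function(preds) {
  out <- do.call(rbind, lapply(split(preds, preds$slide_id),
                               aggregate_slide))
  rownames(out) <- NULL
  out
}

## rank-based (Mann-Whitney) AUC for one class vs the rest; average ranks
## handle ties
auc_binary <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Accuracy, macro F1 and macro one-vs-rest AUC
#'
#' Accuracy is the fraction of argmax-correct items (lowest-index
#' tie-break); F1 is macro-averaged over the classes present in the truth
#' (a class with no predicted and no true positives contributes 0); AUC is
#' the macro average of one-vs-rest rank-based AUCs.
#'
#' @param true_labels character/factor vector.
#' @param probs matrix or data.frame of class probabilities; column names
#'   (optionally prefixed \code{prob_}) give the class order.
#' @return named numeric vector \code{(accuracy, f1, auc)}.
#' @export
compute_metrics <- function(true_labels, probs) {
  probs <- as.matrix(probs)
  classes <- sub("^prob_", "", colnames(probs))
  true_labels <- as.character(true_labels)
  if (!all(true_labels %in% classes)) {
    stop("true labels outside the probability columns", call. = FALSE)
  }
  pred <- classes[max.col(probs, ties.method = "first")]
  acc <- mean(pred == true_labels)
  present <- intersect(classes, unique(true_labels))
  f1s <- vapply(present, function(cl) {
    tp <- sum(pred == cl & true_labels == cl)
    fp <- sum(pred == cl & true_labels != cl)
    fn <- sum(pred != cl & true_labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  if (length(present) < 2) {
    stop("AUC undefined: fewer than 2 classes present in the truth ",
         sprintf("(accuracy = %.4f, macro F1 = %.4f)", acc, mean(f1s)),
         call. = FALSE)
  }
  aucs <- vapply(present, function(cl) {
    auc_binary(probs[, which(classes == cl)], true_labels == cl)
  }, numeric(1))
  c(accuracy = acc, f1 = mean(f1s), auc = mean(aucs))
}

#' Metrics report for one run
#'
#' @param preds prediction data.frame ([predict_patches()] output or
#'   [aggregate_slides()] output).
#' @param level \code{"patch"} or \code{"slide"}; slide-level input is
#'   aggregated first if it still has patch rows.
#' @return list of class \code{metrics_report} with \code{level} and
#'   \code{metrics}.
#' @export
metrics_report <- function(preds, level = c("patch", "slide")) {
  level <- match.arg(level)
  if (level == "slide" && !"predicted_label" %in% names(preds)) {
    preds <- aggregate_slides(preds)
  }
  m <- compute_metrics(preds$true_label,
                       preds[, prob_cols(preds), drop = FALSE])
  structure(list(level = level, metrics = m), class = "metrics_report")
}

#' Mean and standard deviation over repeated runs
#'
#' Runs are repeated (typically 3 times) to account for run-to-run
#' variation; the summary is the elementwise mean and sample (n - 1)
#' standard deviation of each metric. A single run reports its own values
#' with std 0 by convention.
#'
#' @param per_run list of \code{metrics_report}s from identical
#'   configurations.
#' @return list of class \code{metrics_summary} with \code{level},
#'   \code{per_run} (matrix, one row per run), \code{mean}, \code{std},
#'   \code{n_runs}.
#' @export
summarize_runs <- function(per_run) {
  stopifnot(length(per_run) >= 1)
  levels <- unique(vapply(per_run, `[[`, character(1), "level"))
  if (length(levels) != 1) stop("runs mix levels", call. = FALSE)
  mats <- lapply(per_run, `[[`, "metrics")
  nm <- names(mats[[1]])
  if (!all(vapply(mats, function(m) identical(names(m), nm),
                  logical(1)))) {
    stop("inconsistent metric sets across runs", call. = FALSE)
  }
  M <- do.call(rbind, mats)
  std <- if (nrow(M) > 1) apply(M, 2, stats::sd) else
    stats::setNames(numeric(ncol(M)), nm)
  structure(list(level = levels, per_run = M, mean = colMeans(M),
                 std = std, n_runs = nrow(M)),
            class = "metrics_summary")
}

#' Signed metric differences between two conditions
#'
#' \code{a - b} for each metric mean, reported alongside both standard
#' deviations; used to compare the permuted pipeline against its vanilla
#' baseline.
#'
#' @param report_a,report_b \code{metrics_summary} objects at the same
#'   level.
#' @return data.frame with metric, delta, mean_a, std_a, mean_b, std_b.
#' @export
compare_conditions <- function(report_a, report_b) {
  if (!identical(report_a$level, report_b$level)) {
    stop("cannot compare reports at different levels", call. = FALSE)
  }
  if (!identical(names(report_a$mean), names(report_b$mean))) {
    stop("metric sets differ", call. = FALSE)
  }
  data.frame(metric = names(report_a$mean),
             delta = unname(report_a$mean - report_b$mean),
             mean_a = unname(report_a$mean), std_a = unname(report_a$std),
             mean_b = unname(report_b$mean), std_b = unname(report_b$std),
             row.names = NULL)
}

#' Write a metrics summary to JSON
#'
#' @param summary a \code{metrics_summary}.
#' @param path output path.
#' @export
write_metrics_json <- function(summary, path) {
  jsonlite::write_json(
    list(level = summary$level,
         per_run = apply(summary$per_run, 1, as.list),
         mean = as.list(summary$mean), std = as.list(summary$std)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("%s-level metrics over %d run(s)\n", x$level, x$n_runs))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-9s %.4f (%.4f)\n", nm, x$mean[[nm]], x$std[[nm]]))
  }
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s-level metrics\n", x$level))
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-9s %.4f\n", nm, x$metrics[[nm]]))
  }
  invisible(x)
}
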