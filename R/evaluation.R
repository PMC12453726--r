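# Snapshot-ensemble scoring and multi-label metrics. The ensemble is the
# arithmetic mean of the member models' sigmoid score matrices, averaged
# before thresholding. Per-class AUC is the rank (Mann-Whitney) statistic
# with midrank tie handling; aggregates are support-weighted means, the
# appropriate summary under the strong class imbalance of radiograph label
# tables (accuracy is deliberately not reported).

#' Average snapshot score matrices
#'
#' \deqn{h_{ensemble}(x) = \frac{1}{m}\sum_{j=1}^{m} h_j(x)} where
#' \eqn{h_j} is the sigmoid score matrix of the \eqn{j}th fine-tuned
#' snapshot.
#'
#' @param members nonempty list of score matrices with identical
#'   dimensions and dimnames.
#' @return list with \code{scores} (the elementwise mean) and \code{m}
#'   (member count).
#' @export
ensemble_scores <- function(members) {
  if (length(members) == 0L) stop_currimae("need at least one member", "alignment_error")
  ref <- members[[1]]
  for (m in members) {
    if (!all(dim(m) == dim(ref)) || !identical(dimnames(m), dimnames(ref)))
      stop_currimae("member score matrices are not aligned", "alignment_error")
  }
  list(scores = Reduce(`+`, members) / length(members), m = length(members))
}

#' Threshold scores into predictions
#'
#' Entry is 1 iff the score is \emph{at least} the threshold.
#'
#' @param scores score matrix in \code{[0, 1]}.
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @return integer 0/1 matrix.
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop_currimae("threshold must lie strictly in (0, 1)", "config_error")
  out <- (scores >= threshold) * 1L
  dimnames(out) <- dimnames(scores)
  out
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' @param truth binary vector with at least one positive and one negative.
#' @param score numeric scores.
#' @return AUC in \code{[0, 1]}, or \code{NA} when undefined.
#' @export
auc_rank <- function(truth, score) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)                     # midranks on ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class one-vs-rest metrics
#'
#' For each class: AUC from the scores, and sensitivity
#' (\eqn{TP/(TP+FN)}), precision (\eqn{TP/(TP+FP)}) and F1 (their
#' harmonic mean) at the given threshold. A class with no positives or no
#' negatives has undefined AUC and is reported as \code{NA} rather than
#' dropped; zero-denominator threshold metrics return 0 and are flagged in
#' the \code{degenerate} column.
#'
#' @param truth binary matrix (samples x classes).
#' @param scores aligned score matrix.
#' @param threshold decision threshold.
#' @return data.frame with one row per class: \code{class},
#'   \code{support} (positive count), \code{auc}, \code{sensitivity},
#'   \code{precision}, \code{f1}, \code{degenerate}.
#' @export
per_class_metrics <- function(truth, scores, threshold = 0.5) {
  if (!all(dim(truth) == dim(scores)))
    stop_currimae("truth and scores are not aligned", "alignment_error")
  pred <- binarize(scores, threshold)
  classes <- colnames(scores) %||% sprintf("class%d", seq_len(ncol(scores)))
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    y <- truth[, j]
    p <- pred[, j]
    tp <- sum(y == 1 & p == 1)
    fn <- sum(y == 1 & p == 0)
    fp <- sum(y == 0 & p == 1)
    degenerate <- FALSE
    sens <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
    prec <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
    f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else { degenerate <- TRUE; 0 }
    data.frame(class = classes[j], support = sum(y == 1),
               auc = auc_rank(y, scores[, j]), sensitivity = sens,
               precision = prec, f1 = f1, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$degenerate))
    warning("zero-denominator metrics reported as 0 for some classes")
  out
}

#' Support-weighted average of per-class metrics
#'
#' \deqn{\frac{\sum_{i=1}^N w_i m_i}{\sum_{i=1}^N w_i}} with class
#' supports as weights; \code{NA} metric values (e.g. undefined AUC) are
#' excluded together with their weights.
#'
#' @param values per-class metric values \eqn{m_i}.
#' @param weights nonnegative class supports \eqn{w_i}, summing > 0.
#' @return scalar, always within \code{[min, max]} of the values.
#' @examples
#' weighted_average(c(0.8, 0.6), c(3, 1))  # 0.75
#' @export
weighted_average <- function(values, weights) {
  if (length(values) != length(weights))
    stop_currimae("values and weights must have equal length", "weight_error")
  if (any(weights < 0)) stop_currimae("weights must be nonnegative", "weight_error")
  keep <- !is.na(values)
  if (sum(weights[keep]) <= 0) stop_currimae("total weight must be positive", "weight_error")
  sum(weights[keep] * values[keep]) / sum(weights[keep])
}

#' Score and evaluate a set of fine-tuned snapshots
#'
#' Scores each fine-tuned snapshot on the evaluation split with
#' deterministic eval-phase preprocessing, averages the score matrices
#' into the ensemble, and reports per-class and support-weighted metrics
#' (weights are the per-class positive counts in the evaluation split; a
#' multi-label row contributes to every positive class).
#'
#' @param classifiers list of \code{vit_classifier}s sharing one class
#'   schema.
#' @param table evaluation \code{\link{label_table}}.
#' @param images image array/list aligned with \code{table$ids}.
#' @param threshold decision threshold (default 0.5).
#' @return object of class \code{metrics_report}: \code{members} (list of
#'   score matrices), \code{ensemble} (score matrix), \code{per_class}
#'   (data.frame), \code{weighted} (named vector), \code{threshold},
#'   \code{m}.
#' @export
evaluate_ensemble <- function(classifiers, table, images, threshold = 0.5) {
  cls <- classifiers[[1]]$classes
  for (c_ in classifiers)
    if (!identical(c_$classes, cls))
      stop_currimae("snapshot classifiers disagree on the class schema", "alignment_error")
  if (!identical(cls, table$classes))
    stop_currimae("classifier and table class schemas differ", "alignment_error")
  members <- lapply(classifiers, predict_scores, images = images, ids = table$ids)
  ens <- ensemble_scores(members)
  pc <- per_class_metrics(table$labels, ens$scores, threshold)
  weighted <- vapply(c("auc", "sensitivity", "precision", "f1"),
                     function(m) weighted_average(pc[[m]], pc$support),
                     numeric(1))
  structure(list(members = members, ensemble = ens$scores, per_class = pc,
                 weighted = weighted, threshold = threshold, m = ens$m),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %d-member snapshot ensemble, threshold %.2f>\n",
              x$m, x$threshold))
  print(x$per_class[, c("class", "support", "auc", "sensitivity", "precision", "f1")],
        row.names = FALSE, digits = 3)
  cat("weighted: ",
      paste(sprintf("%s=%.3f", names(x$weighted), x$weighted), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Score matrices as CSV (sample-id rows, class columns) and the report as
#' JSON with per-class and weighted blocks.
#'
#' @param report a \code{metrics_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(report$members))
    utils::write.csv(report$members[[j]],
                     file.path(dir, sprintf("scores_member%d.csv", j)))
  utils::write.csv(report$ensemble, file.path(dir, "scores_ensemble.csv"))
  jsonlite::write_json(
    list(threshold = report$threshold, members = report$m,
         per_class = report$per_class, weighted = as.list(report$weighted)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
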