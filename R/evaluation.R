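#' Confusion-matrix statistics for binary calls
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP). A metric whose denominator
#' is zero is reported as `NA` and flagged in `undefined`, never silently 0.
#'
#' @param calls 0/1 (or logical) predicted calls.
#' @param truth 0/1 (or logical) true labels, same length.
#' @return list with counts `tp`, `fp`, `tn`, `fn`, the four metrics, and
#'   `undefined` (character vector naming any undefined metric).
#' @export
confusion_metrics <- function(calls, truth) {
  calls <- as.numeric(calls); truth <- as.numeric(truth)
  if (length(calls) != length(truth)) stop("calls and truth differ in length")
  if (!length(calls)) stop("need at least one entry")
  tp <- sum(calls == 1 & truth == 1)
  fp <- sum(calls == 1 & truth == 0)
  tn <- sum(calls == 0 & truth == 0)
  fn <- sum(calls == 0 & truth == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              accuracy = ratio(tp + tn, tp + tn + fp + fn),
              precision = ratio(tp, tp + fp))
  out$undefined <- names(which(vapply(out[c("sensitivity", "specificity",
                                            "accuracy", "precision")],
                                      is.na, logical(1))))
  out
}

#' ROC curve and area under it
#'
#' The AUC is computed by the rank (Mann-Whitney U) formulation — the
#' probability that a random positive is scored above a random negative,
#' with ties counted 1/2 — which is exact under ties; the curve points come
#' from a threshold sweep over the unique scores.
#'
#' @param scores real-valued classifier scores.
#' @param truth 0/1 labels; both classes must be present.
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.numeric(truth)
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0) stop("no positive labels in truth")
  if (n_neg == 0) stop("no negative labels in truth")
  r <- rank(scores)
  auc <- (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(threshold = th,
                      fpr = vapply(th, function(t) sum(scores >= t & truth == 0),
                                   numeric(1)) / n_neg,
                      tpr = vapply(th, function(t) sum(scores >= t & truth == 1),
                                   numeric(1)) / n_pos)
  list(auc = auc, curve = curve)
}

#' Precision-recall curve and average precision
#'
#' Sweeps thresholds over the unique scores (tied scores enter together) and
#' returns the step-function average precision
#' `AP = sum_k (R_k - R_(k-1)) P_k`.
#'
#' @inheritParams roc_auc
#' @return list with `average_precision` and `curve` (data.frame
#'   `threshold`, `recall`, `precision`).
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.numeric(truth)
  if (length(scores) != length(truth)) stop("scores and truth differ in length")
  n_pos <- sum(truth == 1)
  if (n_pos == 0) stop("no positive labels in truth")
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(scores >= t & truth == 1), numeric(1))
  npred <- vapply(th, function(t) sum(scores >= t), numeric(1))
  precision <- tp / npred
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(average_precision = ap,
       curve = data.frame(threshold = th, recall = recall,
                          precision = precision))
}

#' Evaluate one allele classifier on labelled donors
#'
#' @param scores classifier probabilities.
#' @param truth 0/1 allele status.
#' @param threshold decision threshold (default 0.5).
#' @param allele allele label carried into the report.
#' @return list (an evaluation report): allele, confusion counts and
#'   metrics, `auc_roc`, `auc_pr`.
#' @export
evaluate_classifier <- function(scores, truth, threshold = 0.5, allele = NA) {
  cm <- confusion_metrics(as.numeric(scores >= threshold), truth)
  c(list(allele = allele), cm,
    list(auc_roc = roc_auc(scores, truth)$auc,
         auc_pr = pr_curve(scores, truth)$average_precision))
}

#' Cross-allele summary: precision vs association count and allele prevalence
#'
#' Computes the Pearson correlation of per-allele precision against (i) the
#' number of clonotypes associated with the allele and (ii) the allele's
#' prevalence in the cohort, with p-values.
#'
#' @param reports list of per-allele evaluation reports (from
#'   [evaluate_classifier()]), each with `allele` and `precision`.
#' @param cohort the HLA-typed `tcr_cohort` the models were evaluated on.
#' @param associations association records (used to count associations per
#'   allele).
#' @return data.frame with one row per correlate: `correlate`, `r`, `p`,
#'   `undefined` (TRUE when a correlation is undefined, e.g. zero variance).
#' @export
summarize_across_alleles <- function(reports, cohort, associations) {
  if (length(reports) < 3) stop("need at least 3 alleles to summarize")
  alleles <- vapply(reports, `[[`, character(1), "allele")
  precision <- vapply(reports, function(r) as.numeric(r$precision), numeric(1))
  n_assoc <- vapply(alleles, function(a)
    sum(associations$allele == a), numeric(1))
  prevalence <- vapply(alleles, function(a)
    mean(cohort_allele_status(cohort, a)), numeric(1))
  one <- function(name, x) {
    ok <- !is.na(precision) & !is.na(x)
    if (sum(ok) < 3 || stats::sd(precision[ok]) == 0 || stats::sd(x[ok]) == 0) {
      return(data.frame(correlate = name, r = NA_real_, p = NA_real_,
                        undefined = TRUE))
    }
    ct <- stats::cor.test(precision[ok], x[ok], method = "pearson")
    data.frame(correlate = name, r = unname(ct$estimate), p = ct$p.value,
               undefined = FALSE)
  }
  out <- rbind(one("n_associations", n_assoc), one("prevalence", prevalence))
  rownames(out) <- NULL
  out
}

#' Write per-allele evaluation reports as TSV
#' @param reports list of evaluation reports.
#' @param path output path.
#' @export
write_eval_reports <- function(reports, path) {
  cols <- c("allele", "tp", "fp", "tn", "fn", "sensitivity", "specificity",
            "accuracy", "precision", "auc_roc", "auc_pr")
  df <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
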