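ALPHA_FEATURE <- ".alpha_sequenced"

# 1 iff some candidate CDR3 (same length assumed not checked here) is within
# Hamming distance 1 of `target`
has_hamming1_neighbor <- function(target, candidates) {
  if (!length(candidates)) return(FALSE)
  t_chars <- strsplit(target, "")[[1]]
  for (cand in candidates) {
    mism <- sum(strsplit(cand, "")[[1]] != t_chars)
    if (mism <= 1) return(TRUE)
  }
  FALSE
}

#' Encode a donor as a presence/absence feature vector
#'
#' For each feature clonotype, `x_i = 1` iff the donor's repertoire contains
#' a match. Exact matching requires the identical `(chain, cdr3_aa,
#' v_family)` triple; fuzzy matching (`fuzzy1`) also accepts a donor
#' clonotype of the same chain, V family and CDR3 length whose CDR3 differs
#' by at most one amino acid. Alpha-chain features are structurally 0 for
#' donors whose alpha chain was not sequenced.
#'
#' @param donor a `tcr_donor`.
#' @param features clonotype data.frame (columns `chain`, `cdr3_aa`,
#'   `v_family`).
#' @param matching `"exact"` or `"fuzzy1"`.
#' @return A list with `x` (0/1 vector over features) and `y` (1 if the
#'   donor's alpha chain was sequenced, else 0).
#' @export
encode_donor <- function(donor, features, matching = c("exact", "fuzzy1")) {
  matching <- match.arg(matching)
  if (!nrow(features)) stop("features must be nonempty")
  rep_cl <- donor$clonotypes
  if (matching == "exact") {
    x <- as.numeric(clonotype_key(features) %in% clonotype_key(rep_cl))
  } else {
    rep_len_ <- nchar(rep_cl$cdr3_aa)
    x <- vapply(seq_len(nrow(features)), function(i) {
      sel <- rep_cl$chain == features$chain[i] &
        rep_cl$v_family == features$v_family[i] &
        rep_len_ == nchar(features$cdr3_aa[i])
      as.numeric(has_hamming1_neighbor(features$cdr3_aa[i],
                                       rep_cl$cdr3_aa[sel]))
    }, numeric(1))
  }
  x[features$chain == "alpha" & !donor$has_alpha] <- 0
  list(x = x, y = as.numeric(donor$has_alpha))
}

#' Encode every donor of a cohort
#' @inheritParams encode_donor
#' @param cohort a `tcr_cohort`.
#' @return list with `X` (donor x feature 0/1 matrix) and `y` (alpha flags).
#' @export
encode_cohort <- function(cohort, features, matching = c("exact", "fuzzy1")) {
  matching <- match.arg(matching)
  enc <- lapply(cohort$donors, encode_donor, features = features,
                matching = matching)
  X <- do.call(rbind, lapply(enc, `[[`, "x"))
  rownames(X) <- cohort_donor_ids(cohort)
  colnames(X) <- clonotype_key(features)
  list(X = X, y = vapply(enc, `[[`, numeric(1), "y"))
}

#' Probability of allele positivity from a feature vector
#'
#' The logistic model: `p = 1 / (1 + exp(-sum_i w_i x_i - v*y - b))`, where
#' `x_i` are presence indicators of the allele-associated clonotypes, `y`
#' indicates that the alpha chain was sequenced, `w`/`v` are learned weights
#' and `b` the intercept (0 in intercept-free mode).
#'
#' @param model an `allele_classifier`.
#' @param x 0/1 feature vector conformal with `model$features`.
#' @param y alpha-sequenced indicator (0/1).
#' @return probability in (0, 1).
#' @export
predict_proba <- function(model, x, y) {
  stopifnot(inherits(model, "allele_classifier"))
  if (length(x) != length(model$w)) {
    stop("feature vector length ", length(x), " does not match model (",
         length(model$w), " features)")
  }
  stats::plogis(sum(model$w * x) + model$v * y + model$b)
}

# stratified 70/30 split indices, reproducible; guarantees >=1 donor of each
# class in both portions
stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  train <- logical(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    if (length(idx) < 2) {
      stop("need at least 2 ", if (cls) "positive" else "negative",
           " donors to split")
    }
    n_train <- min(max(round(train_frac * length(idx)), 1), length(idx) - 1)
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

cross_entropy <- function(truth, prob) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Fit a per-allele logistic HLA classifier
#'
#' Trains the logistic model on presence/absence of the allele's associated
#' clonotypes plus the alpha-sequenced indicator. Donors are split 70/30
#' (stratified by allele status); the model is fitted on the 70% over a
#' geometric grid of inverse regularization strengths `C`, and the `C`
#' minimizing the logistic cross-entropy on the held-out 30% is selected
#' (ties broken toward the stronger penalty, i.e. the sparser model under
#' L1). The optimization is performed by `glmnet` with
#' `lambda = 1/(n_train * C)`.
#'
#' @param cohort a fully HLA-typed `tcr_cohort`.
#' @param associations association records from [discover()] (or any
#'   clonotype table with an `allele` column); rows for `allele` become the
#'   model's features. By default only `enriched` associations are used.
#' @param allele the HLA allele to model.
#' @param penalty `"L1"` (lasso, default) or `"L2"` (ridge).
#' @param matching feature matching mode, `"exact"` or `"fuzzy1"`.
#' @param split_seed seed for the 70/30 split (and nothing else).
#' @param train_frac training fraction (default 0.7).
#' @param intercept include an intercept `b` (default `TRUE`); `FALSE` gives
#'   the literal intercept-free model.
#' @param enriched_only use only enriched associations as features.
#' @param threshold decision threshold on the probability scale (default 0.5).
#' @param C_grid inverse-penalty grid (default 20 geometric points from 1e-3
#'   to 1e3).
#' @return An object of class `allele_classifier` with elements `allele`,
#'   `features`, weights `w`, alpha weight `v`, intercept `b`, `threshold`,
#'   `penalty`, selected `C`, the selection `grid` (C, lambda, held-out
#'   cross-entropy, nonzero weight count), the held-out predictions and
#'   `heldout_auc`.
#' @export
fit_allele_classifier <- function(cohort, associations, allele,
                                  penalty = c("L1", "L2"),
                                  matching = c("exact", "fuzzy1"),
                                  split_seed = 1, train_frac = 0.7,
                                  intercept = TRUE, enriched_only = TRUE,
                                  threshold = 0.5,
                                  C_grid = 10^seq(-3, 3, length.out = 20)) {
  penalty <- match.arg(penalty)
  matching <- match.arg(matching)
  allele <- normalize_hla(allele)
  feat <- associations[associations$allele == allele, , drop = FALSE]
  if (enriched_only && "direction" %in% names(feat)) {
    feat <- feat[feat$direction == "enriched", , drop = FALSE]
  }
  feat <- feat[!duplicated(clonotype_key(feat)), c("chain", "cdr3_aa", "v_family")]
  feat <- feat[order_clonotypes(feat), , drop = FALSE]
  rownames(feat) <- NULL
  if (!nrow(feat)) {
    stop("no features: allele ", allele, " has no associated clonotypes")
  }
  labels <- cohort_allele_status(cohort, allele)
  enc <- encode_cohort(cohort, feat, matching = matching)
  design <- cbind(enc$X, enc$y)
  colnames(design) <- c(colnames(enc$X), ALPHA_FEATURE)
  train <- stratified_split(labels, train_frac, split_seed)

  n_train <- sum(train)
  lambda <- sort(1 / (n_train * C_grid), decreasing = TRUE)
  C_sorted <- 1 / (n_train * lambda)          # strongest penalty first
  fit <- glmnet::glmnet(design[train, , drop = FALSE], labels[train],
                        family = "binomial",
                        alpha = if (penalty == "L1") 1 else 0,
                        lambda = lambda, standardize = FALSE,
                        intercept = intercept, thresh = 1e-10, maxit = 1e6)
  test_prob <- stats::predict(fit, design[!train, , drop = FALSE],
                              s = lambda, type = "response", exact = FALSE)
  ce <- apply(test_prob, 2, function(p) cross_entropy(labels[!train], p))
  beta <- as.matrix(fit$beta)
  nonzero <- colSums(abs(beta[seq_len(ncol(enc$X)), , drop = FALSE]) > 0)
  best <- which.min(ce)                       # first minimum = strongest penalty
  coefs <- beta[, best]
  w <- coefs[seq_len(ncol(enc$X))]
  v <- coefs[[ALPHA_FEATURE]]
  b <- if (intercept) fit$a0[[best]] else 0
  heldout_prob <- test_prob[, best]
  heldout_auc <- if (length(unique(labels[!train])) == 2) {
    roc_auc(heldout_prob, as.numeric(labels[!train]))$auc
  } else NA_real_

  structure(list(
    allele = allele, features = feat, w = unname(w), v = v, b = b,
    threshold = threshold, penalty = penalty, C = C_sorted[best],
    matching = matching, intercept = intercept, split_seed = split_seed,
    train_frac = train_frac,
    grid = data.frame(C = C_sorted, lambda = lambda, test_ce = ce,
                      nonzero = nonzero, row.names = NULL),
    train_ids = cohort_donor_ids(cohort)[train],
    heldout = data.frame(donor_id = cohort_donor_ids(cohort)[!train],
                         truth = as.numeric(labels[!train]),
                         prob = heldout_prob, row.names = NULL),
    heldout_auc = heldout_auc),
    class = "allele_classifier")
}

#' @export
print.allele_classifier <- function(x, ...) {
  cat(sprintf("<allele_classifier> %s: %d features (%s, %s matching)\n",
              x$allele, length(x$w), x$penalty, x$matching))
  cat(sprintf("  C = %.4g, nonzero weights = %d/%d, v = %.3f, b = %.3f\n",
              x$C, sum(x$w != 0), length(x$w), x$v, x$b))
  if (!is.na(x$heldout_auc)) {
    cat(sprintf("  held-out AUC = %.3f (n = %d)\n", x$heldout_auc,
                nrow(x$heldout)))
  }
  invisible(x)
}

#' @export
coef.allele_classifier <- function(object, ...) {
  stats::setNames(c(object$b, object$v, object$w),
                  c("(intercept)", "(alpha_sequenced)",
                    clonotype_key(object$features)))
}

#' @export
summary.allele_classifier <- function(object, ...) {
  calls <- as.numeric(object$heldout$prob >= object$threshold)
  metrics <- confusion_metrics(calls, object$heldout$truth)
  out <- list(model = object, heldout_metrics = metrics,
              heldout_auc = object$heldout_auc,
              sparsity = mean(object$w == 0))
  class(out) <- "summary.allele_classifier"
  out
}

#' @export
print.summary.allele_classifier <- function(x, ...) {
  print(x$model)
  m <- x$heldout_metrics
  cat(sprintf("  held-out: sens %.3f  spec %.3f  acc %.3f  prec %s  (zero-weight fraction %.2f)\n",
              m$sensitivity, m$specificity, m$accuracy,
              ifelse(is.na(m$precision), "NA", sprintf("%.3f", m$precision)),
              x$sparsity))
  invisible(x)
}

#' Predict allele positivity for donors
#'
#' @param object an `allele_classifier`.
#' @param newdata a `tcr_cohort` or a single `tcr_donor`.
#' @param type `"response"` (probability), `"class"` (0/1 call at the model
#'   threshold) or `"link"` (linear score).
#' @param ... unused.
#' @return numeric vector named by donor id.
#' @export
predict.allele_classifier <- function(object, newdata,
                                      type = c("response", "class", "link"),
                                      ...) {
  type <- match.arg(type)
  if (inherits(newdata, "tcr_donor")) {
    newdata <- new_cohort(list(newdata), name = "single")
  }
  stopifnot(inherits(newdata, "tcr_cohort"))
  enc <- encode_cohort(newdata, object$features, matching = object$matching)
  link <- drop(enc$X %*% object$w) + object$v * enc$y + object$b
  out <- switch(type,
                link = link,
                response = stats::plogis(link),
                class = as.numeric(stats::plogis(link) >= object$threshold))
  stats::setNames(out, cohort_donor_ids(newdata))
}

#' Weight-free count classifier
#'
#' Counts how many feature clonotypes match the donor's repertoire (all
#' weights equal to 1, no logistic fit) and calls the donor positive when the
#' count reaches `threshold`. Ranking donors by this count is identical to
#' ranking by the logistic score with equal weights.
#'
#' @inheritParams encode_donor
#' @param threshold minimum match count for a positive call (default 1).
#' @return list with `count` and logical `call`.
#' @export
count_classifier <- function(donor, features, matching = c("exact", "fuzzy1"),
                             threshold = 1) {
  matching <- match.arg(matching)
  enc <- encode_donor(donor, features, matching = matching)
  count <- sum(enc$x)
  list(count = count, call = count >= threshold)
}

#' Apply a set of per-allele classifiers to a cohort
#'
#' @param models list of `allele_classifier` objects.
#' @param cohort a `tcr_cohort` (HLA typing not required).
#' @return data.frame with one row per donor x allele: `donor_id`, `allele`,
#'   `prob`, `call`.
#' @export
predict_cohort <- function(models, cohort) {
  if (!length(models)) stop("empty model list")
  rows <- lapply(models, function(m) {
    prob <- predict(m, cohort, type = "response")
    data.frame(donor_id = names(prob), allele = m$allele, prob = unname(prob),
               call = unname(prob) >= m$threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize / deserialize a trained classifier as JSON
#' @param model an `allele_classifier`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  payload <- unclass(model)
  payload$heldout <- NULL
  payload$train_ids <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns an `allele_classifier` (without the held-out
#'   predictions of the training run).
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$features <- as.data.frame(x$features, stringsAsFactors = FALSE)
  x$grid <- as.data.frame(x$grid, stringsAsFactors = FALSE)
  structure(x, class = "allele_classifier")
}
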