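#' Partition untyped donors into random subgroups
#'
#' Applies a seeded random permutation and cuts it into consecutive chunks of
#' `subgroup_size`; the final chunk may be smaller. Every donor lands in
#' exactly one chunk.
#'
#' @param cohort a `tcr_cohort`.
#' @param subgroup_size chunk size (default 100).
#' @param seed permutation seed.
#' @return list of `tcr_donor` lists (empty list for an empty cohort).
#' @export
partition_untyped <- function(cohort, subgroup_size = 100, seed = 1) {
  stopifnot(subgroup_size >= 1)
  n <- length(cohort$donors)
  if (n == 0) return(list())
  set.seed(seed)
  perm <- sample.int(n)
  chunks <- split(perm, ceiling(seq_along(perm) / subgroup_size))
  lapply(unname(chunks), function(idx) unname(cohort$donors[idx]))
}

#' Top-k association discovery under a fixed budget
#'
#' Runs the association tests for a single allele and returns at most
#' `budget` records, ranked by raw p-value (ties broken deterministically).
#' Records with `p_raw = 1` (no evidence at all) are never admitted. This
#' replaces the fixed-FDR threshold during iterative typing: the p-value
#' threshold is effectively tuned so that the number of associated sequences
#' follows the budget.
#'
#' @param cohort HLA-typed `tcr_cohort` (or untyped, if `labels` is given).
#' @param allele the allele under study.
#' @param budget maximum number of associations to return.
#' @param min_publicness publicness threshold (default 3).
#' @param min_carriers minimum allele carriers (default 5).
#' @param labels optional logical vector of per-donor allele status, used
#'   instead of the donors' `hla` fields (needed when labels are imputed).
#' @return association records (at most `budget` rows), columns as in
#'   [association_tests()].
#' @export
budgeted_discover <- function(cohort, allele, budget, min_publicness = 3,
                              min_carriers = 5, labels = NULL) {
  stopifnot(budget >= 1)
  allele <- normalize_hla(allele)
  if (is.null(labels)) {
    labels <- cohort_allele_status(cohort, allele)
  }
  stopifnot(length(labels) == length(cohort$donors))
  if (sum(labels) < min_carriers || sum(labels) == 0) {
    return(empty_association_frame())
  }
  occ <- occurrence_matrix(cohort, min_publicness = min_publicness)
  has_alpha <- cohort_has_alpha(cohort)
  is_alpha_col <- occ$clonotypes$chain == "alpha"
  parts <- list()
  if (any(!is_alpha_col)) {
    parts$beta <- allele_scan(list(matrix = occ$matrix[, !is_alpha_col, drop = FALSE],
                                   clonotypes = occ$clonotypes[!is_alpha_col, , drop = FALSE]),
                              labels)
  }
  if (any(is_alpha_col) && sum(labels[has_alpha]) > 0) {
    parts$alpha <- allele_scan(list(matrix = occ$matrix[has_alpha, is_alpha_col, drop = FALSE],
                                    clonotypes = occ$clonotypes[is_alpha_col, , drop = FALSE]),
                               labels[has_alpha])
  }
  rec <- do.call(rbind, parts)
  if (is.null(rec) || !nrow(rec)) return(empty_association_frame())
  rec$allele <- allele
  rec$direction <- ifelse(rec$n_pp * rec$n_nn > rec$n_pn * rec$n_np,
                          "enriched", "depleted")
  rec <- rec[rec$p_raw < 1, , drop = FALSE]
  rec <- rec[order_association_records(rec), , drop = FALSE]
  rec <- utils::head(rec, budget)
  rownames(rec) <- NULL
  rec
}

#' Iteratively type an untyped cohort and mine new associations
#'
#' The bootstrapping recursion: untyped donors are split into random
#' subgroups; at each step the current classifier imputes the allele status
#' of the next subgroup, the subgroup joins the working cohort with its
#' imputed (and thereafter frozen) labels, associations are re-discovered
#' under a donor-proportional budget — the associations-per-donor ratio is
#' fixed at its value in the initial typed cohort — and the classifier is
#' re-fit on the augmented cohort with a fresh 70/30 split. The loop runs
#' until all subgroups are typed.
#'
#' @param initial an HLA-typed `tcr_cohort` able to support a classifier for
#'   `allele`.
#' @param untyped a `tcr_cohort` without typings.
#' @param allele the allele to type.
#' @param subgroup_size subgroup size (default 100).
#' @param seed seed driving the partition and the per-iteration split seeds.
#' @param q FDR level for the initial discovery (default 0.01).
#' @param min_publicness publicness threshold (default 3).
#' @param penalty,matching passed to [fit_allele_classifier()].
#' @param initial_associations optionally reuse a precomputed association
#'   list for the initial cohort (rows for other alleles are ignored).
#' @return list of class `hla_iteration`: final `model`, `history`
#'   (data.frame iteration, n_donors, n_associations, budget, test
#'   cross-entropy), `imputed` (data.frame donor_id, prob, call),
#'   `budget_ratio`, and the final `associations`.
#' @export
iterate_typing <- function(initial, untyped, allele, subgroup_size = 100,
                           seed = 1, q = 0.01, min_publicness = 3,
                           penalty = "L1", matching = "exact",
                           initial_associations = NULL) {
  allele <- normalize_hla(allele)
  if (is.null(initial_associations)) {
    initial_associations <- discover(initial, q = q,
                                     min_publicness = min_publicness)
  }
  feat0 <- initial_associations[initial_associations$allele == allele &
                                  initial_associations$direction == "enriched", ,
                                drop = FALSE]
  if (!nrow(feat0)) {
    stop("no initial associations for allele ", allele,
         "; cannot fix the association budget ratio")
  }
  n0 <- length(initial$donors)
  budget_ratio <- nrow(feat0) / n0
  model <- fit_allele_classifier(initial, feat0, allele, penalty = penalty,
                                 matching = matching, split_seed = seed)
  subgroups <- partition_untyped(untyped, subgroup_size, seed = seed)
  history <- data.frame(iteration = integer(0), n_donors = integer(0),
                        n_associations = integer(0), budget = numeric(0),
                        test_ce = numeric(0))
  initial_state <- list(n_donors = n0, n_associations = nrow(feat0),
                        test_ce = min(model$grid$test_ce))
  working_donors <- unname(initial$donors)
  working_labels <- cohort_allele_status(initial, allele)
  imputed <- data.frame(donor_id = character(), prob = numeric(),
                        call = logical(), stringsAsFactors = FALSE)
  associations <- feat0

  for (t in seq_along(subgroups)) {
    grp <- subgroups[[t]]
    grp_cohort <- new_cohort(grp, name = "subgroup")
    prob <- predict(model, grp_cohort, type = "response")
    call <- prob >= model$threshold
    imputed <- rbind(imputed,
                     data.frame(donor_id = names(prob), prob = unname(prob),
                                call = unname(call), stringsAsFactors = FALSE))
    working_donors <- c(working_donors, grp)
    working_labels <- c(working_labels, unname(call))
    working <- new_cohort(working_donors, name = "augmented")
    budget <- ceiling(budget_ratio * length(working_donors))
    associations <- budgeted_discover(working, allele, budget = budget,
                                      min_publicness = min_publicness,
                                      labels = working_labels)
    feats <- associations[associations$direction == "enriched", , drop = FALSE]
    if (!nrow(feats)) {
      warning("iteration ", t, ": no enriched associations; stopping early")
      break
    }
    model <- tryCatch(
      fit_with_labels(working, feats, allele, working_labels,
                      penalty = penalty, matching = matching,
                      split_seed = seed + t),
      error = function(e) {
        warning("iteration ", t, ": model fit failed (", conditionMessage(e),
                "); returning history so far")
        NULL
      })
    if (is.null(model)) break
    history <- rbind(history,
                     data.frame(iteration = t,
                                n_donors = length(working_donors),
                                n_associations = nrow(associations),
                                budget = budget,
                                test_ce = min(model$grid$test_ce)))
  }
  structure(list(model = model, history = history, imputed = imputed,
                 budget_ratio = budget_ratio, associations = associations,
                 initial = initial_state, allele = allele),
            class = "hla_iteration")
}

# fit_allele_classifier against an explicit label vector (imputed labels do
# not live in the donors' hla fields)
fit_with_labels <- function(cohort, associations, allele, labels, ...) {
  donors <- lapply(seq_along(cohort$donors), function(i) {
    d <- cohort$donors[[i]]
    d$hla <- if (labels[i]) normalize_hla(allele) else character(0)
    d
  })
  fit_allele_classifier(new_cohort(donors, name = cohort$name),
                        associations, allele, ...)
}

#' @export
print.hla_iteration <- function(x, ...) {
  cat(sprintf("<hla_iteration> %s: %d iterations, budget ratio %.3f assoc/donor\n",
              x$allele, nrow(x$history), x$budget_ratio))
  if (nrow(x$history)) print(utils::tail(x$history, 3), row.names = FALSE)
  invisible(x)
}

#' Write an iteration history and imputed typings
#' @param result an `hla_iteration`.
#' @param history_path TSV output for the history.
#' @param imputed_path CSV output for the imputed per-donor calls.
#' @export
write_iteration <- function(result, history_path, imputed_path = NULL) {
  utils::write.table(result$history, history_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(imputed_path)) {
    utils::write.table(result$imputed, imputed_path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(history_path)
}
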