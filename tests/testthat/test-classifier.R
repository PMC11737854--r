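test_that("exact and fuzzy matching follow the one-mismatch/equal-length rule", {
  feat <- clonotype_frame("beta", "CASSLGETQYF", "TRBV19")
  donor <- make_donor("d", list(c("beta", "CASSLGDTQYF", "TRBV19")))
  expect_equal(encode_donor(donor, feat, "fuzzy1")$x, 1)
  expect_equal(encode_donor(donor, feat, "exact")$x, 0)
  # different CDR3 lengths never fuzzy-match
  donor2 <- make_donor("d2", list(c("beta", "CASSLGETQF", "TRBV19")))
  expect_equal(encode_donor(donor2, feat, "fuzzy1")$x, 0)
  # different V family never matches
  donor3 <- make_donor("d3", list(c("beta", "CASSLGDTQYF", "TRBV5")))
  expect_equal(encode_donor(donor3, feat, "fuzzy1")$x, 0)
  # two mismatches never match
  donor4 <- make_donor("d4", list(c("beta", "CASSLGDTQYA", "TRBV19")))
  expect_equal(encode_donor(donor4, feat, "fuzzy1")$x, 0)
})

test_that("fuzzy matching is a superset of exact matching on simulated donors", {
  sim <- simulate_cohort(sim_config(n_donors = 40, n_background = 120, seed = 77))
  feat <- sim$cohort$donors[[1]]$clonotypes[1:10, ]
  for (d in sim$cohort$donors[1:15]) {
    xe <- encode_donor(d, feat, "exact")$x
    xf <- encode_donor(d, feat, "fuzzy1")$x
    expect_true(all(xe <= xf))
  }
})

test_that("alpha features are structurally zero without alpha sequencing", {
  feat <- clonotype_frame(c("alpha", "beta"),
                          c("CAVRDSNYQLIW", "CASSLGETQYF"),
                          c("TRAV21", "TRBV19"))
  donor <- make_donor("d", list(c("alpha", "CAVRDSNYQLIW", "TRAV21"),
                                c("beta", "CASSLGETQYF", "TRBV19")))
  donor$has_alpha <- FALSE   # declared flag wins over content
  enc <- encode_donor(donor, feat, "exact")
  expect_equal(enc$x, c(0, 1))
  expect_equal(enc$y, 0)
})

test_that("predict_proba is the closed-form logistic of the stored weights", {
  m <- structure(list(allele = "A*02:01",
                      features = clonotype_frame("beta", "CASSF", "TRBV19"),
                      w = 0, v = 0, b = 0, threshold = 0.5),
                 class = "allele_classifier")
  expect_equal(predict_proba(m, 1, 0), 0.5)
  m$w <- log(3)
  expect_equal(predict_proba(m, 1, 0), 0.75)
  m$w <- 0; m$v <- -log(4)
  expect_equal(predict_proba(m, 0, 1), 0.2)
  expect_error(predict_proba(m, c(0, 1), 0), "length")
  # monotonicity: flipping a positive-weight feature on raises the probability
  m$w <- 0.8; m$v <- 0.1; m$b <- -1
  expect_gt(predict_proba(m, 1, 1), predict_proba(m, 0, 1))
  expect_true(predict_proba(m, 1, 1) > 0 && predict_proba(m, 1, 1) < 1)
})

sep_cohort <- function(seed = 1, n = 120) {
  simulate_cohort(sim_config(
    n_donors = n, alleles = data.frame(allele = "A*02:01", freq = 0.5),
    n_background = 60,
    planted = data.frame(allele = "A*02:01", n_clonotypes = 5,
                         p_pos = 1, p_neg = 0),
    alpha_clonotype_fraction = 0, seed = seed))
}

truth_as_associations <- function(truth) {
  cbind(truth[, c("chain", "cdr3_aa", "v_family", "allele")],
        direction = "enriched")
}

test_that("a perfectly separating feature set gives held-out AUC 1 and deterministic fits", {
  sim <- sep_cohort(3)
  assoc <- truth_as_associations(sim$truth)
  m1 <- fit_allele_classifier(sim$cohort, assoc, "A*02:01", split_seed = 5)
  expect_equal(m1$heldout_auc, 1.0)
  m2 <- fit_allele_classifier(sim$cohort, assoc, "A*02:01", split_seed = 5)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$C, m2$C)
  # selected C minimizes held-out cross-entropy over the whole grid
  expect_equal(min(m1$grid$test_ce),
               m1$grid$test_ce[m1$grid$C == m1$C][1])
  # refusal with no features
  expect_error(fit_allele_classifier(sim$cohort, assoc, "B*07:02"),
               "no features")
})

test_that("label-independent features give held-out AUC near 0.5", {
  aucs <- vapply(1:8, function(s) {
    sim <- simulate_cohort(sim_config(
      n_donors = 250, alleles = data.frame(allele = "A*02:01", freq = 0.5),
      n_background = 0,
      planted = data.frame(allele = "A*02:01", n_clonotypes = 40,
                           p_pos = 0.2, p_neg = 0.2),
      seed = 100 + s))
    fit_allele_classifier(sim$cohort, truth_as_associations(sim$truth),
                          "A*02:01", split_seed = s)$heldout_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("planted features recover the signal and carry the weight mass", {
  sim <- simulate_cohort(sim_config(
    n_donors = 500, alleles = data.frame(allele = "A*02:01", freq = 0.3),
    n_background = 300,
    planted = data.frame(allele = "A*02:01", n_clonotypes = 20,
                         p_pos = 0.6, p_neg = 0.05),
    seed = 55))
  assoc <- discover(sim$cohort)
  m <- fit_allele_classifier(sim$cohort, assoc, "A*02:01", split_seed = 9)
  expect_gte(m$heldout_auc, 0.95)
  planted_keys <- tcrhla:::clonotype_key(sim$truth)
  w_named <- setNames(abs(m$w), tcrhla:::clonotype_key(m$features))
  in_planted <- names(w_named) %in% planted_keys
  expect_gt(sum(w_named[in_planted]), sum(w_named[!in_planted]))
  # L1 path: active set grows as the penalty weakens (grid rows are ordered
  # strongest penalty first); with correlated features the lasso path may
  # exchange a single variable between steps, so allow drops of at most one
  expect_true(all(diff(m$grid$nonzero) >= -1))
  expect_gt(m$grid$nonzero[20], m$grid$nonzero[6])
  # L1 sparsity is reported
  expect_true(mean(m$w == 0) >= 0)
})

test_that("count classifier ranking equals the unit-weight logistic ranking", {
  sim <- sep_cohort(21, n = 60)
  feat <- rbind(sim$truth[, c("chain", "cdr3_aa", "v_family")],
                sim$cohort$donors[[1]]$clonotypes[1:5, ])
  counts <- vapply(sim$cohort$donors, function(d)
    count_classifier(d, feat)$count, numeric(1))
  unit <- structure(list(allele = "A*02:01", features = feat,
                         w = rep(1, nrow(feat)), v = 0, b = 0,
                         threshold = 0.5, matching = "exact"),
                    class = "allele_classifier")
  probs <- predict(unit, sim$cohort)
  expect_equal(order(counts, seq_along(counts)),
               order(probs, seq_along(probs)))
  truth <- donor_status(sim$cohort, "A*02:01")
  expect_equal(roc_auc(counts, truth)$auc, roc_auc(probs, truth)$auc)
  # degenerate thresholds
  d0 <- make_donor("none", list(c("beta", "CASSNNMATCHF", "TRBV9")))
  expect_false(count_classifier(d0, feat, threshold = 1)$call)
  expect_true(count_classifier(d0, feat, threshold = 0)$call)
})

test_that("cohort prediction handles empty repertoires and missing alpha data", {
  sim <- sep_cohort(33, n = 80)
  m <- fit_allele_classifier(sim$cohort,
                             truth_as_associations(sim$truth), "A*02:01",
                             split_seed = 2)
  # empty repertoire: baseline score logistic(v*y + b)
  empty <- make_donor("empty", list(), has_alpha = TRUE)
  expect_equal(unname(predict(m, empty)), plogis(m$v + m$b))
  # alpha-only model scored on a donor without alpha data: logistic(b)
  afeat <- clonotype_frame("alpha", "CAVRDSNYQLIW", "TRAV21")
  am <- structure(list(allele = "A*02:01", features = afeat, w = 2.5,
                       v = 0.7, b = -0.4, threshold = 0.5,
                       matching = "exact"),
                  class = "allele_classifier")
  noalpha <- make_donor("na", list(c("beta", "CASSF", "TRBV19")),
                        has_alpha = FALSE)
  expect_equal(unname(predict(am, noalpha)), plogis(-0.4))
  expect_error(predict_cohort(list(), sim$cohort), "empty model list")
  calls <- predict_cohort(list(m), sim$cohort)
  expect_equal(nrow(calls), 80)
  expect_true(all(calls$call == (calls$prob >= 0.5)))
})

test_that("trained models survive a JSON round trip", {
  sim <- sep_cohort(44, n = 80)
  m <- fit_allele_classifier(sim$cohort,
                             truth_as_associations(sim$truth), "A*02:01",
                             split_seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$w, m$w, tolerance = 1e-12)
  expect_equal(predict(back, sim$cohort), predict(m, sim$cohort),
               tolerance = 1e-12)
  # summary/coef methods are consistent with the stored weights
  expect_equal(unname(coef(m)[1]), m$b)
  s <- summary(m)
  expect_equal(s$heldout_auc, m$heldout_auc)
})
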