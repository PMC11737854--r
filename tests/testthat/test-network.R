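assoc_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], cdr3_aa = r[[2]], v_family = r[[3]],
               allele = r[[4]], stringsAsFactors = FALSE)))
}

test_that("edges require same chain, V family, length and Hamming distance <= 1", {
  rec <- assoc_rows(list("beta", "CASSLGETQYF", "TRBV19", "A*02:01"),
                    list("beta", "CASSLGDTQYF", "TRBV19", "A*02:01"),
                    list("beta", "CASSIRSSYEQYF", "TRBV19", "B*07:02"))
  net <- build_network(rec)
  expect_equal(nrow(net$edges), 1)
  expect_equal(nrow(net$components), 2)
  # identical CDR3, different V family: no edge
  rec2 <- assoc_rows(list("beta", "CASSLGETQYF", "TRBV19", "A*02:01"),
                     list("beta", "CASSLGETQYF", "TRBV5", "A*02:01"))
  expect_equal(nrow(build_network(rec2)$edges), 0)
  # same sequence, different chain tag: no edge
  rec3 <- assoc_rows(list("beta", "CASSLGETQYF", "TRBV19", "A*02:01"),
                     list("beta", "CFSSLGETQYA", "TRBV19", "A*02:01"),
                     list("beta", "CASSAAAAQYF", "TRBV19", "A*02:01"))
  net3 <- build_network(rec3)   # all pairwise distance >= 2
  expect_equal(nrow(net3$edges), 0)
  expect_equal(nrow(net3$components), 3)
})

test_that("network construction is invariant to input row order", {
  set.seed(5)
  sim <- simulate_cohort(sim_config(n_donors = 10, n_background = 60, seed = 9))
  cl <- do.call(rbind, lapply(sim$cohort$donors, `[[`, "clonotypes"))
  cl <- cl[!duplicated(tcrhla:::clonotype_key(cl)), ]
  rec <- data.frame(cl, allele = "A*02:01", stringsAsFactors = FALSE)
  n1 <- build_network(rec)
  n2 <- build_network(rec[sample(nrow(rec)), ])
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
})

test_that("component purity is 1 for single-allele inputs and majority-based otherwise", {
  rec <- assoc_rows(list("beta", "CASSLGETQYF", "TRBV19", "A*02:01"),
                    list("beta", "CASSLGDTQYF", "TRBV19", "A*02:01"),
                    list("beta", "CASSLGDTQYA", "TRBV19", "B*07:02"))
  net <- build_network(rec)
  expect_equal(nrow(net$components), 1)
  expect_equal(net$components$majority_allele, "A*02:01")
  expect_equal(net$components$purity, 2 / 3)
  single <- build_network(assoc_rows(
    list("beta", "CASSA", "TRBV19", "A*02:01"),
    list("beta", "CASSK", "TRBV19", "A*02:01")))
  expect_true(all(single$components$purity == 1))
  # a clonotype associated with two alleles keeps both labels on one node
  multi <- build_network(assoc_rows(
    list("beta", "CASSA", "TRBV19", "A*02:01"),
    list("beta", "CASSA", "TRBV19", "B*07:02")))
  expect_equal(nrow(multi$nodes), 1)
  expect_equal(multi$nodes$alleles, "A*02:01,B*07:02")
})

test_that("epitope annotation joins on exact CDR3 + V family", {
  net <- build_network(assoc_rows(
    list("beta", "CASSLGETQYF", "TRBV19", "A*02:01"),
    list("beta", "CASSIRSSYEQYF", "TRBV5", "B*07:02")))
  ref <- data.frame(cdr3_aa = c("CASSLGETQYF", "CASSLGETQYF", ""),
                    v_family = c("TRBV19", "TRBV9", "TRBV19"),
                    epitope = c("GILGFVFTL", "NLVPMVATV", "x"),
                    stringsAsFactors = FALSE)
  expect_message(ann <- annotate_epitopes(net, ref), "1 malformed")
  hit <- ann$nodes$epitopes[ann$nodes$cdr3_aa == "CASSLGETQYF"]
  expect_equal(hit, "GILGFVFTL")   # same CDR3, wrong V family does not attach
  expect_equal(ann$nodes$epitopes[ann$nodes$cdr3_aa == "CASSIRSSYEQYF"], "")
  # empty reference leaves annotations empty
  ann0 <- annotate_epitopes(net, ref[0, ])
  expect_true(all(ann0$nodes$epitopes == ""))
  # network export writes both files
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  write_network(ann, ep, np)
  expect_true(file.exists(ep) && file.exists(np))
})

test_that("CDR3 length profiles are normalized and detect planted shifts", {
  bg <- clonotype_frame("beta", tcrhla:::random_cdr3(300, len = 14), "TRBV19")
  same <- cdr3_length_profile(bg, bg)
  expect_equal(same$beta$lengths$subset_freq, same$beta$lengths$background_freq)
  expect_gte(same$beta$test$p.value, 0.5)
  # subset planted 2 aa shorter
  sub <- clonotype_frame("beta", tcrhla:::random_cdr3(200, len = 12), "TRBV19")
  prof <- cdr3_length_profile(sub, bg)
  expect_lt(prof$beta$subset_mean, prof$beta$background_mean)
  # single-length subset: histogram mass 1 at that length
  one <- clonotype_frame("beta", "CASSLGETQYF", "TRBV19")
  p1 <- cdr3_length_profile(one, bg)
  expect_equal(sum(p1$beta$lengths$subset_freq), 1)
  expect_equal(p1$beta$lengths$subset_freq[p1$beta$lengths$length == 11], 1)
})

test_that("V usage enrichment reports complete per-family frequencies", {
  set.seed(2)
  sub <- clonotype_frame("beta", tcrhla:::random_cdr3(100),
                         sample(c("TRBV19", "TRBV5"), 100, TRUE, c(0.5, 0.5)))
  bg <- clonotype_frame("beta", tcrhla:::random_cdr3(1000),
                        sample(c("TRBV19", "TRBV5", "TRBV9"), 1000, TRUE,
                               c(0.1, 0.45, 0.45)))
  enr <- v_usage_enrichment(sub, bg)
  expect_equal(sum(enr$subset_freq), 1)
  expect_equal(sum(enr$background_freq), 1)
  r19 <- enr$ratio[enr$v_family == "TRBV19"]
  expect_gt(r19, 3)            # planted 50% vs 10% composition
  # family absent from the subset is reported with frequency 0
  expect_equal(enr$subset_freq[enr$v_family == "TRBV9"], 0)
  ident <- v_usage_enrichment(bg, bg)
  expect_true(all(ident$ratio == 1))
})

test_that("repertoire V-usage comparison matches exact enumeration and flags ties", {
  set.seed(31)
  # exact U-distribution p for tiny groups with distinct values
  for (i in 1:10) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    vals <- sample(seq(0.01, 0.99, by = 0.01), na + nb)
    a <- matrix(vals[1:na], ncol = 1, dimnames = list(NULL, "TRBV19"))
    b <- matrix(vals[(na + 1):(na + nb)], ncol = 1,
                dimnames = list(NULL, "TRBV19"))
    res <- compare_repertoire_v_usage(a, b)
    expect_equal(res$p_raw, mw_enum_oracle(drop(a), drop(b)), tolerance = 1e-12)
  }
  # constant identical values in both groups: p = 1 with a tie flag
  a <- matrix(0.2, 3, 1, dimnames = list(NULL, "TRBV19"))
  res <- compare_repertoire_v_usage(a, a)
  expect_equal(res$p_raw, 1)
  expect_true(res$tie_flag)
  expect_error(compare_repertoire_v_usage(a[1, , drop = FALSE], a), "2 donors")
})

test_that("a planted V-usage shift is detected in the shifted family only", {
  set.seed(77)
  fams <- c("TRBV19", "TRBV5", "TRBV9")
  draw_group <- function(n, probs) {
    t(vapply(seq_len(n), function(i) {
      counts <- rmultinom(1, 200, probs)[, 1]
      counts / sum(counts)
    }, numeric(3))) |> `colnames<-`(fams)
  }
  # shift planted in TRBV19; TRBV5 kept at the same expected frequency
  pos <- draw_group(25, c(0.3, 0.2, 0.5))
  neg <- draw_group(25, c(0.1, 0.2, 0.7))
  res <- compare_repertoire_v_usage(pos, neg)
  expect_lt(res$p_adj[res$v_family == "TRBV19"], 0.01)
  expect_gt(res$p_adj[res$v_family == "TRBV5"], 0.05)
  # null replicate calibration: roughly uniform p-values
  set.seed(78)
  p0 <- c(0.2, 0.3, 0.5)
  rej <- mean(replicate(200, {
    res0 <- compare_repertoire_v_usage(draw_group(8, p0), draw_group(8, p0))
    res0$p_raw[1] < 0.05
  }))
  expect_lt(rej, 0.11)
})
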