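#' Two-tailed Fisher exact test p-value for 2x2 tables
#'
#' Uses the point-probability definition of the two-sided p-value: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of tables whose point probability is at most that of the observed table
#' (up to a relative tolerance of 1e-7, as in `stats::fisher.test`).
#' Vectorized over tables so that large association scans stay fast;
#' `stats::fisher.test` returns identical values table by table.
#'
#' @param n_pp donors with both the clonotype and the allele.
#' @param n_pn donors with the clonotype but not the allele.
#' @param n_np donors with the allele but not the clonotype.
#' @param n_nn donors with neither.
#' @return p-values in (0, 1]; degenerate margins give 1.
#' @export
fisher_two_tailed <- function(n_pp, n_pn, n_np, n_nn) {
  counts <- cbind(n_pp, n_pn, n_np, n_nn)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) < 1)) stop("table total must be >= 1")
  vapply(seq_len(nrow(counts)), function(r) {
    a <- counts[r, 1]; b <- counts[r, 2]; c <- counts[r, 3]; d <- counts[r, 4]
    m <- a + b; nn <- c + d; k <- a + c
    lo <- max(0, k - nn); hi <- min(k, m)
    if (lo == hi) return(1)
    probs <- stats::dhyper(lo:hi, m, nn, k)
    min(1, sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (via `stats::p.adjust`), returned in the
#' original order; monotone nondecreasing in the sorted order and capped at 1.
#'
#' @param p_values numeric vector in \[0,1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0,1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# all (clonotype, allele) tests for one allele-status vector over one
# occurrence matrix; returns count columns + p_raw, no multiplicity control
allele_scan <- function(occ, status) {
  mat <- occ$matrix
  n <- nrow(mat)
  carriers <- Matrix::colSums(mat)
  n_allele <- sum(status)
  n_pp <- as.numeric(Matrix::crossprod(mat, status))
  n_pn <- carriers - n_pp
  n_np <- n_allele - n_pp
  n_nn <- n - carriers - n_np
  data.frame(occ$clonotypes,
             n_pp = n_pp, n_pn = n_pn, n_np = n_np, n_nn = n_nn,
             p_raw = fisher_two_tailed(n_pp, n_pn, n_np, n_nn),
             stringsAsFactors = FALSE)
}

# deterministic record ordering: p_adj (if present), p_raw, then labels
order_association_records <- function(rec) {
  if ("p_adj" %in% names(rec)) {
    order(rec$p_adj, rec$p_raw, rec$allele, rec$chain, rec$v_family, rec$cdr3_aa)
  } else {
    order(rec$p_raw, rec$allele, rec$chain, rec$v_family, rec$cdr3_aa)
  }
}

#' All (clonotype, allele) association tests in a cohort
#'
#' Runs a two-tailed Fisher exact test for every retained public clonotype
#' against every tested allele. For alpha-chain clonotypes only donors with
#' alpha-chain data enter the 2x2 table; beta-chain tests use all donors.
#' Publicness is counted across the full cohort.
#'
#' @param cohort a fully HLA-typed `tcr_cohort` with at least 2 donors.
#' @param min_publicness minimum donors sharing a clonotype (default 3).
#' @param alleles alleles to test; default all alleles observed in the
#'   cohort. Alleles carried by fewer than `min_carriers` donors are skipped.
#' @param min_carriers minimum allele carriers for a testable allele
#'   (default 5); alleles with 0 carriers are never tested.
#' @return data.frame of association records: `chain`, `cdr3_aa`, `v_family`,
#'   `allele`, counts `n_pp`/`n_pn`/`n_np`/`n_nn`, `p_raw`, `direction`
#'   (`enriched` iff the sample odds ratio exceeds 1).
#' @export
association_tests <- function(cohort, min_publicness = 3, alleles = NULL,
                              min_carriers = 5) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  if (length(cohort$donors) < 2) stop("cohort must contain at least 2 donors")
  hla <- cohort_hla(cohort)
  if (any(vapply(hla, is.null, logical(1)))) {
    stop("every donor must be HLA-typed for association discovery")
  }
  if (is.null(alleles)) {
    alleles <- sort(unique(unlist(hla)))
  } else {
    alleles <- sort(unique(normalize_hla(alleles)))
  }
  carrier_n <- vapply(alleles, function(a)
    sum(vapply(hla, function(h) a %in% h, logical(1))), numeric(1))
  skipped <- alleles[carrier_n < min_carriers | carrier_n == 0]
  if (length(skipped)) {
    message("skipping ", length(skipped), " allele(s) with <", min_carriers,
            " carriers")
  }
  alleles <- alleles[carrier_n >= max(min_carriers, 1)]
  if (!length(alleles)) return(empty_association_frame())

  occ <- occurrence_matrix(cohort, min_publicness = min_publicness)
  has_alpha <- cohort_has_alpha(cohort)
  is_alpha_col <- occ$clonotypes$chain == "alpha"
  occ_beta <- list(matrix = occ$matrix[, !is_alpha_col, drop = FALSE],
                   clonotypes = occ$clonotypes[!is_alpha_col, , drop = FALSE])
  occ_alpha <- list(matrix = occ$matrix[has_alpha, is_alpha_col, drop = FALSE],
                    clonotypes = occ$clonotypes[is_alpha_col, , drop = FALSE])

  res <- lapply(alleles, function(a) {
    status <- vapply(hla, function(h) a %in% h, logical(1))
    parts <- list()
    if (ncol(occ_beta$matrix)) {
      parts$beta <- cbind(allele_scan(occ_beta, status), allele = a)
    }
    if (ncol(occ_alpha$matrix) && sum(status[has_alpha]) > 0) {
      parts$alpha <- cbind(allele_scan(occ_alpha, status[has_alpha]), allele = a)
    }
    do.call(rbind, parts)
  })
  rec <- do.call(rbind, res)
  if (is.null(rec) || !nrow(rec)) return(empty_association_frame())
  rec$direction <- ifelse(rec$n_pp * rec$n_nn > rec$n_pn * rec$n_np,
                          "enriched", "depleted")
  rec <- rec[order_association_records(rec), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

empty_association_frame <- function() {
  data.frame(chain = character(), cdr3_aa = character(), v_family = character(),
             n_pp = numeric(), n_pn = numeric(), n_np = numeric(),
             n_nn = numeric(), p_raw = numeric(), allele = character(),
             direction = character(), p_adj = numeric(),
             stringsAsFactors = FALSE)
}

#' Discover HLA-associated clonotypes at a fixed false discovery rate
#'
#' Tests every retained public (clonotype, allele) pair with a two-tailed
#' Fisher exact test and controls multiplicity with Benjamini-Hochberg over
#' the full set of tests in this run (jointly across alleles and chains).
#' Records with adjusted p-value at most `q` are returned, sorted by adjusted
#' then raw p-value, with deterministic tie-breaking.
#'
#' @inheritParams association_tests
#' @param q FDR level; default 0.01 (a 1\% false discovery rate).
#' @return data.frame of significant association records, with `p_adj` added.
#' @export
discover <- function(cohort, q = 0.01, min_publicness = 3, alleles = NULL,
                     min_carriers = 5) {
  stopifnot(q > 0, q < 1)
  rec <- association_tests(cohort, min_publicness = min_publicness,
                           alleles = alleles, min_carriers = min_carriers)
  if (!nrow(rec)) return(rec)
  rec$p_adj <- bh_adjust(rec$p_raw)
  rec <- rec[rec$p_adj <= q, , drop = FALSE]
  rec <- rec[order_association_records(rec), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write an association list as TSV
#'
#' Column layout mirrors the published association tables: CDR3, V family,
#' chain, allele, total clonotype carriers, carriers also positive for the
#' allele, raw p, `p_BH`, direction.
#'
#' @param records association data.frame from [discover()].
#' @param path output path.
#' @export
write_associations <- function(records, path) {
  out <- data.frame(cdr3_aa = records$cdr3_aa, v_family = records$v_family,
                    chain = records$chain, allele = records$allele,
                    n_carriers_total = records$n_pp + records$n_pn,
                    n_carriers_allele_positive = records$n_pp,
                    p_raw = records$p_raw,
                    p_BH = if ("p_adj" %in% names(records)) records$p_adj else NA,
                    direction = records$direction, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association list written by [write_associations()]
#' @param path TSV path.
#' @return association data.frame (counts reduced to the columns stored).
#' @export
read_associations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(chain = tab$chain, cdr3_aa = tab$cdr3_aa, v_family = tab$v_family,
             allele = tab$allele,
             n_pp = tab$n_carriers_allele_positive,
             n_pn = tab$n_carriers_total - tab$n_carriers_allele_positive,
             n_np = NA_real_, n_nn = NA_real_,
             p_raw = tab$p_raw, p_adj = tab$p_BH, direction = tab$direction,
             stringsAsFactors = FALSE)
}
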