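DEFAULT_BETA_V <- paste0("TRBV", c(2, 4, 5, 6, 7, 9, 10, 11, 12, 15, 19, 20,
                                   25, 27, 28, 29, 30))
DEFAULT_ALPHA_V <- paste0("TRAV", c(1, 2, 3, 5, 8, 9, 12, 13, 17, 19, 21, 24,
                                    26, 29, 35, 38, 41))

#' Simulation configuration for synthetic HLA-typed cohorts
#'
#' Describes a cohort of donors whose HLA alleles are drawn independently per
#' allele (no linkage) and whose repertoires contain allele-agnostic
#' background clonotypes plus, optionally, planted clonotypes whose presence
#' probability is enriched in allele-positive donors. Alpha-chain clonotypes
#' appear only in donors whose alpha chain was sequenced.
#'
#' @param n_donors number of donors.
#' @param alleles data.frame with columns `allele` (4-digit codes) and `freq`
#'   (population frequency in \[0,1\]); each donor is positive for an allele
#'   with that probability, subject to at most 2 alleles per class-I locus.
#' @param n_background number of background clonotypes, present i.i.d. in
#'   each donor with probability `background_sharing`.
#' @param background_sharing per-donor presence probability of background
#'   clonotypes.
#' @param planted `NULL` or a data.frame with columns `allele`,
#'   `n_clonotypes`, `p_pos`, `p_neg`: each planted clonotype is present with
#'   probability `p_pos` in carriers of its allele and `p_neg` otherwise
#'   (`p_pos >= p_neg`; equality marks a null construction).
#' @param alpha_fraction fraction of donors with alpha-chain data.
#' @param alpha_clonotype_fraction fraction of simulated clonotypes assigned
#'   to the alpha chain.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 100,
                       alleles = data.frame(
                         allele = c("A*02:01", "A*01:01", "B*07:02", "B*08:01"),
                         freq = 0.5),
                       n_background = 500,
                       background_sharing = 0.1,
                       planted = NULL,
                       alpha_fraction = 0.5,
                       alpha_clonotype_fraction = 0.25,
                       seed = 1) {
  stopifnot(n_donors >= 0, n_background >= 0,
            background_sharing >= 0, background_sharing <= 1,
            alpha_fraction >= 0, alpha_fraction <= 1,
            alpha_clonotype_fraction >= 0, alpha_clonotype_fraction <= 1)
  alleles$allele <- normalize_hla(alleles$allele)
  if (any(alleles$freq < 0 | alleles$freq > 1)) {
    stop("allele frequencies must be in [0,1]")
  }
  if (anyDuplicated(alleles$allele)) stop("duplicated allele in panel")
  loc <- hla_locus(alleles$allele)
  forced <- tapply(alleles$freq == 1, loc, sum)
  if (any(forced[names(forced) %in% CLASS_I_LOCI] > 2, na.rm = TRUE)) {
    stop("infeasible allele panel: >2 alleles forced (frequency 1) at one class-I locus")
  }
  if (!is.null(planted)) {
    stopifnot(all(c("allele", "n_clonotypes", "p_pos", "p_neg") %in% names(planted)))
    planted$allele <- normalize_hla(planted$allele)
    if (any(planted$p_pos < 0 | planted$p_pos > 1 |
            planted$p_neg < 0 | planted$p_neg > 1)) {
      stop("planted presence probabilities must be in [0,1]")
    }
    if (any(planted$p_pos < planted$p_neg)) {
      stop("planted signal requires p_pos >= p_neg")
    }
    if (!all(planted$allele %in% alleles$allele)) {
      stop("planted allele(s) not in the allele panel")
    }
  }
  structure(list(n_donors = as.integer(n_donors), alleles = alleles,
                 n_background = as.integer(n_background),
                 background_sharing = background_sharing, planted = planted,
                 alpha_fraction = alpha_fraction,
                 alpha_clonotype_fraction = alpha_clonotype_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read/write a simulation config as JSON
#' @param path file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- x[intersect(names(x), names(formals(sim_config)))]
  x$alleles <- as.data.frame(x$alleles, stringsAsFactors = FALSE)
  if (!is.null(x$planted) && length(x$planted)) {
    x$planted <- as.data.frame(x$planted, stringsAsFactors = FALSE)
  } else {
    x$planted <- NULL
  }
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# random CDR3 amino-acid strings: length 8-20, start C, end F
random_cdr3 <- function(n, len = NULL) {
  if (is.null(len)) {
    lens <- 8:20
    w <- stats::dnorm(lens, mean = 14.5, sd = 2)
    len <- sample(lens, n, replace = TRUE, prob = w)
  } else {
    len <- rep_len(len, n)
  }
  vapply(len, function(L) {
    paste0("C", paste(sample(AA_ALPHABET, L - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

# catalog of n distinct clonotypes with the configured alpha fraction
random_clonotype_catalog <- function(n, alpha_fraction) {
  if (n == 0) return(clonotype_frame())
  n_alpha <- round(n * alpha_fraction)
  chain <- c(rep("alpha", n_alpha), rep("beta", n - n_alpha))
  repeat {
    cdr3 <- random_cdr3(n)
    vfam <- ifelse(chain == "alpha",
                   sample(DEFAULT_ALPHA_V, n, replace = TRUE),
                   sample(DEFAULT_BETA_V, n, replace = TRUE))
    cl <- clonotype_frame(chain, cdr3, vfam)
    if (!anyDuplicated(clonotype_key(cl))) return(cl)
  }
}

#' Simulate an HLA-typed cohort with planted TCR-HLA associations
#'
#' Every source of randomness is driven by `config$seed`; identical configs
#' produce identical cohorts.
#'
#' @param config a [sim_config()].
#' @param name cohort name.
#' @return A list with elements `cohort` (a fully HLA-typed `tcr_cohort`) and
#'   `truth` (data.frame of planted clonotype-allele links with columns
#'   `chain`, `cdr3_aa`, `v_family`, `allele`, `p_pos`, `p_neg`, `null` —
#'   `null` is `TRUE` where `p_pos == p_neg`, i.e. no real signal).
#' @export
simulate_cohort <- function(config, name = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_donors
  if (n == 0) stop("empty cohort: n_donors must be >= 1")
  set.seed(config$seed)

  # allele draw, independent per allele, then enforce <=2 per class-I locus
  nA <- nrow(config$alleles)
  allele_mat <- matrix(stats::runif(n * nA) < rep(config$alleles$freq, each = n),
                       nrow = n, ncol = nA)
  loci <- hla_locus(config$alleles$allele)
  for (L in unique(loci[loci %in% CLASS_I_LOCI])) {
    cols <- which(loci == L)
    if (length(cols) <= 2) next
    for (i in seq_len(n)) {
      pos <- cols[allele_mat[i, cols]]
      if (length(pos) > 2) {
        drop <- sample(pos, length(pos) - 2)
        allele_mat[i, drop] <- FALSE
      }
    }
  }

  has_alpha <- rep(FALSE, n)
  n_alpha_donors <- round(config$alpha_fraction * n)
  if (n_alpha_donors > 0) has_alpha[sample.int(n, n_alpha_donors)] <- TRUE

  n_planted <- if (is.null(config$planted)) 0L else sum(config$planted$n_clonotypes)
  catalog <- random_clonotype_catalog(config$n_background + n_planted,
                                      config$alpha_clonotype_fraction)
  # planted clonotypes are drawn from the catalog tail so background/planted
  # share the same chain and sequence statistics
  if (n_planted > 0) {
    planted_idx <- sample.int(nrow(catalog), n_planted)
  } else {
    planted_idx <- integer(0)
  }
  bg_idx <- setdiff(seq_len(nrow(catalog)), planted_idx)

  presence <- matrix(FALSE, nrow = n, ncol = nrow(catalog))
  if (length(bg_idx)) {
    presence[, bg_idx] <- stats::runif(n * length(bg_idx)) < config$background_sharing
  }
  truth <- NULL
  if (n_planted > 0) {
    at <- integer(0); ptr <- 1
    rows <- list()
    for (r in seq_len(nrow(config$planted))) {
      pl <- config$planted[r, ]
      a_col <- match(pl$allele, config$alleles$allele)
      carriers <- allele_mat[, a_col]
      idx <- planted_idx[ptr:(ptr + pl$n_clonotypes - 1)]
      ptr <- ptr + pl$n_clonotypes
      p <- ifelse(carriers, pl$p_pos, pl$p_neg)
      presence[, idx] <- stats::runif(n * length(idx)) < rep(p, length(idx))
      rows[[r]] <- data.frame(catalog[idx, , drop = FALSE],
                              allele = pl$allele, p_pos = pl$p_pos,
                              p_neg = pl$p_neg, null = pl$p_pos == pl$p_neg,
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(chain = character(), cdr3_aa = character(),
                        v_family = character(), allele = character(),
                        p_pos = numeric(), p_neg = numeric(), null = logical(),
                        stringsAsFactors = FALSE)
  }

  # alpha clonotypes require alpha sequencing
  alpha_cols <- which(catalog$chain == "alpha")
  if (length(alpha_cols)) presence[!has_alpha, alpha_cols] <- FALSE

  donors <- lapply(seq_len(n), function(i) {
    new_donor(sprintf("sim%04d", i),
              catalog[presence[i, ], , drop = FALSE],
              cohort = name, has_alpha = has_alpha[i],
              hla = config$alleles$allele[allele_mat[i, ]])
  })
  list(cohort = new_cohort(donors, name = name), truth = truth)
}

#' Simulate an untyped cohort, retaining the hidden typing as truth
#'
#' Same generative process as [simulate_cohort()] (identical output for the
#' same config), but the returned cohort carries no HLA typings; the true
#' typings are returned separately for evaluation only.
#'
#' @param config a [sim_config()].
#' @param name cohort name.
#' @return A list with `cohort` (HLA fields `NULL`), `hidden_hla` (named list
#'   donor_id -> true allele codes) and `truth` (planted-link table).
#' @export
simulate_untyped <- function(config, name = "synthetic_untyped") {
  sim <- simulate_cohort(config, name = name)
  hidden <- lapply(sim$cohort$donors, `[[`, "hla")
  donors <- lapply(sim$cohort$donors, function(d) { d$hla <- NULL; d })
  list(cohort = new_cohort(unname(donors), name = name),
       hidden_hla = hidden, truth = sim$truth)
}
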