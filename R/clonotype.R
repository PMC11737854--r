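#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

HLA_LOCI <- c("A", "B", "C", "DPA1", "DPB1", "DQA1", "DQB1",
              "DRB1", "DRB3", "DRB4", "DRB5")
CLASS_I_LOCI <- c("A", "B", "C")

#' Construct a validated clonotype table
#'
#' A clonotype is the unit of publicness and association testing: a chain tag
#' (alpha/beta), a CDR3 amino-acid sequence and a V-gene family. Identity is
#' the triple `(chain, cdr3_aa, v_family)`.
#'
#' @param chain character vector, `"alpha"` or `"beta"`.
#' @param cdr3_aa uppercase CDR3 amino-acid sequences (20-letter alphabet).
#' @param v_family V-gene family names, e.g. `"TRBV19"`; must begin with
#'   `TRAV` for alpha chains and `TRBV` for beta chains.
#' @return A `data.frame` with columns `chain`, `cdr3_aa`, `v_family`.
#' @export
clonotype_frame <- function(chain = character(), cdr3_aa = character(),
                            v_family = character()) {
  chain <- as.character(chain)
  cdr3_aa <- as.character(cdr3_aa)
  v_family <- as.character(v_family)
  n <- max(length(chain), length(cdr3_aa), length(v_family))
  if (n > 0) {
    chain <- rep_len(chain, n)
    cdr3_aa <- rep_len(cdr3_aa, n)
    v_family <- rep_len(v_family, n)
  }
  bad_chain <- !chain %in% c("alpha", "beta")
  if (any(bad_chain)) {
    stop("invalid chain value(s): ", paste(unique(chain[bad_chain]), collapse = ", "))
  }
  if (any(!nzchar(cdr3_aa)) || any(!is_productive_cdr3(cdr3_aa))) {
    stop("cdr3_aa must be non-empty and restricted to the 20 amino-acid letters")
  }
  pref <- ifelse(chain == "alpha", "TRAV", "TRBV")
  if (any(substr(v_family, 1, 4) != pref)) {
    stop("v_family prefix must match chain (TRAV for alpha, TRBV for beta)")
  }
  data.frame(chain = chain, cdr3_aa = cdr3_aa, v_family = v_family,
             stringsAsFactors = FALSE)
}

#' Test whether CDR3 amino-acid strings are productive
#'
#' Productive means non-empty and composed only of the 20 standard uppercase
#' amino-acid letters; stop (`*`), frameshift (`_`) or lowercase characters
#' mark nonproductive rearrangements and fail the test.
#'
#' @param cdr3_aa character vector.
#' @return logical vector.
#' @export
is_productive_cdr3 <- function(cdr3_aa) {
  nzchar(cdr3_aa) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", cdr3_aa)
}

#' Normalize a V call to family level
#'
#' Strips allele and gene-subgroup suffixes so that all V calls use one
#' convention: `"TRBV19-01*01"` and `"TRBV19-1"` both become `"TRBV19"`.
#' Multiple comma-separated calls keep the first. Idempotent.
#'
#' @param v_call character vector of V calls.
#' @return character vector of V family names.
#' @export
normalize_v_family <- function(v_call) {
  v <- sub(",.*$", "", as.character(v_call))
  v <- sub("[*/].*$", "", v)
  sub("-.*$", "", v)
}

#' Normalize an HLA allele code to 4-digit resolution
#'
#' Accepts codes like `"A*02:01"` or higher-resolution codes like
#' `"A*02:01:01:02"` (truncated to the first two fields). Two-digit codes
#' (`"A*02"`) are rejected: the method requires protein-level (4-digit)
#' typing. Idempotent on already-normalized codes.
#'
#' @param code character vector of allele codes.
#' @return character vector of codes in `LOCUS*GG:PP` form.
#' @export
normalize_hla <- function(code) {
  code <- trimws(as.character(code))
  m <- regmatches(code, regexec("^([A-Z]+[0-9]*)\\*([0-9]{2,}):([0-9]{2,})", code))
  out <- vapply(seq_along(code), function(i) {
    g <- m[[i]]
    if (length(g) == 0) {
      stop("unparseable HLA allele code (4-digit resolution required): '",
           code[i], "'")
    }
    if (!g[2] %in% HLA_LOCI) {
      stop("unknown HLA locus in allele code: '", code[i], "'")
    }
    paste0(g[2], "*", g[3], ":", g[4])
  }, character(1))
  out
}

#' HLA locus of an allele code
#' @param code allele codes at 4-digit resolution.
#' @return character vector of loci (`"A"`, `"DRB1"`, ...).
#' @export
hla_locus <- function(code) {
  sub("\\*.*$", "", as.character(code))
}

#' MHC class of an HLA allele
#' @param code allele codes.
#' @return `"I"` for loci A/B/C, `"II"` otherwise.
#' @export
hla_mhc_class <- function(code) {
  ifelse(hla_locus(code) %in% CLASS_I_LOCI, "I", "II")
}

# canonical clonotype key used for matching and matrix columns
clonotype_key <- function(clonotypes) {
  paste(clonotypes$chain, clonotypes$v_family, clonotypes$cdr3_aa, sep = "|")
}

# canonical ordering: (chain, v_family, cdr3_aa)
order_clonotypes <- function(clonotypes) {
  order(clonotypes$chain, clonotypes$v_family, clonotypes$cdr3_aa)
}

#' Construct a donor
#'
#' @param donor_id donor identifier, unique within a cohort.
#' @param clonotypes a clonotype `data.frame` (see [clonotype_frame()]);
#'   deduplicated on construction.
#' @param cohort cohort label.
#' @param has_alpha was the alpha chain sequenced for this donor? When `NULL`
#'   (default) it is inferred from the presence of alpha-chain clonotypes; an
#'   explicit flag always wins, because alpha sequencing may have yielded no
#'   public clonotypes.
#' @param hla optional character vector of HLA allele codes (normalized to
#'   4-digit resolution); at most 2 alleles per class-I locus.
#' @return An object of class `tcr_donor`.
#' @export
new_donor <- function(donor_id, clonotypes = clonotype_frame(), cohort = "",
                      has_alpha = NULL, hla = NULL) {
  clonotypes <- clonotype_frame(clonotypes$chain, clonotypes$cdr3_aa,
                                clonotypes$v_family)
  clonotypes <- clonotypes[!duplicated(clonotype_key(clonotypes)), , drop = FALSE]
  rownames(clonotypes) <- NULL
  if (is.null(has_alpha)) {
    has_alpha <- any(clonotypes$chain == "alpha")
  }
  if (!is.null(hla)) {
    hla <- sort(unique(normalize_hla(hla)))
    loc <- hla_locus(hla)
    tab <- table(loc[loc %in% CLASS_I_LOCI])
    if (any(tab > 2)) {
      stop("donor '", donor_id, "' has >2 alleles at class-I locus ",
           paste(names(tab)[tab > 2], collapse = ", "))
    }
  }
  structure(list(donor_id = as.character(donor_id), cohort = as.character(cohort),
                 clonotypes = clonotypes, has_alpha = isTRUE(has_alpha),
                 hla = hla),
            class = "tcr_donor")
}

#' @export
print.tcr_donor <- function(x, ...) {
  cat("<tcr_donor>", x$donor_id,
      sprintf("(%d clonotypes, alpha %s, %s)\n", nrow(x$clonotypes),
              if (x$has_alpha) "sequenced" else "absent",
              if (is.null(x$hla)) "untyped" else
                sprintf("%d HLA alleles", length(x$hla))))
  invisible(x)
}

#' Construct a cohort of donors
#'
#' Donor ids must be unique; duplicated samples from the same donor keep the
#' first encountered (later duplicates are dropped with a message).
#'
#' @param donors list of `tcr_donor` objects.
#' @param name cohort name.
#' @return An object of class `tcr_cohort`.
#' @export
new_cohort <- function(donors, name = "cohort") {
  stopifnot(all(vapply(donors, inherits, logical(1), "tcr_donor")))
  ids <- vapply(donors, `[[`, character(1), "donor_id")
  dup <- duplicated(ids)
  if (any(dup)) {
    message("excluding ", sum(dup), " duplicated donor sample(s): ",
            paste(unique(ids[dup]), collapse = ", "))
    donors <- donors[!dup]
    ids <- ids[!dup]
  }
  names(donors) <- ids
  structure(list(name = as.character(name), donors = donors),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  n <- length(x$donors)
  typed <- sum(vapply(x$donors, function(d) !is.null(d$hla), logical(1)))
  nalpha <- sum(vapply(x$donors, `[[`, logical(1), "has_alpha"))
  cat(sprintf("<tcr_cohort> '%s': %d donors (%d HLA-typed, %d with alpha data)\n",
              x$name, n, typed, nalpha))
  invisible(x)
}

#' @export
length.tcr_cohort <- function(x) length(x$donors)

cohort_donor_ids <- function(cohort) {
  vapply(cohort$donors, `[[`, character(1), "donor_id")
}

cohort_has_alpha <- function(cohort) {
  vapply(cohort$donors, `[[`, logical(1), "has_alpha")
}

cohort_hla <- function(cohort) {
  lapply(cohort$donors, `[[`, "hla")
}

# logical vector: does each donor carry `allele`
cohort_allele_status <- function(cohort, allele) {
  allele <- normalize_hla(allele)
  vapply(cohort$donors, function(d) {
    if (is.null(d$hla)) stop("donor '", d$donor_id, "' is not HLA-typed")
    allele %in% d$hla
  }, logical(1))
}

#' Merge cohorts into one
#' @param ... `tcr_cohort` objects.
#' @param name name for the merged cohort.
#' @return A `tcr_cohort`.
#' @export
merge_cohorts <- function(..., name = "merged") {
  cohorts <- list(...)
  new_cohort(unlist(lapply(cohorts, `[[`, "donors"), recursive = FALSE),
             name = name)
}
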