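#' Read a per-donor clonotype table
#'
#' Reads one donor's repertoire from a tab-separated file. Two layouts are
#' supported:
#' \describe{
#'   \item{`airr`}{AIRR Rearrangement-style columns `junction_aa`, `v_call`
#'     and `locus` (TRA/TRB) or `chain`.}
#'   \item{`simple`}{columns `chain` (alpha/beta), `cdr3_aa`, `v_family`.}
#' }
#' Nonproductive records (CDR3 containing stop `*`, frameshift `_`, lowercase
#' or non-amino-acid characters) are dropped, V calls are truncated to family
#' level, and the clonotype set is deduplicated.
#'
#' @param path path to a TSV file with a header row.
#' @param format `"airr"` or `"simple"`.
#' @param donor_id donor identifier to attach.
#' @param cohort cohort label to attach.
#' @param has_alpha optional explicit alpha-sequenced flag; overrides
#'   inference from content.
#' @return A `tcr_donor`.
#' @export
read_clonotype_table <- function(path, format = c("simple", "airr"),
                                 donor_id = basename(path), cohort = "",
                                 has_alpha = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "airr") {
    need <- c("junction_aa", "v_call")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("AIRR table is missing required column(s): ",
                           paste(miss, collapse = ", "))
    if ("locus" %in% names(tab)) {
      chain <- c(TRA = "alpha", TRB = "beta")[toupper(tab$locus)]
      if (anyNA(chain)) stop("unrecognized locus value(s): ",
                             paste(unique(tab$locus[is.na(chain)]), collapse = ", "))
    } else if ("chain" %in% names(tab)) {
      chain <- tab$chain
    } else {
      stop("AIRR table is missing required column(s): locus (or chain)")
    }
    cdr3 <- tab$junction_aa
    vfam <- normalize_v_family(tab$v_call)
  } else {
    need <- c("chain", "cdr3_aa", "v_family")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("simple clonotype table is missing required column(s): ",
                           paste(miss, collapse = ", "))
    chain <- tab$chain
    cdr3 <- tab$cdr3_aa
    vfam <- normalize_v_family(tab$v_family)
  }
  keep <- is_productive_cdr3(cdr3)
  if (!any(keep)) {
    warning("no productive clonotypes in ", path, "; returning an empty donor")
    return(new_donor(donor_id, clonotype_frame(), cohort, has_alpha = has_alpha))
  }
  new_donor(donor_id,
            clonotype_frame(chain[keep], cdr3[keep], vfam[keep]),
            cohort, has_alpha = has_alpha)
}

#' Write a donor's clonotypes in the simple TSV format
#'
#' Columns `chain`, `cdr3_aa`, `v_family`; reading the file back with
#' [read_clonotype_table()] reproduces the identical clonotype set.
#'
#' @param donor a `tcr_donor`.
#' @param path output path.
#' @export
write_clonotype_table <- function(donor, path) {
  utils::write.table(donor$clonotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an HLA typing table
#'
#' Accepts a tab- or comma-separated table with a `donor_id` column and
#' either a single `hla` column of comma-separated allele codes or wide
#' per-locus columns (any column other than `donor_id` is treated as holding
#' allele codes; empty cells are allowed). All codes are normalized to
#' 4-digit resolution; 2-digit codes are an error.
#'
#' @param path path to the typing table.
#' @param strict when `TRUE`, donors without at least one allele at each
#'   class-I locus (A, B, C) are excluded as incompletely typed.
#' @return A named list mapping `donor_id` to a character vector of allele
#'   codes.
#' @export
read_hla_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"donor_id" %in% names(tab)) stop("HLA table is missing column donor_id")
  allele_cols <- setdiff(names(tab), "donor_id")
  if (!length(allele_cols)) stop("HLA table has no allele columns")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    cells <- unlist(tab[i, allele_cols], use.names = FALSE)
    toks <- unlist(strsplit(as.character(cells), ","))
    toks <- trimws(toks)
    toks <- toks[nzchar(toks) & !is.na(toks)]
    alleles <- sort(unique(normalize_hla(toks)))
    loc <- hla_locus(alleles)
    tab1 <- table(loc[loc %in% CLASS_I_LOCI])
    if (any(tab1 > 2)) {
      stop("donor '", tab$donor_id[i], "': >2 alleles at class-I locus ",
           paste(names(tab1)[tab1 > 2], collapse = ", "))
    }
    alleles
  })
  names(out) <- as.character(tab$donor_id)
  if (strict) {
    complete <- vapply(out, function(a) {
      all(CLASS_I_LOCI %in% hla_locus(a))
    }, logical(1))
    if (any(!complete)) {
      message("excluding ", sum(!complete),
              " donor(s) with incomplete class-I typing: ",
              paste(names(out)[!complete], collapse = ", "))
      out <- out[complete]
    }
  }
  out
}

#' Write an HLA typing table
#' @param hla named list of allele-code vectors (as from [read_hla_table()]).
#' @param path output path (`.csv` or `.tsv`).
#' @export
write_hla_table <- function(hla, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(donor_id = names(hla),
                   hla = vapply(hla, paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Write a whole cohort as a combined clonotype TSV plus HLA table
#'
#' The clonotype file has columns `donor_id`, `cohort`, `has_alpha`, `chain`,
#' `cdr3_aa`, `v_family` (one row per donor clonotype; donors with empty
#' repertoires get a single row with empty clonotype fields). The HLA file is
#' written only for typed donors.
#'
#' @param cohort a `tcr_cohort`.
#' @param clonotype_path output TSV path for clonotypes.
#' @param hla_path optional output path for the HLA typing table.
#' @export
write_cohort <- function(cohort, clonotype_path, hla_path = NULL) {
  rows <- lapply(cohort$donors, function(d) {
    cl <- d$clonotypes
    if (!nrow(cl)) {
      cl <- data.frame(chain = "", cdr3_aa = "", v_family = "",
                       stringsAsFactors = FALSE)
    }
    data.frame(donor_id = d$donor_id, cohort = d$cohort,
               has_alpha = d$has_alpha, cl, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), clonotype_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(hla_path)) {
    typed <- Filter(function(d) !is.null(d$hla), cohort$donors)
    if (length(typed)) {
      write_hla_table(lapply(typed, `[[`, "hla"), hla_path)
    }
  }
  invisible(clonotype_path)
}

#' Read a cohort written by [write_cohort()]
#' @param clonotype_path combined clonotype TSV.
#' @param hla_path optional HLA typing table to attach.
#' @param name cohort name.
#' @param strict passed to [read_hla_table()].
#' @return A `tcr_cohort`.
#' @export
read_cohort <- function(clonotype_path, hla_path = NULL, name = "cohort",
                        strict = FALSE) {
  tab <- utils::read.delim(clonotype_path, stringsAsFactors = FALSE)
  need <- c("donor_id", "chain", "cdr3_aa", "v_family")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table is missing column(s): ",
                         paste(miss, collapse = ", "))
  hla <- if (!is.null(hla_path)) read_hla_table(hla_path, strict = strict) else NULL
  donors <- lapply(split(tab, factor(tab$donor_id, levels = unique(tab$donor_id))),
                   function(rows) {
    keep <- nzchar(rows$cdr3_aa) & !is.na(rows$cdr3_aa)
    cl <- clonotype_frame(rows$chain[keep], rows$cdr3_aa[keep],
                          normalize_v_family(rows$v_family[keep]))
    id <- rows$donor_id[1]
    new_donor(id, cl,
              cohort = if ("cohort" %in% names(rows)) rows$cohort[1] else "",
              has_alpha = if ("has_alpha" %in% names(rows))
                as.logical(rows$has_alpha[1]) else NULL,
              hla = if (!is.null(hla) && id %in% names(hla)) hla[[id]] else NULL)
  })
  if (!is.null(hla) && strict) {
    donors <- Filter(function(d) !is.null(d$hla), donors)
  }
  new_cohort(unname(donors), name = name)
}

#' Donor-by-clonotype presence matrix of public clonotypes
#'
#' Builds the binary occurrence structure over which association tests run.
#' Publicness is counted across the full (merged) input cohort: only
#' clonotypes present in at least `min_publicness` donors are retained.
#' Presence is binary; clone abundance is ignored.
#'
#' @param cohort a `tcr_cohort`.
#' @param min_publicness minimum number of donors sharing a clonotype
#'   (default 3).
#' @param chain optionally restrict to `"alpha"` or `"beta"` clonotypes.
#' @return A list of class `occurrence_matrix` with elements `matrix` (sparse
#'   donor x clonotype 0/1 matrix, rows in donor order, columns sorted by
#'   `(chain, v_family, cdr3_aa)`), `clonotypes` (column metadata) and
#'   `donor_ids`.
#' @export
occurrence_matrix <- function(cohort, min_publicness = 3, chain = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  if (!length(cohort$donors)) stop("empty cohort")
  if (min_publicness < 1) stop("min_publicness must be >= 1")
  donor_ids <- cohort_donor_ids(cohort)
  cl_list <- lapply(cohort$donors, `[[`, "clonotypes")
  if (!is.null(chain)) {
    cl_list <- lapply(cl_list, function(cl) cl[cl$chain == chain, , drop = FALSE])
  }
  nper <- vapply(cl_list, nrow, integer(1))
  all_cl <- do.call(rbind, cl_list)
  if (is.null(all_cl) || !nrow(all_cl)) {
    keys <- character(0)
    mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(length(donor_ids), 0))
    meta <- clonotype_frame()
  } else {
    keys_all <- clonotype_key(all_cl)
    keys <- unique(keys_all)
    j <- match(keys_all, keys)
    i <- rep(seq_along(cl_list), nper)
    mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                dims = c(length(donor_ids), length(keys)))
    publicness <- Matrix::colSums(mat)
    keep <- which(publicness >= min_publicness)
    first <- match(keys, keys_all)
    meta <- all_cl[first, , drop = FALSE][keep, , drop = FALSE]
    mat <- mat[, keep, drop = FALSE]
    ord <- order_clonotypes(meta)
    meta <- meta[ord, , drop = FALSE]
    rownames(meta) <- NULL
    mat <- mat[, ord, drop = FALSE]
  }
  dimnames(mat) <- list(donor_ids, clonotype_key(meta))
  structure(list(matrix = mat, clonotypes = meta, donor_ids = donor_ids),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("<occurrence_matrix> %d donors x %d public clonotypes (%d alpha, %d beta)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$clonotypes$chain == "alpha"),
              sum(x$clonotypes$chain == "beta")))
  invisible(x)
}
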