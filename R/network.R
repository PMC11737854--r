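#' Hamming-1 similarity network of HLA-associated clonotypes
#'
#' One node per distinct clonotype; an edge connects two clonotypes that
#' share chain, V family and CDR3 length and whose CDR3s differ by at most
#' one amino acid. Connected components are labelled and the allele purity
#' of each component (fraction of nodes whose allele set contains the
#' component's majority allele) is reported.
#'
#' @param records association records (columns `chain`, `cdr3_aa`,
#'   `v_family`, `allele`); a clonotype associated with several alleles
#'   keeps all its allele labels on one node.
#' @return A list of class `tcr_network`: `nodes` (with `component` and
#'   comma-joined `alleles`), `edges` (`from`, `to` node indices),
#'   `components` (per-component size, majority allele, purity), and the
#'   underlying `igraph` object `graph`.
#' @export
build_network <- function(records) {
  if (!nrow(records)) stop("no association records")
  key <- clonotype_key(records)
  first <- !duplicated(key)
  nodes <- records[first, c("chain", "cdr3_aa", "v_family"), drop = FALSE]
  ord <- order_clonotypes(nodes)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  node_key <- clonotype_key(nodes)
  allele_sets <- lapply(node_key, function(k)
    sort(unique(records$allele[key == k])))
  nodes$alleles <- vapply(allele_sets, paste, character(1), collapse = ",")

  # candidate pairs only within (chain, v_family, length) groups
  grp <- paste(nodes$chain, nodes$v_family, nchar(nodes$cdr3_aa), sep = "|")
  edges <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    seqs <- strsplit(nodes$cdr3_aa[idx], "")
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        if (sum(seqs[[a]] != seqs[[b]]) <= 1) {
          edges[[length(edges) + 1]] <- c(idx[a], idx[b])
        }
      }
    }
  }
  edge_df <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges)) |> stats::setNames(c("from", "to"))
  } else {
    data.frame(from = integer(0), to = integer(0))
  }
  g <- igraph::graph_from_data_frame(
    edge_df, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes))))
  comp <- igraph::components(g)
  nodes$component <- comp$membership[as.character(seq_len(nrow(nodes)))]
  components <- do.call(rbind, lapply(seq_len(comp$no), function(ci) {
    members <- which(nodes$component == ci)
    alle <- unlist(allele_sets[members])
    tab <- sort(table(alle), decreasing = TRUE)
    majority <- names(tab)[1]
    purity <- mean(vapply(allele_sets[members],
                          function(s) majority %in% s, logical(1)))
    data.frame(component = ci, size = length(members),
               majority_allele = majority, purity = purity,
               stringsAsFactors = FALSE)
  }))
  structure(list(nodes = nodes, edges = edge_df, components = components,
                 graph = g),
            class = "tcr_network")
}

#' @export
print.tcr_network <- function(x, ...) {
  cat(sprintf("<tcr_network> %d nodes, %d edges, %d components (mean purity %.2f)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$components),
              mean(x$components$purity)))
  invisible(x)
}

#' @export
plot.tcr_network <- function(x, ...) {
  pal <- grDevices::rainbow(max(x$nodes$component))
  igraph::plot.igraph(x$graph, vertex.label = NA, vertex.size = 4,
                      vertex.color = pal[x$nodes$component], ...)
  invisible(x)
}

#' Annotate network nodes with known epitope specificities
#'
#' Matches each node against a user-supplied reference table (e.g. a VDJdb
#' export) by exact CDR3 amino-acid sequence and V-gene family; every
#' matching epitope is attached. Malformed reference rows (missing CDR3 or V)
#' are skipped with a message.
#'
#' @param network a `tcr_network`.
#' @param reference data.frame with columns `cdr3_aa`, `v_family`, `epitope`
#'   and optionally `hla`.
#' @return the network with a `nodes$epitopes` column (comma-joined; `""`
#'   for unannotated nodes).
#' @export
annotate_epitopes <- function(network, reference) {
  stopifnot(inherits(network, "tcr_network"))
  need <- c("cdr3_aa", "v_family", "epitope")
  miss <- setdiff(need, names(reference))
  if (length(miss)) stop("reference table is missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- !is.na(reference$cdr3_aa) & nzchar(reference$cdr3_aa) &
    !is.na(reference$v_family) & nzchar(reference$v_family) &
    !is.na(reference$epitope) & nzchar(reference$epitope)
  if (any(!ok)) message("skipping ", sum(!ok), " malformed reference row(s)")
  ref <- reference[ok, , drop = FALSE]
  ref$v_family <- normalize_v_family(ref$v_family)
  ref_key <- paste(ref$cdr3_aa, ref$v_family, sep = "|")
  node_key <- paste(network$nodes$cdr3_aa, network$nodes$v_family, sep = "|")
  network$nodes$epitopes <- vapply(node_key, function(k)
    paste(sort(unique(ref$epitope[ref_key == k])), collapse = ","),
    character(1), USE.NAMES = FALSE)
  network
}

#' Export a network as edge-list and node-attribute TSVs
#' @param network a `tcr_network`.
#' @param edge_path,node_path output paths.
#' @export
write_network <- function(network, edge_path, node_path) {
  nodes <- network$nodes
  nodes$node <- seq_len(nrow(nodes))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}

#' CDR3 length distributions of a clonotype subset vs background
#'
#' Per chain, normalized length histograms for the subset and the background,
#' plus a two-sided Mann-Whitney U comparison of the length distributions
#' (the location test is a package choice; the underlying histograms are the
#' primary output).
#'
#' @param subset,background clonotype data.frames.
#' @return list per chain, each with `lengths` (data.frame `length`,
#'   `subset_freq`, `background_freq`) and `test` (`wilcox.test` result, or
#'   `NULL` if a chain is absent from either list).
#' @export
cdr3_length_profile <- function(subset, background) {
  if (!nrow(subset) || !nrow(background)) stop("both clonotype lists must be nonempty")
  out <- list()
  for (ch in intersect(unique(subset$chain), unique(background$chain))) {
    ls <- nchar(subset$cdr3_aa[subset$chain == ch])
    lb <- nchar(background$cdr3_aa[background$chain == ch])
    lengths <- sort(unique(c(ls, lb)))
    out[[ch]] <- list(
      lengths = data.frame(
        length = lengths,
        subset_freq = as.numeric(table(factor(ls, levels = lengths))) / length(ls),
        background_freq = as.numeric(table(factor(lb, levels = lengths))) / length(lb)),
      test = if (length(unique(c(ls, lb))) == 1) {
        list(p.value = 1, note = "all lengths tied")   # degenerate comparison
      } else {
        stats::wilcox.test(ls, lb, exact = FALSE)
      },
      subset_mean = mean(ls), background_mean = mean(lb))
  }
  out
}

#' V-family usage of a clonotype subset vs background
#'
#' Per chain, the frequency of each V family among unique clonotypes in the
#' subset and in the background (each column sums to 1 per chain); families
#' absent from one side are reported with frequency 0, not dropped.
#'
#' @param subset,background clonotype data.frames.
#' @return data.frame `chain`, `v_family`, `subset_freq`, `background_freq`,
#'   `ratio`.
#' @export
v_usage_enrichment <- function(subset, background) {
  if (!nrow(subset) || !nrow(background)) stop("both clonotype lists must be nonempty")
  out <- list()
  for (ch in union(unique(subset$chain), unique(background$chain))) {
    vs <- subset$v_family[subset$chain == ch]
    vb <- background$v_family[background$chain == ch]
    fams <- sort(unique(c(vs, vb)))
    sf <- as.numeric(table(factor(vs, levels = fams))) /
      max(length(vs), 1)
    bf <- as.numeric(table(factor(vb, levels = fams))) /
      max(length(vb), 1)
    out[[ch]] <- data.frame(chain = ch, v_family = fams, subset_freq = sf,
                            background_freq = bf,
                            ratio = ifelse(bf > 0, sf / bf, NA_real_),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-donor V-family frequency vector of a repertoire
#'
#' Frequencies over unique clonotypes of one chain; families listed in
#' `v_families` but absent from the repertoire get 0.
#'
#' @param donor a `tcr_donor`.
#' @param chain `"alpha"` or `"beta"`.
#' @param v_families V families to report (default: those in the donor).
#' @return named numeric vector summing to 1 (all zeros for an empty chain).
#' @export
donor_v_frequencies <- function(donor, chain = "beta", v_families = NULL) {
  v <- donor$clonotypes$v_family[donor$clonotypes$chain == chain]
  if (is.null(v_families)) v_families <- sort(unique(v))
  counts <- table(factor(v, levels = v_families))
  n <- length(v)
  stats::setNames(if (n) as.numeric(counts) / n else rep(0, length(v_families)),
                  v_families)
}

#' Compare whole-repertoire V-family usage between two donor groups
#'
#' Two-sided Mann-Whitney U test per V family on per-donor frequencies of
#' that family, with Benjamini-Hochberg adjustment across families. V
#' families whose frequencies are identical constants in both groups get
#' p = 1 with a tie flag.
#'
#' @param group_a,group_b matrices (or data.frames) of per-donor V-family
#'   frequencies, one row per donor, columns named by V family (as from
#'   [donor_v_frequencies()] stacked with `rbind`).
#' @return data.frame `v_family`, `p_raw`, `p_adj`, `tie_flag`, and the two
#'   group means.
#' @export
compare_repertoire_v_usage <- function(group_a, group_b) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop("need at least 2 donors per group")
  }
  fams <- union(colnames(group_a), colnames(group_b))
  res <- lapply(fams, function(f) {
    xa <- if (f %in% colnames(group_a)) group_a[, f] else rep(0, nrow(group_a))
    xb <- if (f %in% colnames(group_b)) group_b[, f] else rep(0, nrow(group_b))
    tie <- length(unique(c(xa, xb))) == 1
    p <- if (tie) 1 else
      stats::wilcox.test(xa, xb, exact = (length(xa) + length(xb) <= 30) &&
                           !any(duplicated(c(xa, xb))))$p.value
    data.frame(v_family = f, p_raw = p, tie_flag = tie,
               mean_a = mean(xa), mean_b = mean(xb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[, c("v_family", "p_raw", "p_adj", "tie_flag", "mean_a", "mean_b")]
  rownames(out) <- NULL
  out
}
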