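# shared fixtures, built in code

# donor from compact spec: list of c(chain, cdr3, v)
make_donor <- function(id, rows, hla = NULL, has_alpha = NULL, cohort = "test") {
  cl <- if (length(rows)) {
    m <- do.call(rbind, rows)
    clonotype_frame(m[, 1], m[, 2], m[, 3])
  } else clonotype_frame()
  new_donor(id, cl, cohort = cohort, has_alpha = has_alpha, hla = hla)
}

# tiny hand-built typed cohort: clonotype X shared by donors 1-3
tiny_cohort <- function() {
  X <- c("beta", "CASSLGETQYF", "TRBV19")
  Y <- c("beta", "CASSIRSSYEQYF", "TRBV5")
  new_cohort(list(
    make_donor("d1", list(X, Y), hla = c("A*02:01", "B*07:02")),
    make_donor("d2", list(X), hla = c("A*02:01", "B*07:02")),
    make_donor("d3", list(X, Y), hla = c("A*02:01", "B*08:01")),
    make_donor("d4", list(Y), hla = c("A*01:01", "B*07:02")),
    make_donor("d5", list(Y), hla = c("A*01:01", "B*08:01"))
  ), name = "tiny")
}

donor_status <- function(cohort, allele) {
  vapply(cohort$donors, function(d) allele %in% d$hla, logical(1))
}

# enumeration oracle for the two-sided Fisher p (point-probability method)
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  obs <- dhyper(a, m, n, k)
  total <- 0
  for (x in lo:hi) {
    px <- dhyper(x, m, n, k)
    if (px <= obs * (1 + 1e-7)) total <- total + px
  }
  min(1, total)
}

# independent step-up BH reference
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# all-pairs ROC-AUC oracle with half-credit ties
auc_pairs_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (distinct values assumed)
mw_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(nx))
  mu <- nx * ny / 2
  if (u_obs <= mu) {
    p <- 2 * mean(us <= u_obs)
  } else {
    p <- 2 * mean(us >= u_obs)
  }
  min(1, p)
}
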