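# Independent single-pass oracle implementations used to cross-check the
# package metrics. These deliberately avoid the package's code paths.

naive_clonality <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  if (length(p) == 1) return(1)
  1 - (-sum(p * log(p))) / log(length(p))
}

naive_morisita_horn <- function(xa, xb) {
  # xa, xb: named count vectors keyed by clone id
  keys <- union(names(xa), names(xb))
  x <- ifelse(keys %in% names(xa), xa[keys], 0)
  y <- ifelse(keys %in% names(xb), xb[keys], 0)
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  X <- sum(x); Y <- sum(y)
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  2 * sum(x * y) / ((dx + dy) * X * Y)
}

# brute-force enumeration of all distinct 8-11mers spanning a given index
naive_mut_peptides <- function(window, mut_index, lengths = 8:11) {
  seqs <- character(0)
  for (L in lengths) {
    if (nchar(window) < L) next
    for (s in 1:(nchar(window) - L + 1)) {
      if (s <= mut_index && mut_index <= s + L - 1) {
        seqs <- c(seqs, substr(window, s, s + L - 1))
      }
    }
  }
  unique(seqs)
}

# independent Mantel-Cox log-rank arithmetic (observed minus expected)
naive_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1/2
  times <- sort(unique(time[event]))
  o_minus_e <- 0
  var_sum <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g == 1)
    if (n < 2) next
    e1 <- d * n1 / n
    v <- d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    o_minus_e <- o_minus_e + (d1 - e1)
    var_sum <- var_sum + v
  }
  (o_minus_e)^2 / var_sum
}

random_repertoire <- function(n_clones, max_count = 50) {
  ids <- paste0("clone", sample.int(1e6, n_clones))
  as_repertoire(data.frame(
    cdr3_nt = ids,
    count = sample.int(max_count, n_clones, replace = TRUE)
  ))
}

make_rep <- function(counts, ids = NULL, productive = TRUE) {
  ids <- ids %||% sprintf("nt%03d", seq_along(counts))
  as_repertoire(data.frame(cdr3_nt = ids, count = counts,
                           productive = productive))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
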