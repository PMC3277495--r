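# Independent brute-force oracles kept deliberately naive and separate from
# the implementation paths they check.

# P(X >= k) for X ~ Binomial(m, p), by direct pmf summation
oracle_binom_tail <- function(k, m, p) {
  if (k <= 0) return(1)
  if (k > m) return(0)
  sum(vapply(k:m, function(j) choose(m, j) * p^j * (1 - p)^(m - j), numeric(1)))
}

# tail of the sum of n iid {0,1,2} counts, by full enumeration of 3^n outcomes
oracle_trinomial_tail <- function(n, pi0, pi1, pi2, t) {
  if (n == 0) return(as.numeric(t <= 0))
  grid <- do.call(expand.grid, rep(list(0:2), n))
  pr <- apply(grid, 1, function(x) prod(c(pi0, pi1, pi2)[x + 1]))
  sum(pr[rowSums(grid) >= t])
}

# tail of a sum of independent Bernoulli(q_i), by full enumeration
oracle_poisbin_tail <- function(q, t) {
  n <- length(q)
  if (t <= 0) return(1)
  if (t > n) return(0)
  grid <- do.call(expand.grid, rep(list(0:1), n))
  pr <- apply(grid, 1, function(x) prod(ifelse(x == 1, q, 1 - q)))
  sum(pr[rowSums(grid) >= t])
}

# long-format counts tibble from a dense patients-by-genes matrix
counts_from_matrix <- function(mat, patient_ids = NULL, gene_ids = NULL) {
  patient_ids <- patient_ids %||% paste0("P", seq_len(nrow(mat)))
  gene_ids <- gene_ids %||% paste0("G", seq_len(ncol(mat)))
  idx <- which(mat >= 0, arr.ind = TRUE)
  tibble::tibble(
    patient_id = patient_ids[idx[, 1]],
    gene_id = gene_ids[idx[, 2]],
    count = as.integer(mat[idx])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
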