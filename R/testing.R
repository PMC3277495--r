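#' Bonferroni-corrected per-gene significance level
#'
#' With `M` genes tested genome-wide, the family-wise level `alpha_family`
#' is divided by `M` to control genome-wide false positives.
#'
#' @param alpha_family Family-wise significance level in (0, 1].
#' @param M Number of genes tested.
#' @return The per-gene level `alpha_family / M`.
#' @examples
#' per_gene_alpha(0.05, 20000)
#' @export
per_gene_alpha <- function(alpha_family, M) {
  if (any(alpha_family <= 0 | alpha_family > 1)) {
    stop("`alpha_family` must be in (0, 1]")
  }
  if (any(M < 1)) stop("`M` must be at least 1")
  alpha_family / M
}

#' Exact significance cutoff for a discrete burden statistic
#'
#' The rejection rule is one-sided upper-tail: reject when `T >= t*` with
#' `t* = min { t : P(T >= t | null) <= alpha }`. Because the statistic is
#' discrete the achieved size `P(T >= t* | null)` is at most, and usually
#' well below, the nominal `alpha`; `t* = size + 1` means rejection is
#' impossible at this level. The cutoff is found by bisection on the exact
#' survival function.
#'
#' @param null A `mendel_dist` null distribution (binomial).
#' @param alpha Per-gene significance level in (0, 1].
#' @return A list of class `mendel_cutoff` with elements `cutoff` (integer
#'   `t*`), `achieved_size`, `alpha`, and `null`.
#' @examples
#' significance_cutoff(null_dist(2, 300, 20000, "Tr"), per_gene_alpha(0.05, 20000))
#' @export
significance_cutoff <- function(null, alpha) {
  stopifnot(inherits(null, "mendel_dist"))
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  hi <- dist_max_support(null) + 1L
  # smallest t in [0, hi] with tail(t) <= alpha; tail is non-increasing in t
  # and tail(hi) = 0 <= alpha always
  lo <- 0L
  if (dist_tail(null, lo) <= alpha) {
    t_star <- lo
  } else {
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (dist_tail(null, mid) <= alpha) hi <- mid else lo <- mid
    }
    t_star <- hi
  }
  structure(
    list(
      cutoff = as.integer(t_star),
      achieved_size = dist_tail(null, t_star),
      alpha = alpha,
      null = null
    ),
    class = "mendel_cutoff"
  )
}

#' @export
print.mendel_cutoff <- function(x, ...) {
  cat(sprintf(
    "<cutoff t* = %d, achieved size = %.4g (nominal alpha = %.4g)>\n",
    x$cutoff, x$achieved_size, x$alpha
  ))
  invisible(x)
}

#' Raw and Bonferroni-adjusted p-value for an observed statistic
#'
#' `P(T >= t_obs | null)` under the exact null, and its Bonferroni
#' adjustment `min(1, M * p)` for `M` genes tested. One-sided upper-tail
#' only: the alternative can only inflate counts.
#'
#' @param t_obs Observed value of the statistic (non-negative integer).
#' @param null A `mendel_dist` null distribution.
#' @param M Number of genes tested (Bonferroni divisor).
#' @return A tibble with one row: `p_value`, `p_adjusted`.
#' @examples
#' gene_pvalue(2, null_dist(2, 300, 20000, "Tr"), M = 20000)
#' @export
gene_pvalue <- function(t_obs, null, M) {
  if (t_obs < 0) stop("`t_obs` must be non-negative")
  p <- dist_tail(null, t_obs)
  tibble::tibble(p_value = p, p_adjusted = min(1, M * p))
}

#' Gene-level burden statistics from a mutation count table
#'
#' Collapses a long-format patient-by-gene rare-variant count table into
#' the three gene-level statistics: `Ta` (total variant count across
#' patients), `Tr` (number of patients with at least two variants in the
#' gene) and `Td` (number of patients with at least one — the collapsed
#' count).
#'
#' @param counts A data frame with columns `patient_id`, `gene_id`,
#'   `count` (long format; absent pairs are zero).
#' @return A tibble with one row per gene: `gene_id`, `Ta`, `Tr`, `Td`.
#' @examples
#' counts <- tibble::tibble(
#'   patient_id = c("P1", "P1", "P2", "P2"),
#'   gene_id = c("G1", "G2", "G1", "G2"),
#'   count = c(2L, 0L, 1L, 1L)
#' )
#' burden_statistics(counts)
#' @export
burden_statistics <- function(counts) {
  counts <- validate_counts(counts)
  counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      Ta = sum(.data$count),
      Tr = sum(.data$count >= 2L),
      Td = sum(.data$count >= 1L),
      .groups = "drop"
    )
}

validate_counts <- function(counts) {
  if (!is.data.frame(counts)) stop("`counts` must be a data frame")
  need <- c("patient_id", "gene_id", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("`counts` is missing columns: ", paste(miss, collapse = ", "))
  if (any(counts$count < 0)) stop("mutation counts must be non-negative")
  tibble::as_tibble(counts[need])
}

# Exact tail P(S >= t) of a sum of independent Bernoulli(q_i) variables
# (Poisson-binomial), by convolution. Used for the null of Td / Tr when the
# per-patient mutation totals (hence the q_i) differ between patients.
poisson_binomial_tail <- function(q, t) {
  stopifnot(all(q >= 0 & q <= 1))
  n <- length(q)
  if (t <= 0) return(1)
  if (t > n) return(0)
  if (n == 0) return(0)
  if (length(unique(q)) == 1L) {
    return(stats::pbinom(t - 1, n, q[1], lower.tail = FALSE))
  }
  pmf <- 1
  for (qi in q) {
    pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
  }
  sum(pmf[(t + 1L):(n + 1L)])
}

#' Rank candidate genes by exact burden-test p-values
#'
#' Tests every gene in an observed (or simulated) mutation count table
#' against its own gene-length-adjusted exact null and ranks genes by raw
#' p-value. This is the data-analysis counterpart of the power machinery:
#' a longer gene needs a larger count to reach the same significance, so a
#' gene carried by fewer patients can out-rank a much longer gene carried
#' by all of them.
#'
#' Each patient's background mutation total `m` is taken as that patient's
#' row total in `counts` (set `common_m` to impose the constant-`m` model
#' instead). With per-patient totals varying, the null of `Td` / `Tr` is the
#' exact Poisson-binomial law of the per-patient indicator sum; `Ta` remains
#' binomial with `sum(m_i)` trials.
#'
#' @param counts Long-format count table (`patient_id`, `gene_id`, `count`).
#'   Patients with no variants still count toward `n` only if present in
#'   the table (use a zero-count row to include them).
#' @param genes Optional gene table, a data frame with `gene_id` and `w`
#'   (relative length) — e.g. from [read_gene_table()]. Genes absent from
#'   it get `w = 1`; every gene in `counts` must appear if `genes` is
#'   supplied with `strict = TRUE`.
#' @param M Number of genes in the captured region (Bonferroni divisor and
#'   null genome size).
#' @param stat Statistic to rank by: `"Td"`, `"Tr"` or `"Ta"`.
#' @param alpha_family Family-wise significance level.
#' @param common_m Optional common per-patient mutation total overriding
#'   the observed row totals.
#' @param strict If `TRUE` (default when `genes` is given), error on genes
#'   in `counts` missing from `genes`.
#' @return An object of class `burden_test`; see [tidy.burden_test()],
#'   [glance.burden_test()] and [autoplot.burden_test()].
#' @examples
#' counts <- tibble::tibble(
#'   patient_id = rep(paste0("P", 1:3), each = 2),
#'   gene_id = rep(c("G1", "G2"), 3),
#'   count = c(2L, 1L, 2L, 0L, 0L, 1L)
#' )
#' fit <- burden_test(counts, M = 100, stat = "Tr")
#' tidy(fit)
#' @export
burden_test <- function(counts, genes = NULL, M = 20000,
                        stat = c("Td", "Tr", "Ta"), alpha_family = 0.05,
                        common_m = NULL, strict = !is.null(genes)) {
  stat <- match.arg(stat)
  counts <- validate_counts(counts)
  alpha <- per_gene_alpha(alpha_family, M)

  stats_tbl <- burden_statistics(counts)
  if (nrow(stats_tbl) == 0L) {
    out <- tibble::tibble(
      gene_id = character(), w = numeric(), statistic = integer(),
      p_value = numeric(), p_adjusted = numeric(), rank = integer()
    )
    return(new_burden_test(out, stat, M, alpha_family, n_patients = 0L))
  }

  if (!is.null(genes)) {
    if (!all(c("gene_id", "w") %in% names(genes))) {
      stop("`genes` must have columns gene_id and w (see read_gene_table())")
    }
    missing_ids <- setdiff(stats_tbl$gene_id, genes$gene_id)
    if (strict && length(missing_ids)) {
      stop(
        "genes present in `counts` but missing from `genes`: ",
        paste(missing_ids, collapse = ", ")
      )
    }
    stats_tbl <- dplyr::left_join(
      stats_tbl, dplyr::select(genes, "gene_id", "w"),
      by = "gene_id"
    ) |>
      dplyr::mutate(w = dplyr::coalesce(.data$w, 1))
  } else {
    stats_tbl$w <- 1
  }

  m_i <- counts |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(m = sum(.data$count), .groups = "drop")
  if (!is.null(common_m)) m_i$m <- common_m
  n <- nrow(m_i)

  pvals <- purrr::pmap_dbl(
    list(stats_tbl$gene_id, stats_tbl[[stat]], stats_tbl$w),
    function(gid, t_obs, w) {
      p <- hit_probability(w, M)
      switch(stat,
        Ta = dist_tail(dist_binomial(sum(m_i$m), p), t_obs),
        Td = poisson_binomial_tail(prob_ge1(m_i$m, p), t_obs),
        Tr = poisson_binomial_tail(prob_ge2(m_i$m, p), t_obs)
      )
    }
  )

  out <- stats_tbl |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      w = .data$w,
      statistic = .data[[stat]],
      p_value = pvals,
      p_adjusted = pmin(1, M * pvals)
    ) |>
    # deterministic ordering: p, then shorter gene, then id
    dplyr::arrange(.data$p_value, .data$w, .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())

  new_burden_test(out, stat, M, alpha_family, n_patients = n)
}

new_burden_test <- function(results, stat, M, alpha_family, n_patients) {
  structure(
    list(
      results = results, stat = stat, M = M,
      alpha_family = alpha_family, n_patients = n_patients
    ),
    class = "burden_test"
  )
}

#' @export
print.burden_test <- function(x, ...) {
  cat(sprintf(
    "Case-only burden test (%s), %d patients, %d gene(s) tested, Bonferroni over M = %d\n",
    x$stat, x$n_patients, nrow(x$results), x$M
  ))
  print(utils::head(x$results, 10))
  invisible(x)
}

#' Tidy a burden test into a per-gene tibble
#'
#' @param x A `burden_test` object.
#' @param ... Unused.
#' @return The per-gene results: `gene_id`, `w`, `statistic`, `p_value`,
#'   `p_adjusted`, `rank`.
#' @export
tidy.burden_test <- function(x, ...) {
  x$results
}

#' One-row summary of a burden test
#'
#' @inheritParams tidy.burden_test
#' @return A tibble with the statistic used, patient and gene counts, the
#'   per-gene level, and the number of genome-wide-significant genes.
#' @export
glance.burden_test <- function(x, ...) {
  tibble::tibble(
    stat = x$stat,
    n_patients = x$n_patients,
    n_genes_tested = nrow(x$results),
    M = x$M,
    alpha_family = x$alpha_family,
    per_gene_alpha = per_gene_alpha(x$alpha_family, x$M),
    n_significant = sum(x$results$p_adjusted <= x$alpha_family)
  )
}

#' Plot burden-test results
#'
#' A Manhattan-style plot of `-log10` raw p-values per gene, with the
#' Bonferroni-corrected per-gene significance level as a dashed line.
#'
#' @param object A `burden_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_test <- function(object, ...) {
  df <- object$results
  thr <- -log10(per_gene_alpha(object$alpha_family, object$M))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$rank),
    y = -log10(pmax(.data$p_value, .Machine$double.xmin))
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "gene (ranked)",
      y = expression(-log[10] ~ "p"),
      title = sprintf("Case-only %s burden test", object$stat)
    ) +
    ggplot2::theme_minimal()
}
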