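#' Simulate a null cohort mutation count table
#'
#' For each of `n` patients independently, places `m` background mutations
#' over `M` genes by multinomial sampling with probabilities proportional
#' to `gene_weights` (uniform by default) — mutations may land in the same
#' gene more than once. Returns the sparse long-format count table used
#' throughout the package; genes absent from the table have count zero.
#'
#' @param n Number of patients.
#' @param m Mutations per patient.
#' @param M Number of genes.
#' @param gene_weights Optional positive weights of length `M` (relative
#'   gene lengths); uniform if `NULL`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   cohort exactly.
#' @return A tibble with columns `patient_id` (integer 1..n), `gene_id`
#'   (integer 1..M) and `count`, containing only non-zero cells. The
#'   attribute `M` records the genome size and `n` the patient count.
#' @examples
#' simulate_null_counts(n = 3, m = 10, M = 50, seed = 1)
#' @export
simulate_null_counts <- function(n, m, M, gene_weights = NULL, seed = NULL) {
  stopifnot(n >= 1, m >= 0, M >= 1)
  if (!is.null(gene_weights)) {
    stopifnot(length(gene_weights) == M, all(is.finite(gene_weights)), all(gene_weights > 0))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  tab <- draw_null_cells(n, m, M, gene_weights)
  out <- tibble::tibble(
    patient_id = tab$patient_id, gene_id = tab$gene_id, count = tab$count
  )
  attr(out, "M") <- as.integer(M)
  attr(out, "n") <- as.integer(n)
  out
}

# one cohort's non-zero (patient, gene) cells; assumes RNG already seeded
draw_null_cells <- function(n, m, M, gene_weights = NULL, exclude_gene = NULL) {
  if (m == 0 || n == 0) {
    return(list(patient_id = integer(), gene_id = integer(), count = integer()))
  }
  prob <- gene_weights
  if (!is.null(exclude_gene)) {
    # redirect background away from the causal gene
    prob <- if (is.null(prob)) rep(1, M) else prob
    prob[exclude_gene] <- 0
  }
  draws <- sample.int(M, n * m, replace = TRUE, prob = prob)
  pat <- rep.int(seq_len(n), rep.int(m, n))
  key <- (pat - 1) * as.double(M) + draws
  r <- rle(sort(key))
  key_u <- r$values
  list(
    patient_id = as.integer((key_u - 1) %/% M + 1),
    gene_id = as.integer((key_u - 1) %% M + 1),
    count = r$lengths
  )
}

#' Simulate a cohort with one causal gene
#'
#' Each patient is attributable to the causal gene with probability `R`.
#' An attributable patient carries two causal mutations (recessive) or one
#' (dominant), each detected independently with sensitivity `Ps`; the
#' detected causal mutations are added to the causal gene's count.
#' Background mutations are placed as in [simulate_null_counts()], but by
#' default placements that would land in the causal gene are redirected to
#' other genes, matching the analytic alternative in which the causal
#' gene's count is purely causal. Set `contaminate = TRUE` to let
#' background mutations also fall in the causal gene.
#'
#' @inheritParams simulate_null_counts
#' @param Ps Detection sensitivity for a true causal mutation.
#' @param R Fraction of patients attributable to the causal gene.
#' @param mode `"recessive"` (two causal mutations) or `"dominant"` (one).
#' @param causal_gene Index of the causal gene (default 1).
#' @param contaminate If `TRUE`, background mutations may land in the
#'   causal gene as well.
#' @return A long-format count tibble as in [simulate_null_counts()], with
#'   attribute `causal_gene`.
#' @examples
#' simulate_alt_counts(n = 4, m = 10, M = 50, Ps = 1, R = 1, mode = "recessive", seed = 1)
#' @export
simulate_alt_counts <- function(n, m, M, Ps, R, mode = c("recessive", "dominant"),
                                causal_gene = 1L, gene_weights = NULL,
                                contaminate = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, m >= 0, M >= 1, Ps >= 0, Ps <= 1, R >= 0, R <= 1)
  stopifnot(causal_gene >= 1, causal_gene <= M)
  if (!is.null(seed)) withr::local_seed(seed)

  causal <- causal_column(n, Ps, R, mode)
  bg <- draw_null_cells(
    n, m, M, gene_weights,
    exclude_gene = if (contaminate) NULL else causal_gene
  )

  pat <- c(bg$patient_id, which(causal > 0))
  gid <- c(bg$gene_id, rep.int(as.integer(causal_gene), sum(causal > 0)))
  cnt <- c(bg$count, causal[causal > 0])
  agg <- rowsum(cnt, group = (pat - 1) * as.double(M) + gid)
  key <- as.double(rownames(agg))
  ord <- order(key)
  out <- tibble::tibble(
    patient_id = as.integer((key[ord] - 1) %/% M + 1),
    gene_id = as.integer((key[ord] - 1) %% M + 1),
    count = as.integer(agg[ord, 1])
  )
  attr(out, "M") <- as.integer(M)
  attr(out, "n") <- as.integer(n)
  attr(out, "causal_gene") <- as.integer(causal_gene)
  out
}

# detected causal mutation count per patient; assumes RNG already seeded
causal_column <- function(n, Ps, R, mode) {
  copies <- if (mode == "recessive") 2L else 1L
  is_causal <- stats::rbinom(n, 1L, R)
  stats::rbinom(n, copies, Ps) * is_causal
}

#' Empirical family-wise type-I error of the burden tests
#'
#' Simulates null cohorts, computes all three statistics for every gene,
#' and records for each statistic whether any gene reaches its
#' Bonferroni-level exact cutoff. The family-wise rejection proportion
#' should stay at or below the nominal level (usually well below, because
#' the discrete cutoffs are conservative).
#'
#' @inheritParams simulate_null_counts
#' @param alpha_family Family-wise significance level.
#' @param replicates Number of simulated cohorts.
#' @param seed Integer seed.
#' @return A tibble with one row per statistic: `stat`, `rejections`,
#'   `replicates`, `rate` and its binomial standard error `se`.
#' @examples
#' empirical_type1(n = 5, m = 50, M = 200, replicates = 50, seed = 1)
#' @export
empirical_type1 <- function(n, m, M, alpha_family = 0.05, replicates = 1000,
                            gene_weights = NULL, seed = NULL) {
  stopifnot(replicates >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  alpha <- per_gene_alpha(alpha_family, M)
  # uniform-length genes share one cutoff per statistic
  cuts <- vapply(
    c(Ta = "Ta", Tr = "Tr", Td = "Td"),
    function(s) significance_cutoff(null_dist(n, m, M, stat = s), alpha)$cutoff,
    integer(1)
  )
  rej <- c(Ta = 0L, Tr = 0L, Td = 0L)
  for (r in seq_len(replicates)) {
    cells <- draw_null_cells(n, m, M, gene_weights)
    mx <- max_statistics(cells, M)
    rej <- rej + as.integer(mx >= cuts)
  }
  rate <- rej / replicates
  tibble::tibble(
    stat = names(rej),
    rejections = as.integer(rej),
    replicates = as.integer(replicates),
    rate = as.numeric(rate),
    se = sqrt(rate * (1 - rate) / replicates)
  )
}

# max over genes of each statistic, from non-zero cells
max_statistics <- function(cells, M) {
  if (length(cells$gene_id) == 0L) {
    return(c(Ta = 0L, Tr = 0L, Td = 0L))
  }
  ta <- max(rowsum(cells$count, cells$gene_id))
  td_counts <- tabulate(cells$gene_id, nbins = M)
  ge2 <- cells$gene_id[cells$count >= 2L]
  tr <- if (length(ge2)) max(tabulate(ge2, nbins = M)) else 0L
  c(Ta = as.integer(ta), Tr = as.integer(tr), Td = as.integer(max(td_counts)))
}

#' Empirical power of discovering the causal gene
#'
#' Monte-Carlo estimate of the probability that the causal gene's
#' statistic reaches the Bonferroni-level exact cutoff. In the default
#' (uncontaminated) model the causal gene's count depends only on the
#' causal genotypes and detection thinning, so the simulation draws the
#' causal column directly; with `contaminate = TRUE` full cohorts are
#' simulated so background mutations can add to the causal gene.
#'
#' @inheritParams simulate_alt_counts
#' @param stat Statistic whose power is estimated.
#' @param alpha_family Family-wise significance level.
#' @param replicates Number of simulated cohorts.
#' @return A one-row tibble: `stat`, `cutoff`, `rejections`, `replicates`,
#'   `rate` (the empirical power) and `se`.
#' @examples
#' empirical_power(
#'   n = 2, m = 300, M = 20000, Ps = 0.8, R = 1,
#'   mode = "recessive", stat = "Tr", replicates = 200, seed = 1
#' )
#' @export
empirical_power <- function(n, m, M, Ps, R, mode = c("recessive", "dominant"),
                            stat = c("Tr", "Td", "Ta"), alpha_family = 0.05,
                            replicates = 2000, w = 1, causal_gene = 1L,
                            gene_weights = NULL, contaminate = FALSE,
                            seed = NULL) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  null <- null_dist(n, m, M, stat = stat, w = w)
  cut <- significance_cutoff(null, per_gene_alpha(alpha_family, M))

  hits <- 0L
  if (!contaminate) {
    for (r in seq_len(replicates)) {
      col <- causal_column(n, Ps, R, mode)
      t_obs <- switch(stat,
        Ta = sum(col),
        Tr = sum(col >= 2L),
        Td = sum(col >= 1L)
      )
      hits <- hits + as.integer(t_obs >= cut$cutoff)
    }
  } else {
    for (r in seq_len(replicates)) {
      cohort <- simulate_alt_counts(
        n, m, M, Ps, R,
        mode = mode, causal_gene = causal_gene,
        gene_weights = gene_weights, contaminate = TRUE
      )
      cc <- cohort[cohort$gene_id == causal_gene, ]
      t_obs <- switch(stat,
        Ta = sum(cc$count),
        Tr = sum(cc$count >= 2L),
        Td = sum(cc$count >= 1L)
      )
      hits <- hits + as.integer(t_obs >= cut$cutoff)
    }
  }
  rate <- hits / replicates
  tibble::tibble(
    stat = stat,
    cutoff = cut$cutoff,
    rejections = as.integer(hits),
    replicates = as.integer(replicates),
    rate = rate,
    se = sqrt(rate * (1 - rate) / replicates)
  )
}
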