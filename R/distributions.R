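#' Probability that a background mutation lands in a gene
#'
#' Under the null model a candidate mutation falls into a given gene with
#' probability proportional to the gene's relative coding length `w` (the
#' ratio of its length to the average gene length). With `M` genes in the
#' captured region the hit probability is `w / M`, i.e. the genome-average
#' probability `1/M` scaled by gene length.
#'
#' @param w Relative gene length, a positive real. `w = 1` is a gene of
#'   average length.
#' @param M Number of genes in the captured region (positive integer).
#' @return The per-mutation hit probability `w / M`, a value in (0, 1].
#' @examples
#' hit_probability(w = 1, M = 20000)
#' hit_probability(w = 2, M = 20000)
#' @export
hit_probability <- function(w, M) {
  stopifnot(is.numeric(w), is.numeric(M), length(w) == length(M) || length(w) == 1 || length(M) == 1)
  if (any(w <= 0)) stop("relative gene length `w` must be positive, got ", min(w))
  if (any(M < 1)) stop("gene count `M` must be at least 1, got ", min(M))
  p <- w / M
  if (any(p > 1)) {
    bad <- which(p > 1)[1]
    stop(
      "hit probability w/M exceeds 1 (w = ", w[min(bad, length(w))],
      ", M = ", M[min(bad, length(M))], ")"
    )
  }
  p
}

#' Per-patient probability of at least one background hit
#'
#' Exact probability that a patient carrying `m` independent candidate
#' mutations has one or more of them in a gene with hit probability `p`:
#' `1 - (1 - p)^m`. This is the per-patient Bernoulli success probability
#' underlying the null distribution of the collapsed (dominant) statistic.
#'
#' @param m Number of candidate mutations per patient (non-negative integer).
#' @param p Per-mutation hit probability in `[0, 1]`.
#' @return Probability of at least one hit. Vectorised over `m` and `p`.
#' @examples
#' prob_ge1(m = 300, p = 5e-5)
#' @export
prob_ge1 <- function(m, p) {
  check_m_p(m, p)
  ifelse(m == 0, 0, -expm1(m * log1p(-p)))
}

#' Per-patient probability of at least two background hits
#'
#' Exact probability that at least two of a patient's `m` candidate
#' mutations fall in the same gene with hit probability `p`:
#' `1 - (1 - p)^m - m p (1 - p)^(m - 1)`. This is the per-patient success
#' probability for the null of the recessive statistic (patients with two
#' or more variants in the gene). Returns 0 for `m < 2`.
#'
#' @inheritParams prob_ge1
#' @return Probability of at least two hits. Vectorised over `m` and `p`.
#' @examples
#' prob_ge2(m = 300, p = 5e-5)
#' @export
prob_ge2 <- function(m, p) {
  check_m_p(m, p)
  # survival form of the Binomial(m, p) tail at 2; stable for tiny p
  out <- ifelse(m < 2, 0, stats::pbinom(1, pmax(m, 2), p, lower.tail = FALSE))
  ifelse(p == 0, 0, out)
}

check_m_p <- function(m, p) {
  if (any(m < 0)) stop("mutation count `m` must be non-negative")
  if (any(m != floor(m))) stop("mutation count `m` must be an integer")
  if (any(p < 0 | p > 1)) stop("hit probability `p` must be in [0, 1]")
  invisible(TRUE)
}

#' Distribution specifications for the burden statistics
#'
#' Lightweight containers for the exact laws of the gene-level statistics.
#' `dist_binomial(size, prob)` is the usual binomial; `dist_trinomial()`
#' describes the sum over `size` patients of i.i.d. per-patient counts
#' taking values 0, 1 or 2 with probabilities `pi0`, `pi1`, `pi2` — the law
#' of the total variant count in a causal gene under a recessive model,
#' where a causal patient carries two mutations each detected independently
#' with sensitivity `Ps`.
#'
#' @param size Number of trials (patients, or total mutations for the
#'   additive statistic).
#' @param prob Per-trial success probability.
#' @param pi0,pi1,pi2 Probabilities that one patient contributes 0, 1 or 2
#'   counts; must sum to 1.
#' @return An object of class `mendel_dist`.
#' @examples
#' dist_binomial(10, 0.05)
#' dist_trinomial(4, pi0 = 0.5, pi1 = 0, pi2 = 0.5)
#' @export
dist_binomial <- function(size, prob) {
  stopifnot(length(size) == 1, length(prob) == 1)
  if (size < 0 || size != floor(size)) stop("`size` must be a non-negative integer")
  if (prob < 0 || prob > 1) stop("`prob` must be in [0, 1]")
  structure(
    list(family = "binomial", size = as.integer(size), prob = as.numeric(prob)),
    class = "mendel_dist"
  )
}

#' @rdname dist_binomial
#' @export
dist_trinomial <- function(size, pi0, pi1, pi2) {
  stopifnot(length(size) == 1)
  if (size < 0 || size != floor(size)) stop("`size` must be a non-negative integer")
  pis <- c(pi0, pi1, pi2)
  if (any(pis < -1e-12 | pis > 1 + 1e-12)) stop("trinomial cell probabilities must be in [0, 1]")
  if (abs(sum(pis) - 1) > 1e-12) stop("trinomial cell probabilities must sum to 1, got ", sum(pis))
  pis <- pmin(pmax(pis, 0), 1)
  structure(
    list(
      family = "trinomial", size = as.integer(size),
      pi0 = pis[1], pi1 = pis[2], pi2 = pis[3]
    ),
    class = "mendel_dist"
  )
}

#' @export
print.mendel_dist <- function(x, ...) {
  if (x$family == "binomial") {
    cat(sprintf("<Binomial(size = %d, prob = %.6g)>\n", x$size, x$prob))
  } else {
    cat(sprintf(
      "<Trinomial(size = %d, pi0 = %.6g, pi1 = %.6g, pi2 = %.6g)>\n",
      x$size, x$pi0, x$pi1, x$pi2
    ))
  }
  invisible(x)
}

dist_max_support <- function(dist) {
  switch(dist$family,
    binomial = dist$size,
    trinomial = 2L * dist$size
  )
}

#' Exact upper-tail probability of a burden statistic
#'
#' Computes `P(T >= t)` for a `mendel_dist`. Binomial tails use the survival
#' form of [stats::pbinom()] (never `1 - cdf`, which loses precision at the
#' ~1e-6 significance boundary). Trinomial tails are computed by exact
#' discrete convolution over patients; a normal approximation (continuity
#' corrected) is available behind `method = "normal"` for reference only and
#' is never used for cutoff determination.
#'
#' @param dist A `mendel_dist` from [dist_binomial()] or [dist_trinomial()].
#' @param t Integer threshold; `t <= 0` gives 1, `t` above the support gives 0.
#' @param method `"exact"` (default) or `"normal"` (trinomial only).
#' @return `P(T >= t)` as a single numeric probability.
#' @examples
#' dist_tail(dist_binomial(2, 0.5), 1)
#' dist_tail(dist_trinomial(2, 0.25, 0.5, 0.25), 4)
#' @export
dist_tail <- function(dist, t, method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(inherits(dist, "mendel_dist"), length(t) == 1, is.numeric(t))
  t <- ceiling(t)
  if (t <= 0) return(1)
  if (t > dist_max_support(dist)) return(0)
  if (dist$family == "binomial") {
    return(stats::pbinom(t - 1, dist$size, dist$prob, lower.tail = FALSE))
  }
  if (method == "normal") {
    mu <- dist$size * (dist$pi1 + 2 * dist$pi2)
    v <- dist$size * (dist$pi1 + 4 * dist$pi2 - (dist$pi1 + 2 * dist$pi2)^2)
    if (v <= 0) return(as.numeric(mu >= t))
    return(stats::pnorm(t - 0.5, mean = mu, sd = sqrt(v), lower.tail = FALSE))
  }
  pmf <- trinomial_pmf(dist)
  sum(pmf[(t + 1L):length(pmf)])
}

# pmf of the sum of `size` iid {0,1,2}-valued counts, by iterated convolution
trinomial_pmf <- function(dist) {
  kernel <- c(dist$pi0, dist$pi1, dist$pi2)
  pmf <- 1
  for (i in seq_len(dist$size)) {
    n_out <- length(pmf) + 2L
    out <- numeric(n_out)
    out[seq_along(pmf)] <- pmf * kernel[1]
    out[seq_along(pmf) + 1L] <- out[seq_along(pmf) + 1L] + pmf * kernel[2]
    out[seq_along(pmf) + 2L] <- out[seq_along(pmf) + 2L] + pmf * kernel[3]
    pmf <- out
  }
  pmf
}

#' Null distribution of a burden statistic
#'
#' Exact null law of a gene-level statistic when the gene has no link to the
#' disease and all `m` candidate mutations per patient are random background.
#' With hit probability `p = w/M`:
#' * `Td` (collapsed count) ~ `Binomial(n, 1 - (1-p)^m)`;
#' * `Tr` (patients with >= 2 hits) ~ `Binomial(n, 1 - (1-p)^m - mp(1-p)^(m-1))`;
#' * `Ta` (total variant count) ~ `Binomial(n * m, p)`.
#'
#' Per-patient probabilities are exact, not the small-`m` approximations.
#'
#' @param n Number of sequenced patients.
#' @param m Candidate mutations per patient after filtering.
#' @param M Number of genes in the captured region.
#' @param stat One of `"Ta"`, `"Tr"`, `"Td"`.
#' @param w Relative gene length (default 1, average-length gene).
#' @return A `mendel_dist` (always binomial under the null).
#' @examples
#' null_dist(n = 2, m = 300, M = 20000, stat = "Tr")
#' @export
null_dist <- function(n, m, M, stat = c("Tr", "Td", "Ta"), w = 1) {
  stat <- match.arg(stat)
  stopifnot(n >= 1, n == floor(n))
  p <- hit_probability(w, M)
  switch(stat,
    Td = dist_binomial(n, prob_ge1(m, p)),
    Tr = dist_binomial(n, prob_ge2(m, p)),
    Ta = dist_binomial(n * m, p)
  )
}

#' Alternative distribution of a burden statistic at the causal gene
#'
#' Law of a gene-level statistic at the true disease gene. A patient is
#' attributable to the gene with probability `R` (locus heterogeneity); an
#' attributable patient carries exactly two causal mutations (recessive,
#' one per chromosome) or exactly one (dominant), each surviving sequencing
#' and filtering independently with sensitivity `Ps`. Background mutations
#' are not added to the causal gene (the `contaminate` option of the
#' simulator quantifies the effect of relaxing this).
#'
#' Recessive: `Tr ~ Binomial(n, R Ps^2)`, `Td ~ Binomial(n, R (1-(1-Ps)^2))`,
#' `Ta ~` trinomial with `pi2 = R Ps^2`, `pi1 = 2 R Ps (1-Ps)`.
#' Dominant: `Td` and `Ta ~ Binomial(n, R Ps)`; `Tr` carries no causal
#' signal (a dominant patient contributes at most one mutation), so its
#' alternative is the null law itself.
#'
#' @inheritParams null_dist
#' @param Ps Sensitivity of detecting a true causal mutation, in `[0, 1]`.
#' @param R Fraction of patients attributable to this gene, in `[0, 1]`.
#' @param mode Inheritance model, `"recessive"` or `"dominant"`.
#' @return A `mendel_dist`.
#' @examples
#' alt_dist(n = 2, m = 300, M = 20000, Ps = 0.8, R = 1, mode = "recessive", stat = "Tr")
#' @export
alt_dist <- function(n, m, M, Ps, R, mode = c("recessive", "dominant"),
                     stat = c("Tr", "Td", "Ta"), w = 1) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  stopifnot(n >= 1, n == floor(n))
  if (Ps < 0 || Ps > 1) stop("sensitivity `Ps` must be in [0, 1]")
  if (R < 0 || R > 1) stop("attributable fraction `R` must be in [0, 1]")
  if (mode == "recessive") {
    switch(stat,
      Tr = dist_binomial(n, R * Ps^2),
      Td = dist_binomial(n, R * (1 - (1 - Ps)^2)),
      Ta = dist_trinomial(
        n,
        pi2 = R * Ps^2,
        pi1 = 2 * R * Ps * (1 - Ps),
        pi0 = 1 - R * Ps^2 - 2 * R * Ps * (1 - Ps)
      )
    )
  } else {
    switch(stat,
      Td = dist_binomial(n, R * Ps),
      Ta = dist_binomial(n, R * Ps),
      # no causal signal reaches Tr under a dominant model
      Tr = null_dist(n, m, M, stat = "Tr", w = w)
    )
  }
}
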