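#' Build a grid of study-design scenarios
#'
#' Crosses every combination of the supplied parameter values into a tidy
#' scenario table, one row per (design, gene hypothesis, statistic) triple,
#' ready to pipe into [exome_power()]. Defaults are the framework's
#' reference configuration: `R = 0.05`, `w = 1`, `Ps = 0.8`, `m = 300`,
#' `M = 20000`, family-wise `alpha = 0.05`.
#'
#' @param n Patient count(s).
#' @param m Candidate mutations per patient after filtering.
#' @param M Genes in the captured region.
#' @param Ps Sensitivity of detecting a true causal mutation.
#' @param R Fraction of patients attributable to the gene (locus
#'   heterogeneity is `1/R`).
#' @param w Relative gene length.
#' @param mode Inheritance model(s): `"recessive"`, `"dominant"`.
#' @param stat Statistic(s): `"Tr"`, `"Td"`, `"Ta"`.
#' @param alpha_family Family-wise significance level.
#' @return A tibble with one row per parameter combination.
#' @examples
#' power_scenarios(n = c(2, 10), R = c(0.05, 1))
#' @export
power_scenarios <- function(n, m = 300, M = 20000, Ps = 0.8, R = 0.05,
                            w = 1, mode = "recessive", stat = "Tr",
                            alpha_family = 0.05) {
  tidyr::expand_grid(
    n = n, m = m, M = M, Ps = Ps, R = R, w = w,
    mode = mode, stat = stat, alpha_family = alpha_family
  )
}

validate_scenarios <- function(scenarios) {
  need <- c("n", "m", "M", "Ps", "R", "w", "mode", "stat", "alpha_family")
  miss <- setdiff(need, names(scenarios))
  if (length(miss)) {
    stop("scenario table is missing columns: ", paste(miss, collapse = ", "))
  }
  with(scenarios, {
    stopifnot(
      all(n >= 1), all(n == floor(n)), all(m >= 0), all(m == floor(m)),
      all(M >= 1), all(Ps >= 0 & Ps <= 1), all(R >= 0 & R <= 1),
      all(w > 0), all(alpha_family > 0 & alpha_family <= 1),
      all(mode %in% c("recessive", "dominant")),
      all(stat %in% c("Ta", "Tr", "Td"))
    )
  })
  tibble::as_tibble(scenarios)
}

power_one <- function(n, m, M, Ps, R, w, mode, stat, alpha_family) {
  null <- null_dist(n, m, M, stat = stat, w = w)
  cut <- significance_cutoff(null, per_gene_alpha(alpha_family, M))
  alt <- alt_dist(n, m, M, Ps, R, mode = mode, stat = stat, w = w)
  list(
    per_gene_alpha = cut$alpha,
    cutoff = cut$cutoff,
    achieved_size = cut$achieved_size,
    power = dist_tail(alt, cut$cutoff)
  )
}

#' Analytic power of exome sequencing for each scenario
#'
#' For every row of a scenario table (see [power_scenarios()]): builds the
#' exact binomial null of the chosen statistic, finds the Bonferroni-level
#' exact cutoff `t*`, and evaluates the power as the upper tail of the
#' alternative distribution at `t*`. For a dominant gene the `Tr` statistic
#' carries no causal signal, so its "power" equals the achieved size of the
#' test (numerically ~0).
#'
#' @param scenarios A data frame with columns `n`, `m`, `M`, `Ps`, `R`,
#'   `w`, `mode`, `stat`, `alpha_family` — typically from
#'   [power_scenarios()].
#' @return The input tibble with columns `per_gene_alpha`, `cutoff`,
#'   `achieved_size` and `power` appended; class `power_grid`, plottable
#'   with [autoplot.power_grid()].
#' @examples
#' power_scenarios(n = 2, R = 1, stat = "Tr") |> exome_power()
#' @export
exome_power <- function(scenarios) {
  scenarios <- validate_scenarios(scenarios)
  res <- purrr::pmap(
    scenarios[c("n", "m", "M", "Ps", "R", "w", "mode", "stat", "alpha_family")],
    power_one
  )
  out <- dplyr::bind_cols(
    scenarios,
    tibble::tibble(
      per_gene_alpha = purrr::map_dbl(res, "per_gene_alpha"),
      cutoff = purrr::map_int(res, "cutoff"),
      achieved_size = purrr::map_dbl(res, "achieved_size"),
      power = purrr::map_dbl(res, "power")
    )
  )
  class(out) <- c("power_grid", class(out))
  out
}

#' Power curve over one varying parameter
#'
#' Convenience wrapper: holds all parameters fixed except one, computes the
#' power at each value, and tags the result so [autoplot()] draws the curve.
#' Because the significance cutoff is a discrete step function of the null,
#' power is not always monotone in `n` — the characteristic zigzag of exact
#' tests.
#'
#' @param vary Name of the parameter to vary: one of `"n"`, `"R"`, `"m"`,
#'   `"Ps"`, `"w"`.
#' @param values Values the varying parameter takes.
#' @inheritParams power_scenarios
#' @return A `power_grid` tibble with an attribute `vary` naming the
#'   varying parameter.
#' @examples
#' power_curve("R", c(0.05, 0.2, 1), n = 40)
#' @export
power_curve <- function(vary, values, n = 200, m = 300, M = 20000, Ps = 0.8,
                        R = 0.05, w = 1, mode = "recessive", stat = "Tr",
                        alpha_family = 0.05) {
  choices <- c("n", "R", "m", "Ps", "w")
  if (!is.character(vary) || length(vary) != 1 || !vary %in% choices) {
    stop("`vary` must be one of: ", paste(choices, collapse = ", "))
  }
  fixed <- list(
    n = n, m = m, M = M, Ps = Ps, R = R, w = w,
    mode = mode, stat = stat, alpha_family = alpha_family
  )
  fixed[[vary]] <- values
  out <- exome_power(do.call(power_scenarios, fixed))
  attr(out, "vary") <- vary
  out
}

#' Plot a power grid
#'
#' Power against the varying parameter, one line per statistic/mode
#' combination. For a grid built with [power_curve()] the x-axis is the
#' varied parameter; otherwise supply `x`.
#'
#' @param object A `power_grid` from [exome_power()] or [power_curve()].
#' @param x Name of the column to place on the x-axis; defaults to the
#'   `vary` attribute set by [power_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_grid <- function(object, x = attr(object, "vary"), ...) {
  if (is.null(x)) stop("no varying parameter recorded; supply `x`")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[x]], y = .data$power,
    colour = interaction(.data$stat, .data$mode, sep = " / "),
    group = interaction(.data$stat, .data$mode, .data$R, .data$m, .data$w, .data$Ps)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = x, y = "power", colour = "statistic / model") +
    ggplot2::theme_minimal()
}

#' Combined power of discovering any of several causal genes
#'
#' With `J` disease genes each discoverable independently with power
#' `P_j`, the probability of identifying at least one is
#' `1 - prod(1 - P_j)`.
#'
#' @param powers Numeric vector of per-gene powers in `[0, 1]`.
#' @return A single probability; 0 for an empty vector.
#' @examples
#' combined_any_power(c(0.5, 0.5))
#' @export
combined_any_power <- function(powers) {
  if (length(powers) == 0L) return(0)
  if (any(powers < 0 | powers > 1)) stop("powers must be probabilities in [0, 1]")
  1 - prod(1 - powers)
}
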