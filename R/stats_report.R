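# Responder and neurite statistics.
#
# The exact 2x2 test is computed from first principles (hypergeometric
# enumeration, two-sided by the sum-of-small-p convention) because the
# responder tables are the headline statistic of the stretch assay; the
# generic group comparisons delegate to the standard R routines behind a
# normality-gated dispatch.

#' Exact two-sided test for a 2x2 contingency table
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities,
#' over all tables with the observed margins, that do not exceed the
#' probability of the observed table. Probabilities within a relative
#' tolerance of 1e-7 of the observed one count as ties and are included.
#'
#' @param a,b,c,d Non-negative integer counts: group-1 responders, group-1
#'   non-responders, group-2 responders, group-2 non-responders. `a` may also
#'   be a 2x2 matrix.
#' @param tie_tol Relative tolerance for treating near-equal point
#'   probabilities as ties.
#' @return One-row tibble: `p_two_sided`, `odds_ratio` (sample OR),
#'   `degenerate` (TRUE when a margin is zero, in which case p = 1).
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             tie_tol = 1e-7) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers.")
  }
  m <- a + c        # column 1 total (responders)
  n2 <- b + d       # column 2 total
  k <- a + b        # row 1 total
  if (m == 0 || n2 == 0 || k == 0 || (c + d) == 0) {
    return(tibble(p_two_sided = 1, odds_ratio = NaN, degenerate = TRUE))
  }
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + tie_tol)])
  or <- (a * d) / (b * c)
  tibble(p_two_sided = min(1, p), odds_ratio = or, degenerate = FALSE)
}

#' Proportion as an exact fraction and a rounded percent
#'
#' Percentages are rounded to the nearest integer, halves away from zero.
#'
#' @param x Numerator count (0 <= x <= n).
#' @param n Denominator count (> 0).
#' @return One-row tibble: `x`, `n`, `fraction`, `percent_exact`, `percent`.
#' @export
proportion_percent <- function(x, n) {
  if (n <= 0) abort("`n` must be > 0.")
  if (x < 0 || x > n) abort("need 0 <= x <= n.")
  pct <- 100 * x / n
  tibble(x = x, n = n, fraction = x / n, percent_exact = pct,
         percent = floor(pct + 0.5))
}

#' Per-group neurite summaries
#'
#' For each group: the percentage of neurite-bearing cells, the mean and SEM
#' of the longest neurite over neurite-bearing cells, and the cumulative
#' distribution of neurite counts over all cells (as a list-column).
#'
#' @param cells Tibble with columns `group`, `longest_neurite_um`,
#'   `n_neurites` (and optionally `neurite_bearing`; otherwise derived as
#'   `n_neurites >= 1`).
#' @return Tibble with one row per group: `group`, `n_cells`, `n_bearing`,
#'   `percent_bearing`, `mean_longest_um`, `sem_longest_um`, `count_cdf`
#'   (list-column of tibbles `n_neurites`, `cum_fraction`).
#' @export
summarize_neurites <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("group", "longest_neurite_um", "n_neurites") %in% names(cells)))
  if (!"neurite_bearing" %in% names(cells)) {
    cells$neurite_bearing <- cells$n_neurites >= 1
  }
  groups <- if (is.factor(cells$group)) levels(cells$group) else unique(cells$group)
  purrr::map_dfr(groups, function(g) {
    rows <- cells[cells$group == g, ]
    if (!nrow(rows)) abort(sprintf("group `%s` has no cells.", g))
    bearing <- rows[rows$neurite_bearing, ]
    nb <- nrow(bearing)
    cdf <- tibble(n_neurites = sort(unique(rows$n_neurites)))
    cdf$cum_fraction <- vapply(cdf$n_neurites,
                               function(k) mean(rows$n_neurites <= k),
                               numeric(1))
    tibble(group = g, n_cells = nrow(rows), n_bearing = nb,
           percent_bearing = proportion_percent(nb, nrow(rows))$percent,
           mean_longest_um = if (nb) mean(bearing$longest_neurite_um) else NA_real_,
           sem_longest_um = if (nb > 1) sd(bearing$longest_neurite_um) / sqrt(nb)
                            else NA_real_,
           count_cdf = list(cdf))
  })
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) z-statistics into K^2 = z1^2 + z2^2, compared against a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector, n >= 8.
#' @return One-row tibble: `k2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson test needs n >= 8.")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - e_b2) / sqrt(var_b2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble(k2 = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
         z_skew = z1, z_kurt = z2, n = n)
}

# normality gate: D'Agostino-Pearson when n >= 8, Shapiro-Wilk for smaller
# samples (where the moment tests are unreliable)
normality_p <- function(x) {
  if (length(x) >= 8) dagostino_pearson(x)$p_value else shapiro.test(x)$p.value
}

# Dunn's rank-based post-hoc z-tests after Kruskal-Wallis, with ties
# correction; p-values unadjusted unless `p_adjust` says otherwise
dunn_posthoc <- function(values, groups, reference = NULL,
                         p_adjust = "none") {
  groups <- as.factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- if (is.null(reference)) {
    utils::combn(lv, 2, simplify = FALSE)
  } else {
    lapply(setdiff(lv, reference), function(g) c(reference, g))
  }
  out <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (mr[[i]] - mr[[j]]) / se
    tibble(comparison = paste(i, "vs", j), statistic = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Normality-gated group comparison
#'
#' Every group is screened for normality (D'Agostino-Pearson, alpha = 0.05;
#' Shapiro-Wilk below n = 8). When all groups pass, the parametric branch is
#' used: Welch's t-test for two groups, one-way ANOVA with Dunnett's post-hoc
#' (against the first group) otherwise. When any group fails, the
#' nonparametric branch is used: Mann-Whitney for two groups, Kruskal-Wallis
#' with Dunn's post-hoc otherwise. Dunn p-values are unadjusted unless
#' `p_adjust` is set.
#'
#' @param data Tibble with columns named by `value` and `group`.
#' @param value,group Column names (strings).
#' @param alpha Significance level of the normality screen.
#' @param p_adjust Multiplicity adjustment for Dunn's post-hoc
#'   (a [stats::p.adjust()] method).
#' @return Tibble with columns `test`, `comparison`, `statistic`, `p_value`;
#'   the dispatch decision is recorded in the `branch` attribute.
#' @export
group_compare <- function(data, value = "value", group = "group",
                          alpha = 0.05, p_adjust = "none") {
  stopifnot(is.data.frame(data), all(c(value, group) %in% names(data)))
  v <- data[[value]]
  g <- as.factor(data[[group]])
  ns <- table(g)
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (any(ns < 3)) abort("need at least 3 values per group.")
  norm_p <- tapply(v, g, normality_p)
  parametric <- all(norm_p >= alpha)
  lv <- levels(g)

  if (parametric && nlevels(g) == 2) {
    tt <- t.test(v ~ g)
    out <- tibble(test = "Welch t", comparison = paste(lv[1], "vs", lv[2]),
                  statistic = unname(tt$statistic), p_value = tt$p.value)
  } else if (parametric) {
    df <- data.frame(v = v, g = g)
    fit <- aov(v ~ g, data = df)
    an <- summary(fit)[[1]]
    omnibus <- tibble(test = "one-way ANOVA", comparison = "omnibus",
                      statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1])
    dn <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(dn)
    post <- tibble(test = "Dunnett",
                   comparison = names(sm$test$coefficients),
                   statistic = unname(sm$test$tstat),
                   p_value = unname(as.numeric(sm$test$pvalues)))
    out <- dplyr::bind_rows(omnibus, post)
  } else if (nlevels(g) == 2) {
    wt <- wilcox.test(v ~ g, exact = FALSE)
    out <- tibble(test = "Mann-Whitney", comparison = paste(lv[1], "vs", lv[2]),
                  statistic = unname(wt$statistic), p_value = wt$p.value)
  } else {
    kw <- kruskal.test(v, g)
    omnibus <- tibble(test = "Kruskal-Wallis", comparison = "omnibus",
                      statistic = unname(kw$statistic), p_value = kw$p.value)
    post <- dunn_posthoc(v, g, reference = lv[1], p_adjust = p_adjust)
    post$test <- "Dunn"
    out <- dplyr::bind_rows(omnibus, post[c("test", "comparison",
                                            "statistic", "p_value")])
  }
  attr(out, "branch") <- if (parametric) "parametric" else "nonparametric"
  attr(out, "normality_p") <- norm_p
  out
}
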