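## Group-comparison statistics: permutation tests on participant-level
## metrics and conventional effect sizes.

stat_mean_difference <- function(values, sizes) {
  mean(values[seq_len(sizes[1])]) -
    mean(values[sizes[1] + seq_len(sizes[2])])
}

stat_anova_f <- function(values, sizes) {
  n <- length(values)
  k <- length(sizes)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in seq_len(k)) {
    v <- values[starts[g]:ends[g]]
    m <- mean(v)
    ssb <- ssb + sizes[g] * (m - grand)^2
    ssw <- ssw + sum((v - m)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation test on group metrics
#'
#' Compares groups of participant-level values with a Monte-Carlo
#' permutation test. For two groups the test statistic is the difference
#' between group means (two-sided, on `|statistic|`); for two or more
#' groups it is the F value of a one-way ANOVA (upper tail). The null
#' distribution is built by random shuffles of group assignment
#' (`null = "shuffle"`, the default); `null = "bootstrap"` resamples the
#' pooled values with replacement instead. The p-value uses the exact-test
#' convention `p = (count(null >= observed) + 1) / (n_perm + 1)`, which
#' never returns 0.
#'
#' @param groups list of numeric vectors, one per group.
#' @param statistic `"mean_difference"` (exactly 2 groups) or `"anova_F"`.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed RNG seed (restored afterwards); `NULL` uses the current
#'   RNG state.
#' @param null `"shuffle"` or `"bootstrap"`.
#' @return list with `statistic`, `observed`, `p_value`, `n_perm`, `seed`,
#'   `null`.
#' @examples
#' permutation_test(list(rnorm(10), rnorm(10, 1)), n_perm = 1000, seed = 1)
#' @export
permutation_test <- function(groups,
                             statistic = c("mean_difference", "anova_F"),
                             n_perm = 10000, seed = NULL,
                             null = c("shuffle", "bootstrap")) {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  if (!is.list(groups) || length(groups) < 2) {
    stop_clamp("'groups' must be a list of at least two numeric vectors",
               "invalid_groups_error")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    stop_clamp("every group must contain at least one value",
               "invalid_groups_error")
  }
  if (statistic == "mean_difference" && length(groups) != 2) {
    stop_clamp("'mean_difference' requires exactly two groups",
               "invalid_groups_error")
  }
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  stat_fun <- if (statistic == "mean_difference") {
    function(v) abs(stat_mean_difference(v, sizes))
  } else {
    function(v) stat_anova_f(v, sizes)
  }
  observed_signed <- if (statistic == "mean_difference") {
    stat_mean_difference(values, sizes)
  } else {
    stat_anova_f(values, sizes)
  }
  observed <- stat_fun(values)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      v <- values[sample.int(n, n, replace = (null == "bootstrap"))]
      stat_fun(v)
    }, numeric(1))
  })
  p <- (sum(null_stats >= observed) + 1) / (n_perm + 1)
  list(statistic = statistic, observed = observed_signed, p_value = p,
       n_perm = n_perm, seed = seed, null = null)
}

#' Effect sizes for group comparisons
#'
#' Pooled-SD Cohen's d (two independent groups), d_z (paired samples,
#' `mean(diff)/sd(diff)`), eta squared and partial eta squared from a
#' one-way decomposition (`SS_between / SS_total` and
#' `SS_between / (SS_between + SS_within)`). Quantities undefined because
#' of zero variance are returned as `NA` and named in `undefined`.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @param paired if `TRUE`, the two groups are paired samples of equal
#'   length and d_z is computed on their differences.
#' @return list with `cohens_d`, `d_z`, `eta_squared`,
#'   `partial_eta_squared`, `undefined` (character vector).
#' @export
effect_sizes <- function(groups, paired = FALSE) {
  sizes <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  undefined <- character(0)

  cohens_d <- NA_real_
  d_z <- NA_real_
  if (length(groups) == 2) {
    n1 <- sizes[1]; n2 <- sizes[2]
    v1 <- var(groups[[1]]); v2 <- var(groups[[2]])
    pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    if (is.finite(pooled) && pooled > 0) {
      cohens_d <- (mean(groups[[1]]) - mean(groups[[2]])) / pooled
    } else {
      undefined <- c(undefined, "cohens_d")
    }
    if (paired) {
      if (n1 != n2) {
        stop_clamp("paired samples must have equal length",
                   "invalid_groups_error")
      }
      d <- groups[[1]] - groups[[2]]
      if (is.finite(sd(d)) && sd(d) > 0) {
        d_z <- mean(d) / sd(d)
      } else {
        undefined <- c(undefined, "d_z")
      }
    }
  }

  grand <- mean(values)
  ssb <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sst <- ssb + ssw
  if (sst > 0) {
    eta2 <- ssb / sst
    peta2 <- ssb / (ssb + ssw)
  } else {
    eta2 <- NA_real_
    peta2 <- NA_real_
    undefined <- c(undefined, "eta_squared", "partial_eta_squared")
  }
  list(cohens_d = unname(cohens_d), d_z = d_z, eta_squared = eta2,
       partial_eta_squared = peta2, undefined = undefined)
}

#' Conventional parametric tests (plumbing)
#'
#' Thin wrappers over [stats::t.test()] and a one-way F so a full
#' statistics block (classical test + permutation p + effect size) can be
#' emitted for each comparison.
#'
#' @param groups list of numeric vectors.
#' @param paired passed to [stats::t.test()] when there are two groups.
#' @return list with the t or F statistic, degrees of freedom, `p_value`,
#'   and the 95% CI for two-group comparisons.
#' @export
classical_test <- function(groups, paired = FALSE) {
  if (length(groups) == 2) {
    tt <- stats::t.test(groups[[1]], groups[[2]], paired = paired,
                        var.equal = TRUE)
    list(test = if (paired) "paired t" else "t",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, conf_int = as.numeric(tt$conf.int))
  } else {
    values <- unlist(groups, use.names = FALSE)
    sizes <- lengths(groups)
    f <- stat_anova_f(values, sizes)
    df1 <- length(groups) - 1
    df2 <- length(values) - length(groups)
    list(test = "one-way ANOVA F", statistic = f, df = c(df1, df2),
         p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
}
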