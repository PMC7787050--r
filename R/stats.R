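# The testing ladder: Levene's homogeneity gate, one-way ANOVA, Tukey HSD or
# Dunnett's T3 post hoc, Student's t, all at alpha = 0.05 by default.
#
# All tests take a data frame plus a value column and a grouping column, in
# keeping with the rest of the package; group sizes below 2 are rejected.

.group_split <- function(data, value, group) {
  data <- as_tibble(data)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  groups <- split(v[keep], factor(g[keep], levels = unique(g[keep])))
  if (length(groups) < 2) abort("need at least 2 groups.")
  small <- names(groups)[vapply(groups, length, 1L) < 2]
  if (length(small) > 0) {
    abort(paste0("group(s) with fewer than 2 observations: ",
                 paste(small, collapse = ", ")))
  }
  groups
}

.anova_from_groups <- function(groups) {
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, 1)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  df1 <- k - 1
  df2 <- N - k
  if (ss_within <= .Machine$double.eps * max(1, ss_between, sum(unlist(groups)^2))) {
    if (ss_between <= .Machine$double.eps * max(1, sum(unlist(groups)^2))) {
      return(list(statistic = 0, df1 = df1, df2 = df2, p_value = 1, degenerate = TRUE))
    }
    return(list(statistic = Inf, df1 = df1, df2 = df2, p_value = 0, degenerate = TRUE))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, df1 = df1, df2 = df2,
       p_value = pf(f, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Standard between/within F test with (k - 1, N - k) degrees of freedom,
#' assuming equal variances. With two groups the F statistic equals the
#' square of the pooled t statistic.
#'
#' @param data A data frame.
#' @param value,group Unquoted column names of the measurements and the
#'   grouping variable.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`, `method`.
#' @export
oneway_anova <- function(data, value, group) {
  groups <- .group_split(data, {{ value }}, {{ group }})
  res <- .anova_from_groups(groups)
  tibble(statistic = res$statistic, df1 = res$df1, df2 = res$df2,
         p_value = res$p_value, method = "one-way ANOVA")
}

#' Levene's test for homogeneity of variance
#'
#' The classic mean-centred form: a one-way ANOVA applied to the absolute
#' deviations of each observation from its group mean. Returns that ANOVA's
#' F and p exactly. When all values are identical across groups the test is
#' degenerate and reported as W = 0, p = 1 with `degenerate = TRUE`.
#'
#' @inheritParams oneway_anova
#' @return A one-row tibble: `statistic` (W), `df1`, `df2`, `p_value`,
#'   `degenerate`, `method`.
#' @export
levene_test <- function(data, value, group) {
  groups <- .group_split(data, {{ value }}, {{ group }})
  devs <- lapply(groups, function(x) abs(x - mean(x)))
  res <- .anova_from_groups(devs)
  tibble(statistic = res$statistic, df1 = res$df1, df2 = res$df2,
         p_value = res$p_value, degenerate = res$degenerate,
         method = "Levene (mean-centred)")
}

#' Student's two-sample t-test (pooled variance)
#'
#' Two-sided pooled-variance t-test, used for the renewal-vs-control and
#' soluble-vs-insoluble contrasts.
#'
#' @param a,b Numeric vectors (both of length >= 2).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
student_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("both samples need n >= 2.")
  df <- length(a) + length(b) - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (sp2 <= .Machine$double.eps * max(1, mean(a)^2, mean(b)^2)) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                  df = df, p_value = if (eq) 1 else 0,
                  method = "Student t (pooled)"))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  tibble(statistic = tstat, df = df,
         p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
         method = "Student t (pooled)")
}

.pairs_of <- function(labels) {
  k <- length(labels)
  idx <- utils::combn(k, 2)
  tibble(i = idx[1, ], j = idx[2, ],
         group1 = labels[idx[1, ]], group2 = labels[idx[2, ]])
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise comparisons under the equal-variance assumption, using the
#' studentized-range distribution with the pooled within-group variance
#' (Tukey-Kramer for unequal group sizes).
#'
#' @inheritParams oneway_anova
#' @param alpha Familywise significance level.
#' @return A tibble with one row per pair: `group1`, `group2`, `mean_diff`,
#'   `statistic` (studentized range q), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  groups <- .group_split(data, {{ value }}, {{ group }})
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  df <- sum(ns) - k
  sp2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1)) / df
  pr <- .pairs_of(names(groups))
  diff <- means[pr$i] - means[pr$j]
  if (sp2 <= .Machine$double.eps * max(1, means^2)) {
    q <- ifelse(abs(diff) < sqrt(.Machine$double.eps), 0, Inf)
  } else {
    se <- sqrt(sp2 / 2 * (1 / ns[pr$i] + 1 / ns[pr$j]))
    q <- abs(diff) / se
  }
  p <- unname(ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  tibble(group1 = pr$group1, group2 = pr$group2, mean_diff = unname(diff),
         statistic = unname(q), df = df, p_adj = p,
         significant = p < alpha, method = "Tukey HSD")
}

# Studentized maximum modulus distribution function:
# P(max_{i=1..m} |T_i| <= q) for m independent N(0,1) numerators over one
# common chi(df)/sqrt(df) denominator. Integrated over the chi-square density.
psmm <- function(q, m, df) {
  vapply(q, function(qi) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    if (qi <= 0) return(0)
    if (!is.finite(df)) return((2 * pnorm(qi) - 1)^m)
    f <- function(x) (2 * pnorm(qi * sqrt(x / df)) - 1)^m * dchisq(x, df)
    integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, 1)
}

# Upper-alpha quantile of the studentized maximum modulus distribution.
qsmm <- function(p, m, df) {
  vapply(p, function(pi) {
    uniroot(function(q) psmm(q, m, df) - pi,
            lower = 1e-8, upper = 100, tol = 1e-9)$root
  }, 1)
}

#' Dunnett's T3 pairwise comparisons
#'
#' Heteroscedasticity-robust pairwise comparisons: each pair uses the Welch
#' statistic \eqn{t_{ij} = (\bar x_i - \bar x_j)/\sqrt{s_i^2/n_i + s_j^2/n_j}}
#' with Welch-Satterthwaite degrees of freedom, referred to the studentized
#' maximum modulus distribution with \eqn{m = k(k-1)/2} comparisons (each
#' pair evaluated at its own df, as in the standard T3 procedure). When both
#' groups of a pair have zero variance the comparison degenerates to exact
#' equality: p = 1 if the means agree, p = 0 otherwise.
#'
#' @inheritParams tukey_hsd
#' @return A tibble with one row per pair: `group1`, `group2`, `mean_diff`,
#'   `statistic` (Welch t), `df`, `p_adj`, `significant`.
#' @export
dunnett_t3 <- function(data, value, group, alpha = 0.05) {
  groups <- .group_split(data, {{ value }}, {{ group }})
  k <- length(groups)
  m <- k * (k - 1) / 2
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  vars <- vapply(groups, function(x) sum((x - mean(x))^2) / (length(x) - 1), 1)
  pr <- .pairs_of(names(groups))
  res <- purrr::pmap_dfr(pr, function(i, j, group1, group2) {
    vi <- vars[i] / ns[i]; vj <- vars[j] / ns[j]
    diff <- means[i] - means[j]
    if (vi + vj <= .Machine$double.eps * max(1, means[i]^2, means[j]^2)) {
      eq <- abs(diff) < sqrt(.Machine$double.eps)
      return(tibble(group1 = group1, group2 = group2, mean_diff = unname(diff),
                    statistic = if (eq) 0 else Inf * sign(diff),
                    df = NA_real_, p_adj = if (eq) 1 else 0))
    }
    tstat <- unname(diff / sqrt(vi + vj))
    df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
    tibble(group1 = group1, group2 = group2, mean_diff = unname(diff),
           statistic = unname(tstat), df = unname(df),
           p_adj = 1 - psmm(abs(tstat), m, df))
  })
  res$significant <- res$p_adj < alpha
  res$method <- "Dunnett T3"
  res
}

# Compact letter display by the insertion algorithm over the significance
# matrix: start from one class holding all groups; every significant pair
# splits the classes containing both members; absorbed (subset) classes are
# dropped. Ties are broken by group order in the input.
compact_letters <- function(labels, sig_pairs) {
  classes <- list(labels)
  if (nrow(sig_pairs) > 0) {
    for (r in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs$group1[r]; g2 <- sig_pairs$group2[r]
      new_classes <- list()
      for (cl in classes) {
        if (g1 %in% cl && g2 %in% cl) {
          new_classes <- c(new_classes, list(setdiff(cl, g1)), list(setdiff(cl, g2)))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      keep <- rep(TRUE, length(new_classes))
      for (a in seq_along(new_classes)) {
        for (b in seq_along(new_classes)) {
          if (a != b && keep[b] &&
              all(new_classes[[a]] %in% new_classes[[b]]) &&
              (length(new_classes[[a]]) < length(new_classes[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      classes <- unique(new_classes[keep])
    }
  }
  ord <- order(vapply(classes, function(cl) min(match(cl, labels)), 1))
  classes <- classes[ord]
  letters_out <- vapply(labels, function(g) {
    paste(letters[which(vapply(classes, function(cl) g %in% cl, TRUE))],
          collapse = "")
  }, "")
  tibble(group = labels, letters = unname(letters_out))
}

#' Full group comparison following the homogeneity-gated ladder
#'
#' Runs Levene's test on the groups; when homogeneity holds (Levene p >=
#' `alpha`) the post hoc is Tukey HSD, otherwise Dunnett's T3. The one-way
#' ANOVA omnibus is always included, and group letters (compact letter
#' display, as used to annotate figures) are derived from the adjusted
#' pairwise significances.
#'
#' @inheritParams tukey_hsd
#' @return An object of class `mt_comparison`: a list with elements `levene`,
#'   `anova`, `posthoc`, `letters`, `group_stats`, `method`, `alpha`.
#'   Use [tidy()] for the pairwise table and [glance()] for the omnibus row.
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  groups <- .group_split(data, {{ value }}, {{ group }})
  df_long <- tibble(
    value = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
  lev <- levene_test(df_long, value, group)
  aov_res <- oneway_anova(df_long, value, group)
  homogeneous <- lev$p_value >= alpha
  post <- if (homogeneous) {
    tukey_hsd(df_long, value, group, alpha)
  } else {
    dunnett_t3(df_long, value, group, alpha)
  }
  letters_tbl <- compact_letters(names(groups),
                                 post[post$significant, c("group1", "group2")])
  gs <- df_long %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean = mean(.data$value), sem = .sem(.data$value),
              .groups = "drop")
  structure(
    list(levene = lev, anova = aov_res, posthoc = post,
         letters = left_join(gs, letters_tbl, by = "group"),
         method = post$method[1], alpha = alpha),
    class = "mt_comparison"
  )
}

#' @export
print.mt_comparison <- function(x, ...) {
  cat("Group comparison (alpha =", x$alpha, ")\n")
  cat("  Levene p =", format(x$levene$p_value, digits = 4),
      "->", x$method, "post hoc\n")
  cat("  ANOVA F(", x$anova$df1, ",", x$anova$df2, ") =",
      format(x$anova$statistic, digits = 4),
      ", p =", format(x$anova$p_value, digits = 4), "\n", sep = "")
  print(x$letters)
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `mt_comparison` object.
#' @param ... Unused.
#' @method tidy mt_comparison
#' @export
tidy.mt_comparison <- function(x, ...) {
  x$posthoc
}

#' @rdname compare_groups
#' @method glance mt_comparison
#' @export
glance.mt_comparison <- function(x, ...) {
  tibble(
    method = x$method,
    levene_statistic = x$levene$statistic,
    levene_p = x$levene$p_value,
    anova_statistic = x$anova$statistic,
    anova_df1 = x$anova$df1,
    anova_df2 = x$anova$df2,
    anova_p = x$anova$p_value,
    alpha = x$alpha,
    n_groups = nrow(x$letters)
  )
}
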