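#' Two-sample t test with Cohen's d
#'
#' Student's pooled-variance independent-samples t test with
#' `df = n_a + n_b - 2`, two-sided p, and Cohen's d computed against the
#' pooled SD `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`
#' (for equal group sizes this is `sqrt((s_a^2 + s_b^2) / 2)`). Either
#' group may be given as a raw numeric vector or as published summary
#' statistics `c(mean = , sd = , n = )` (or a list with those names), so
#' printed group tables can be re-analyzed without raw data. A Welch test
#' (Satterthwaite df, unpooled d denominator unchanged) is available via
#' `var_equal = FALSE`.
#'
#' @param group_a,group_b numeric vectors, or summaries with `mean`, `sd`,
#'   `n`.
#' @param metric_name label carried on the result.
#' @param var_equal pooled test when `TRUE` (default).
#' @return A `group_comparison`: list with the group summaries, `t_stat`,
#'   `df`, `p_two_sided`, `cohens_d`, `test = "student_t"` (or
#'   `"welch_t"`).
#' @examples
#' t_and_d(c(mean = 9.63, sd = 3.23, n = 18), c(mean = 5.96, sd = 2.73, n = 18))
#' @export
t_and_d <- function(group_a, group_b, metric_name = "metric",
                    var_equal = TRUE) {
  a <- as_summary(group_a); b <- as_summary(group_b)
  if (a$n < 2 || b$n < 2)
    stop("both groups need n >= 2", call. = FALSE)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0)
    stop("zero pooled variance: groups are constant", call. = FALSE)
  d <- (a$mean - b$mean) / sqrt(sp2)
  if (var_equal) {
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t_stat <- (a$mean - b$mean) / se
  structure(
    list(metric_name = metric_name,
         mean_a = a$mean, sd_a = a$sd, n_a = a$n,
         mean_b = b$mean, sd_b = b$sd, n_b = b$n,
         t_stat = t_stat, df = df,
         p_two_sided = 2 * pt(-abs(t_stat), df),
         cohens_d = d,
         test = if (var_equal) "student_t" else "welch_t"),
    class = "group_comparison")
}

as_summary <- function(g) {
  is_sum <- (is.list(g) || !is.null(names(g))) &&
    all(c("mean", "sd", "n") %in% names(g))
  if (is_sum) {
    g <- as.list(g)
    return(list(mean = as.numeric(g$mean), sd = as.numeric(g$sd),
                n = as.numeric(g$n)))
  }
  if (!is.numeric(g))
    stop("group input must be a numeric sample or mean/sd/n summary",
         call. = FALSE)
  g <- g[!is.na(g)]
  list(mean = mean(g), sd = sd(g), n = length(g))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent ordinal samples with midrank tie
#' handling. The U statistic reported is for the first sample
#' (`U_a = R_a - n_a (n_a + 1) / 2`, the number of pairs where an `a` value
#' exceeds a `b` value, counting ties as 1/2). The p-value is computed by
#' exact enumeration of group assignments when the smaller sample has at
#' most 8 observations (valid under ties, two-sided as twice the smaller
#' tail, capped at 1), and otherwise by the normal approximation with tie
#' correction and optional continuity correction.
#'
#' @param sample_a,sample_b numeric (or ordered-factor-coercible) vectors.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation; default `TRUE`.
#' @param exact_max largest size of the smaller sample for which the exact
#'   permutation distribution is enumerated.
#' @return A `group_comparison` with `u_stat`, `p_two_sided`,
#'   `test = "mann_whitney"`, and the usual group summaries.
#' @export
mann_whitney <- function(sample_a, sample_b, continuity = TRUE,
                         exact_max = 8L) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both samples must be nonempty", call. = FALSE)
  na <- length(a); nb <- length(b); nn <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (min(na, nb) <= exact_max && choose(nn, min(na, nb)) <= 5e5) {
    # exact permutation distribution of U under exchangeability
    small_first <- na <= nb
    k <- if (small_first) na else nb
    combos <- combn(nn, k)
    ra <- colSums(matrix(r[combos], nrow = k))
    us <- ra - k * (k + 1) / 2
    u_ref <- if (small_first) u else na * nb - u   # U of the enumerated side
    p_lo <- mean(us <= u_ref + 1e-9)
    p_hi <- mean(us >= u_ref - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma <- sqrt(na * nb / 12 * (nn + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- if (continuity) 0.5 else 0
      z <- (u - mu - sign(u - mu) * cc) / sigma
      p <- 2 * pnorm(-abs(z))
    }
  }
  structure(
    list(metric_name = "mann_whitney",
         mean_a = mean(a), sd_a = if (na > 1) sd(a) else NA_real_, n_a = na,
         mean_b = mean(b), sd_b = if (nb > 1) sd(b) else NA_real_, n_b = nb,
         t_stat = NA_real_, df = NA_real_,
         p_two_sided = min(1, p), cohens_d = NA_real_,
         u_stat = u, test = "mann_whitney"),
    class = "group_comparison")
}

#' Pearson correlation with two-sided p
#'
#' Product-moment correlation with the t-transform p-value on `n - 2`
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, nonconstant.
#' @param x_name,y_name labels carried on the result.
#' @return A `correlation_result`: list with `r`, `p_two_sided`, `n`.
#' @export
pearson_cor <- function(x, y, x_name = deparse(substitute(x)),
                        y_name = deparse(substitute(y))) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(x_name = x_name, y_name = y_name,
         r = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%s, %s) = %.4f, p = %.4g, n = %d\n",
              x$x_name, x$y_name, x$r, x$p_two_sided, x$n))
  invisible(x)
}

#' Summary of a score column
#'
#' Arithmetic mean and sample SD, e.g. of a group's AQ scores.
#'
#' @param values numeric vector.
#' @return Named numeric `c(mean, sd, n)`; `sd` is `NA` for a single value.
#' @export
score_summary <- function(values) {
  v <- as.numeric(values); v <- v[!is.na(v)]
  if (!length(v)) stop("no values", call. = FALSE)
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
    n = length(v))
}

#' Compare the synchrony features of two groups
#'
#' Runs [t_and_d()] for each requested metric of a per-dyad feature table
#' (one row per dyad with a two-level group column), mirroring the
#' across-group results layout: metric, group means/SDs, t, df, p, d.
#'
#' @param features data frame with one row per dyad.
#' @param metrics character vector of numeric columns to compare; defaults
#'   to the four synchrony features present in the table.
#' @param group_col name of the two-level group column; the first level in
#'   sorted order (conventionally `"ASD" < "TD"`, so pass `ref` to choose)
#'   is group B and `ref` is group A.
#' @param ref level treated as group A (default `"TD"` when present).
#' @param exclude optional dyad id(s) (matched against a `dyad_id` column)
#'   removed before testing — the leave-one-pair-out sensitivity analysis.
#' @param var_equal pooled test when `TRUE`.
#' @return A `group_comparison_table`: named list of `group_comparison`
#'   objects.
#' @export
compare_groups <- function(features, metrics = NULL, group_col = "group",
                           ref = NULL, exclude = NULL, var_equal = TRUE) {
  stopifnot(is.data.frame(features), group_col %in% names(features))
  if (!is.null(exclude)) {
    if (!"dyad_id" %in% names(features))
      stop("exclude requires a dyad_id column", call. = FALSE)
    if (!all(exclude %in% features$dyad_id))
      stop("unknown dyad id(s): ",
           paste(setdiff(exclude, features$dyad_id), collapse = ", "),
           call. = FALSE)
    features <- features[!features$dyad_id %in% exclude, , drop = FALSE]
  }
  g <- as.character(features[[group_col]])
  lev <- sort(unique(g))
  if (length(lev) != 2)
    stop("group column must have exactly two levels, got ",
         length(lev), call. = FALSE)
  ref <- ref %||% if ("TD" %in% lev) "TD" else lev[1]
  if (!ref %in% lev) stop("ref level not present", call. = FALSE)
  other <- setdiff(lev, ref)
  if (is.null(metrics))
    metrics <- intersect(c("density", "mean_ms", "sd_ms", "kurtosis"),
                         names(features))
  out <- lapply(metrics, function(m) {
    t_and_d(features[[m]][g == ref], features[[m]][g == other],
            metric_name = m, var_equal = var_equal)
  })
  names(out) <- metrics
  structure(out, groups = c(a = ref, b = other),
            class = "group_comparison_table")
}

#' Leave-one-dyad-out sensitivity re-test
#'
#' Recomputes [t_and_d()] for one metric with a single dyad excluded from
#' its group, to check that a group difference is not driven by an outlier
#' pair.
#'
#' @param features per-dyad feature table with `dyad_id` and group columns.
#' @param metric column to test.
#' @param excluded_dyad dyad id to drop.
#' @inheritParams compare_groups
#' @return A `group_comparison`.
#' @export
leave_one_out <- function(features, metric, excluded_dyad,
                          group_col = "group", ref = NULL) {
  compare_groups(features, metrics = metric, group_col = group_col,
                 ref = ref, exclude = excluded_dyad)[[metric]]
}

#' @export
print.group_comparison <- function(x, ...) {
  if (identical(x$test, "mann_whitney")) {
    cat(sprintf("Mann-Whitney U = %.1f, p = %.4g (n = %d vs %d)\n",
                x$u_stat, x$p_two_sided, x$n_a, x$n_b))
  } else {
    cat(sprintf("%s: M = %.3f (SD %.3f, n %d) vs M = %.3f (SD %.3f, n %d)\n",
                x$metric_name, x$mean_a, x$sd_a, x$n_a,
                x$mean_b, x$sd_b, x$n_b))
    cat(sprintf("  t(%s) = %.2f, p = %.4g, Cohen's d = %.2f\n",
                format(round(x$df, 2)), x$t_stat, x$p_two_sided, x$cohens_d))
  }
  invisible(x)
}

#' @export
print.group_comparison_table <- function(x, ...) {
  gr <- attr(x, "groups")
  cat(sprintf("Group comparison: %s (A) vs %s (B)\n", gr["a"], gr["b"]))
  cat(sprintf("%-10s %10s %10s %8s %5s %10s %8s\n",
              "metric", "mean_A(SD)", "mean_B(SD)", "t", "df", "p", "d"))
  for (m in names(x)) {
    cc <- x[[m]]
    cat(sprintf("%-10s %5.2f(%4.2f) %5.2f(%4.2f) %8.2f %5d %10.4g %8.2f\n",
                m, cc$mean_a, cc$sd_a, cc$mean_b, cc$sd_b, cc$t_stat,
                as.integer(round(cc$df)), cc$p_two_sided, cc$cohens_d))
  }
  invisible(x)
}

#' @export
as.data.frame.group_comparison_table <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(m) {
    cc <- x[[m]]
    data.frame(metric = m, mean_a = cc$mean_a, sd_a = cc$sd_a, n_a = cc$n_a,
               mean_b = cc$mean_b, sd_b = cc$sd_b, n_b = cc$n_b,
               t = cc$t_stat, df = cc$df, p = cc$p_two_sided,
               cohens_d = cc$cohens_d)
  }))
}
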