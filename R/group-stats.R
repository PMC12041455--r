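new_mea_test <- function(df, details = NULL) {
  structure(list(result = df, details = details), class = "mea_test")
}

#' @export
print.mea_test <- function(x, ...) {
  print(x$result, ...)
  invisible(x)
}

#' @export
tidy.mea_test <- function(x, ...) x$result

#' @export
glance.mea_test <- function(x, ...) {
  r <- x$result
  r[1, intersect(c("method", "statistic", "df1", "df2", "df", "p_value"),
                 names(r)), drop = FALSE]
}

#' Welch's unpaired two-tailed t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric value vectors (each n >= 2).
#' @return A `mea_test`; `tidy()` gives a one-row tibble with `statistic`,
#'   `df`, `p_value`, `estimate` (mean of `a` minus mean of `b`) and the group
#'   means.
#' @export
#' @examples
#' tidy(welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6)))
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    abort("each group needs at least 2 values.")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    res <- tibble(method = "Welch t", statistic = 0,
                  df = length(a) + length(b) - 2, p_value = 1,
                  estimate = 0, mean_a = mean(a), mean_b = mean(b))
    return(new_mea_test(res))
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  new_mea_test(tibble(
    method = "Welch t",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = mean(a) - mean(b),
    mean_a = mean(a), mean_b = mean(b)), details = ht)
}

check_groups <- function(groups, min_groups = 3) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < min_groups)
    abort(sprintf("at least %d groups are required.", min_groups))
  if (any(vapply(groups, length, integer(1)) < 2))
    abort("each group needs at least 2 values.")
  groups
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' @param groups List of numeric value vectors (>= 3 groups, each n >= 2).
#' @return A `mea_test`; `tidy()` gives `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
welch_anova <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, sd, numeric(1)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1) {
    return(new_mea_test(tibble(method = "Welch one-way ANOVA",
                               statistic = 0, df1 = length(groups) - 1,
                               df2 = Inf, p_value = 1)))
  }
  ht <- oneway.test(x ~ g, var.equal = FALSE)
  new_mea_test(tibble(
    method = "Welch one-way ANOVA",
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]),
    df2 = unname(ht$parameter[2]),
    p_value = ht$p.value), details = ht)
}

#' Brown-Forsythe heteroscedastic one-way ANOVA
#'
#' The Brown-Forsythe F* statistic: between-group sum of squares divided by
#' `sum((1 - n_i/N) * s_i^2)`, with Satterthwaite-approximated denominator
#' degrees of freedom. (This is the ANOVA variant robust to unequal
#' variances, not the Levene-type spread test of the same name.)
#'
#' @param groups List of numeric value vectors (>= 3 groups, each n >= 2).
#' @return A `mea_test`; `tidy()` gives `statistic` (F*), `df1`, `df2`,
#'   `p_value`.
#' @export
brown_forsythe_anova <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, var, numeric(1))
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  ci <- (1 - n / N) * s2
  den <- sum(ci)
  if (den == 0) {
    p <- if (num == 0) 1 else 0
    return(new_mea_test(tibble(method = "Brown-Forsythe one-way ANOVA",
                               statistic = if (num == 0) 0 else Inf,
                               df1 = k - 1, df2 = Inf, p_value = p)))
  }
  f_star <- num / den
  df2 <- den^2 / sum(ci^2 / (n - 1))
  p <- pf(f_star, k - 1, df2, lower.tail = FALSE)
  new_mea_test(tibble(
    method = "Brown-Forsythe one-way ANOVA",
    statistic = f_star, df1 = k - 1, df2 = df2, p_value = p))
}

#' Two-way ANOVA with post-hoc Tukey HSD
#'
#' Fits `value ~ f1 * f2` (main effects and interaction) and runs Tukey's
#' honestly-significant-difference test across the four (or more) factor-cell
#' combinations, using the studentized-range distribution; unbalanced cells
#' get the Tukey-Kramer adjustment (the behavior of [stats::TukeyHSD()]).
#'
#' @param data Data frame.
#' @param value,f1,f2 Column names (strings) of the response and the two
#'   categorical factors.
#' @return A `mea_test`; `tidy()` gives the ANOVA table (one row per term)
#'   and the `tukey` element of `$details` the pairwise adjusted p values.
#' @export
two_way_anova_tukey <- function(data, value, f1, f2) {
  stopifnot(is.data.frame(data),
            all(c(value, f1, f2) %in% names(data)))
  df <- data.frame(y = data[[value]],
                   a = factor(data[[f1]]),
                   b = factor(data[[f2]]))
  df <- df[complete.cases(df), ]
  cell_n <- table(df$a, df$b)
  if (any(cell_n < 2)) abort("every factor cell needs at least 2 values.")
  fit <- aov(y ~ a * b, data = df)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  terms[terms == "a"] <- f1
  terms[terms == "b"] <- f2
  terms[terms == "a:b"] <- paste0(f1, ":", f2)
  anova_tbl <- tibble(
    term = terms,
    df = sm[["Df"]],
    sum_sq = sm[["Sum Sq"]],
    statistic = sm[["F value"]],
    p_value = sm[["Pr(>F)"]])
  cell <- interaction(df$a, df$b, sep = ":")
  tk <- TukeyHSD(aov(y ~ cell, data = data.frame(y = df$y, cell = cell)))$cell
  tukey_tbl <- tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"])
  new_mea_test(anova_tbl[!is.na(anova_tbl$statistic), ],
               details = list(fit = fit, tukey = tukey_tbl))
}

#' Repeated-measures one-way ANOVA
#'
#' Within-subject one-way ANOVA for paired designs (e.g. the same larva
#' before and after PTZ): subject is a blocking factor and the condition
#' effect is tested against the subject-by-condition residual. With two
#' conditions the F statistic equals the square of the paired t statistic.
#' Only complete cases (subjects observed in every condition) are used.
#'
#' @param data Data frame.
#' @param value,condition,subject Column names (strings).
#' @return A `mea_test`; `tidy()` gives `statistic` (F), `df1`, `df2`,
#'   `p_value`, `n_subjects`.
#' @export
rm_one_way_anova <- function(data, value, condition, subject) {
  stopifnot(is.data.frame(data),
            all(c(value, condition, subject) %in% names(data)))
  df <- data.frame(y = data[[value]],
                   cond = factor(data[[condition]]),
                   id = factor(data[[subject]]))
  df <- df[complete.cases(df), ]
  k <- nlevels(df$cond)
  if (k < 2) abort("at least 2 conditions are required.")
  full <- names(which(table(df$id) == k))
  df <- df[df$id %in% full, ]
  df$id <- droplevels(df$id)
  n <- nlevels(df$id)
  if (n < 3) abort("at least 3 complete subjects are required.")
  # within-subject decomposition
  grand <- mean(df$y)
  cond_m <- tapply(df$y, df$cond, mean)
  subj_m <- tapply(df$y, df$id, mean)
  ss_cond <- n * sum((cond_m - grand)^2)
  fitted <- cond_m[df$cond] + subj_m[df$id] - grand
  ss_err <- sum((df$y - fitted)^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) { if (ms_cond == 0) 0 else Inf } else ms_cond / ms_err
  p <- if (is.infinite(f)) 0 else if (ms_err == 0) 1 else
    pf(f, df1, df2, lower.tail = FALSE)
  new_mea_test(tibble(
    method = "repeated-measures one-way ANOVA",
    statistic = f, df1 = df1, df2 = df2, p_value = p,
    n_subjects = n))
}

#' ROUT robust outlier flagging
#'
#' The ROUT procedure (robust fit followed by a false-discovery-rate test on
#' residuals) specialized to a one-sample location fit: the robust "fit" is
#' the sample median, the robust scale is the RSDR (the 68.27th percentile of
#' absolute residuals times `N/(N - 1)`), each point gets a two-tailed t
#' p value from `|residual|/RSDR` with `N - 1` degrees of freedom, and points
#' are flagged by Benjamini-Hochberg at FDR level `Q`. Outlier removal in the
#' pipeline is always an explicit, logged, opt-in step - this function only
#' partitions the data.
#'
#' @param values Numeric vector (n >= 3).
#' @param q FDR level Q in percent (default 1).
#' @return Tibble with one row per input value: `value`, `residual`,
#'   `p_value`, `outlier`; the RSDR is attached as attribute `rsdr`.
#' @export
#' @examples
#' rout_outliers(c(10.0, 10.1, 9.9, 10.05, 50))
rout_outliers <- function(values, q = 1) {
  values <- as.numeric(values)
  if (length(values) < 3) abort("ROUT needs at least 3 values.")
  if (any(is.na(values))) abort("missing values are not allowed.")
  check_number(q, "q", lower = 0, strict_lower = TRUE, upper = 100)
  n <- length(values)
  center <- median(values)
  resid <- values - center
  p68 <- quantile(abs(resid), 0.6827, names = FALSE, type = 7)
  rsdr <- p68 * n / (n - 1)
  if (rsdr == 0) {
    # degenerate spread: any deviation from the median is an outlier
    out <- resid != 0
    res <- tibble(value = values, residual = resid,
                  p_value = ifelse(out, 0, 1), outlier = out)
    attr(res, "rsdr") <- 0
    return(res)
  }
  tstat <- abs(resid) / rsdr
  p <- 2 * pt(tstat, df = n - 1, lower.tail = FALSE)
  flag <- p.adjust(p, method = "BH") <= q / 100
  res <- tibble(value = values, residual = resid, p_value = p,
                outlier = flag)
  attr(res, "rsdr") <- rsdr
  res
}
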