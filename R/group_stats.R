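#' Cohen's d for two samples
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled SD
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @return The standardized mean difference (unitless).
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs n >= 2")
  sp <- pooled_sd(x, y)
  if (sp == 0) stop("pooled SD is zero")
  (mean(x) - mean(y)) / sp
}

pooled_sd <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
}

#' Two-sample t test (pooled variance)
#'
#' Student's t with pooled variance on `n1 + n2 - 2` degrees of freedom and a
#' two-sided p value; Welch's unequal-variance form is available by flag.
#' Identical samples give t = 0, p = 1; zero pooled variance with unequal
#' means is an error.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @param welch use the Welch-Satterthwaite correction instead of pooling.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs n >= 2")
  if (welch) {
    tt <- stats::t.test(x, y)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value))
  }
  sp <- pooled_sd(x, y)
  if (sp == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = n1 + n2 - 2L, p_value = 1))
    stop("zero pooled variance with unequal means")
  }
  t <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

## between/within sums of squares for k groups
anova_ss <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stop("each group needs n >= 2")
  all <- unlist(groups, use.names = FALSE)
  grand <- mean(all)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(k = k, N = sum(n), ssb = ssb, ssw = ssw, sst = ssb + ssw)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition, `F = MSb / MSw`, upper-tail p on
#' (k - 1, N - k) degrees of freedom. All observations identical gives F = 0,
#' p = 1; zero within-group variance with unequal group means is an error.
#'
#' @param groups a list of k >= 2 numeric samples, each with at least 2
#'   values.
#' @return A list with `statistic`, `df` (length 2), `p_value`.
#' @export
one_way_anova <- function(groups) {
  ss <- anova_ss(groups)
  msb <- ss$ssb / (ss$k - 1)
  msw <- ss$ssw / (ss$N - ss$k)
  if (msw == 0) {
    if (msb == 0)
      return(list(statistic = 0, df = c(ss$k - 1, ss$N - ss$k), p_value = 1))
    stop("zero within-group variance with unequal means")
  }
  f <- msb / msw
  list(statistic = f, df = c(ss$k - 1, ss$N - ss$k),
       p_value = stats::pf(f, ss$k - 1, ss$N - ss$k, lower.tail = FALSE))
}

#' Omega squared effect size for a one-way design
#'
#' `(SSb - (k - 1) MSw) / (SSt + MSw)`. Reported unclamped, so under the
#' null its expectation is about zero and individual values may be negative.
#'
#' @inheritParams one_way_anova
#' @return The omega squared estimate (unitless).
#' @export
omega_squared <- function(groups) {
  ss <- anova_ss(groups)
  msw <- ss$ssw / (ss$N - ss$k)
  if (ss$sst + msw == 0) stop("no variance in the data")
  (ss$ssb - (ss$k - 1) * msw) / (ss$sst + msw)
}

#' Compare groups on every measure of a cohort table
#'
#' For each measure column, rows with a missing value are dropped for that
#' measure only, and a two-group t test with Cohen's d (two groups) or a
#' one-way ANOVA with omega squared (three or more groups) is run. A measure
#' with fewer than 2 usable subjects in any group is flagged rather than
#' fatal.
#'
#' @param table a cohort data frame (e.g. from [extract_all()]).
#' @param measures character vector of measure column names; default every
#'   column starting with `"m"` followed by digits.
#' @param group_col name of the group label column.
#' @param design `"auto"` picks by the number of groups; `"two_group"` and
#'   `"k_group"` force the test family.
#' @param welch use Welch's t test in the two-group design.
#' @return A data frame with one row per measure: test, per-group n
#'   (comma-separated, in group level order), statistic, p value, effect
#'   size, and a `flagged` column for unusable measures.
#' @export
compare_measures <- function(table, measures = NULL, group_col = "group",
                             design = c("auto", "two_group", "k_group"),
                             welch = FALSE) {
  design <- match.arg(design)
  if (!group_col %in% names(table)) stop("no '", group_col, "' column")
  if (is.null(measures))
    measures <- grep("^m[0-9]", names(table), value = TRUE)
  g <- factor(table[[group_col]], levels = unique(table[[group_col]]))
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (design == "auto") design <- if (k == 2L) "two_group" else "k_group"
  if (design == "two_group" && k != 2L) stop("two_group design needs 2 groups")
  out <- lapply(measures, function(mc) {
    v <- table[[mc]]
    ok <- !is.na(v)
    groups <- split(v[ok], g[ok])
    ns <- lengths(groups)
    base <- data.frame(measure = mc,
                       test = if (design == "two_group") "t" else "anova",
                       n = paste(ns, collapse = ","),
                       statistic = NA_real_, p_value = NA_real_,
                       effect_size = NA_real_,
                       effect_type = if (design == "two_group") "cohens_d"
                       else "omega_squared",
                       flagged = FALSE, stringsAsFactors = FALSE)
    if (length(groups) < k || any(ns < 2L)) {
      base$flagged <- TRUE
      return(base)
    }
    if (design == "two_group") {
      tt <- two_sample_t(groups[[1]], groups[[2]], welch = welch)
      base$statistic <- tt$statistic
      base$p_value <- tt$p_value
      base$effect_size <- tryCatch(cohens_d(groups[[1]], groups[[2]]),
                                   error = function(e) NA_real_)
    } else {
      av <- one_way_anova(groups)
      base$statistic <- av$statistic
      base$p_value <- av$p_value
      base$effect_size <- omega_squared(groups)
    }
    base
  })
  do.call(rbind, out)
}
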