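## Covariate-matched subset selection and the matched-resampling evaluation:
## repeatedly draw one group, select a covariate-matched subset of the other,
## and record per-measure effect sizes and test outcomes.

## two-sample t-test p value that tolerates constant data (binary covariates
## coded 0/1 are t-tested like the paper's blanket matching rule)
match_p <- function(x, y) {
  if (pooled_sd(x, y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
  two_sample_t(x, y)$p_value
}

covariate_p_values <- function(reference, subset, covariates) {
  vapply(covariates, function(cv) match_p(reference[[cv]], subset[[cv]]),
         numeric(1))
}

subset_score <- function(reference, pool, rows, covariates) {
  min(covariate_p_values(reference, pool[rows, , drop = FALSE], covariates))
}

#' Select a covariate-matched subset
#'
#' Finds `n` rows of `pool` such that every covariate's two-sample t test
#' against `reference` has p > `p_min` (binary covariates are coded 0/1 and
#' t-tested like the rest). The search is rejection sampling over random
#' subsets, followed by greedy single-swap refinement of the best subset
#' found; it is deterministic under `seed`.
#'
#' @param reference data frame of reference subjects.
#' @param pool data frame of candidate subjects (`nrow(pool) >= n`).
#' @param covariates character vector of covariate column names present in
#'   both tables.
#' @param n subset size.
#' @param p_min matching criterion: all covariate p values must exceed this
#'   (default 0.2).
#' @param max_iter total subset evaluations allowed before declaring failure.
#' @param seed optional integer seed.
#' @return Integer row indices into `pool`, with the covariate p values as
#'   attribute `"p_values"`. Failure to find a matched subset raises an
#'   error of class `roisum_match_failure`.
#' @export
covariate_match <- function(reference, pool, covariates, n, p_min = 0.2,
                            max_iter = 10000, seed = NULL) {
  if (nrow(pool) < n) stop("pool smaller than requested subset")
  miss <- setdiff(covariates, intersect(names(reference), names(pool)))
  if (length(miss)) stop("covariates absent from tables: ",
                         paste(miss, collapse = ", "))
  with_seed(seed, {
    best <- NULL
    best_score <- -Inf
    used <- 0L
    n_random <- ceiling(max_iter / 2)
    while (used < n_random) {
      used <- used + 1L
      rows <- sample.int(nrow(pool), n)
      sc <- subset_score(reference, pool, rows, covariates)
      if (sc > best_score) {
        best <- rows
        best_score <- sc
      }
      if (sc > p_min)
        return(structure(rows, p_values = covariate_p_values(
          reference, pool[rows, , drop = FALSE], covariates)))
    }
    ## greedy single-swap refinement of the best random subset
    repeat {
      improved <- FALSE
      outside <- setdiff(seq_len(nrow(pool)), best)
      for (i in seq_along(best)) {
        for (cand in outside) {
          if (used >= max_iter) break
          used <- used + 1L
          trial <- best
          trial[i] <- cand
          sc <- subset_score(reference, pool, trial, covariates)
          if (sc > best_score) {
            best <- trial
            best_score <- sc
            improved <- TRUE
            break
          }
        }
        if (best_score > p_min || used >= max_iter) break
      }
      if (best_score > p_min)
        return(structure(best, p_values = covariate_p_values(
          reference, pool[best, , drop = FALSE], covariates)))
      if (!improved || used >= max_iter)
        stop(errorCondition(
          sprintf("no matched subset found within %d evaluations (best min p = %.3g)",
                  used, best_score),
          class = c("roisum_match_failure", "error", "condition")))
    }
  })
}

#' Matched-resampling evaluation of measure sensitivity
#'
#' Replicates the random sampling-and-matching procedure: per replicate,
#' `n_draw` subjects are drawn without replacement from the first group, a
#' covariate-matched subset of `n_draw` is selected from the second group,
#' and a pooled-variance t test plus Cohen's d is computed per measure.
#' Replicates whose matching fails are redrawn (counted in the output);
#' more than 50% failed attempts aborts with a diagnostic.
#'
#' @param table cohort data frame with a group column, covariates and
#'   measure columns.
#' @param measures character vector of measure columns; default every column
#'   starting with `"m"` followed by digits.
#' @param covariates covariate columns to match on; default
#'   `c("age", "sex", "wrat", "accuracy")`.
#' @param group_col group label column; the first level is sampled, the
#'   second matched.
#' @param n_draw subjects drawn per group per replicate (default 50).
#' @param n_rep number of replicates (default 1000).
#' @param p_min matching criterion, see [covariate_match()].
#' @param match_iter matching evaluations allowed per replicate.
#' @param seed optional integer seed for the whole run.
#' @return A data frame with one row per measure: mean Cohen's d across
#'   replicates, the fraction of replicates with p < 0.05 and with p < 0.01,
#'   and the count of usable replicates; the number of redrawn (match-failed)
#'   attempts is attached as attribute `"n_match_failures"`.
#' @export
replicate_comparison <- function(table, measures = NULL,
                                 covariates = c("age", "sex", "wrat", "accuracy"),
                                 group_col = "group", n_draw = 50,
                                 n_rep = 1000, p_min = 0.2,
                                 match_iter = 2000, seed = NULL) {
  if (is.null(measures))
    measures <- grep("^m[0-9]", names(table), value = TRUE)
  g <- factor(table[[group_col]], levels = unique(table[[group_col]]))
  if (nlevels(g) != 2L) stop("matched resampling needs exactly 2 groups")
  rows1 <- which(g == levels(g)[1])
  rows2 <- which(g == levels(g)[2])
  if (length(rows1) < n_draw || length(rows2) < n_draw)
    stop("both groups must be larger than n_draw")
  with_seed(seed, {
    d <- matrix(NA_real_, n_rep, length(measures),
                dimnames = list(NULL, measures))
    p <- matrix(NA_real_, n_rep, length(measures),
                dimnames = list(NULL, measures))
    failures <- 0L
    for (r in seq_len(n_rep)) {
      repeat {
        draw1 <- table[sample(rows1, n_draw), , drop = FALSE]
        matched <- tryCatch(
          covariate_match(draw1, table[rows2, , drop = FALSE], covariates,
                          n_draw, p_min = p_min, max_iter = match_iter),
          roisum_match_failure = function(e) NULL)
        if (!is.null(matched)) break
        failures <- failures + 1L
        if (failures > (n_rep + failures) / 2)
          stop("more than half of the matching attempts failed; ",
               "the groups' covariates are too far apart for p_min = ", p_min)
      }
      draw2 <- table[rows2[matched], , drop = FALSE]
      for (mc in measures) {
        x <- draw1[[mc]]; y <- draw2[[mc]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2L || length(y) < 2L) next
        tt <- tryCatch(two_sample_t(x, y), error = function(e) NULL)
        if (is.null(tt)) next
        p[r, mc] <- tt$p_value
        d[r, mc] <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
      }
    }
    out <- data.frame(
      measure = measures,
      mean_d = colMeans(d, na.rm = TRUE),
      frac_p_lt_05 = colMeans(p < 0.05, na.rm = TRUE),
      frac_p_lt_01 = colMeans(p < 0.01, na.rm = TRUE),
      n_used = colSums(!is.na(p)),
      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "n_match_failures") <- failures
    out
  })
}
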