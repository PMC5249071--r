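#' Risk category scheme
#'
#' Ordered cut-points defining half-open risk categories
#' `[0, e1), [e1, e2), ..., [ek, 1)`. The default edges
#' `(0.01, 0.015, 0.02, 0.025, 0.03, 0.04)` give the seven conventional
#' 5-year-risk reporting categories `<1.0%`, `1.0-1.4%`, `1.5-1.9%`,
#' `2.0-2.4%`, `2.5-2.9%`, `3.0-3.9%`, `>4.0%`.
#'
#' @param edges strictly increasing cut-points in (0, 1).
#' @return object of class `category_scheme`: list with `edges` and
#'   human-readable `labels`.
#' @export
category_scheme <- function(edges = c(0.01, 0.015, 0.02, 0.025, 0.03, 0.04)) {
  if (length(edges) < 1 || any(diff(edges) <= 0) ||
      any(edges <= 0 | edges >= 1)) {
    stop("`edges` must be strictly increasing and inside (0, 1)",
         call. = FALSE)
  }
  k <- length(edges)
  pct <- function(x) formatC(100 * x, format = "fg")
  labels <- c(
    paste0("<", pct(edges[1]), "%"),
    if (k > 1) {
      paste0(pct(edges[-k]), "-", pct(edges[-1]), "%")
    },
    paste0(">=", pct(edges[k]), "%")
  )
  structure(list(edges = edges, labels = labels), class = "category_scheme")
}

#' Assign risks to categories
#'
#' Index (1-based) of the half-open category `[lower, upper)` containing
#' each risk; every risk in (0, 1) maps to exactly one category.
#'
#' @param risk numeric vector of risks in (0, 1).
#' @param scheme a [category_scheme()].
#' @return integer vector of category indices in
#'   `1 .. length(scheme$edges) + 1`.
#' @examples
#' sch <- category_scheme()
#' categorize(c(0.0299, 0.030, 0.05), sch) # 5, 6, 7
#' @export
categorize <- function(risk, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (any(risk <= 0 | risk >= 1)) {
    stop("`risk` must lie strictly inside (0, 1)", call. = FALSE)
  }
  findInterval(risk, c(0, scheme$edges), rightmost.closed = FALSE) |>
    as.integer()
}

#' Pre/post reclassification matrix
#'
#' Joint empirical distribution of (pre-test category, post-test category)
#' over a cohort: cell (i, j) is the proportion of the whole population
#' with prior in category i and posterior in category j. Row marginals are
#' the pre-test distribution, column marginals the post-test distribution;
#' all cells sum to 1.
#'
#' @param cohort a `prs_cohort` from [sample_cohort()].
#' @param scheme a [category_scheme()].
#' @return object of class `reclass_matrix`: a k x k proportion matrix with
#'   category labels, with attributes `pre_marginal` and `post_marginal`.
#' @export
reclass_matrix <- function(cohort, scheme = category_scheme()) {
  stopifnot(inherits(cohort, "prs_cohort"))
  pre <- categorize(cohort$subjects$prior, scheme)
  post <- categorize(cohort$subjects$posterior, scheme)
  k <- length(scheme$edges) + 1L
  tab <- table(factor(pre, levels = seq_len(k), labels = scheme$labels),
               factor(post, levels = seq_len(k), labels = scheme$labels))
  m <- unclass(tab) / length(pre)
  structure(m,
            pre_marginal = rowSums(m),
            post_marginal = colSums(m),
            class = c("reclass_matrix", "matrix"))
}

#' @export
print.reclass_matrix <- function(x, digits = 3, ...) {
  cat("reclassification matrix (proportion of population; rows = pre, columns = post)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Apply a tiered SNP-testing strategy
#'
#' Only women whose prior risk falls in the tested band
#' `[test_lower, test_upper)` receive the genotype update (their posterior
#' replaces the prior); everyone else keeps the prior. Crossings of the
#' treatment threshold are tallied in both directions, and the benefit
#' fraction compares the strategy's total crossings against testing
#' everyone in the same cohort — a paired comparison on identical draws, so
#' strategy rankings carry no Monte-Carlo noise between arms.
#'
#' @param cohort a `prs_cohort`.
#' @param test_lower lower edge of the tested prior-risk band (0 tests
#'   everyone from the bottom).
#' @param test_upper optional upper edge (default `NULL` = unbounded).
#' @param treat_threshold treatment threshold on 5-year risk; default 0.03,
#'   applied as `>=` (the guideline wording is "at or above 3%").
#' @return object of class `strategy_result`: list with `test_lower`,
#'   `test_upper`, `pct_tested`, `pct_up`, `pct_down` (all proportions of
#'   the whole population), `benefit_fraction`, `treat_threshold`.
#' @export
apply_strategy <- function(cohort, test_lower, test_upper = NULL,
                           treat_threshold = 0.03) {
  stopifnot(inherits(cohort, "prs_cohort"))
  check_prob(treat_threshold, "treat_threshold")
  if (test_lower < 0 || test_lower >= 1) {
    stop("`test_lower` must lie in [0, 1)", call. = FALSE)
  }
  s <- cohort$subjects
  tested <- s$prior >= test_lower
  if (!is.null(test_upper)) {
    if (test_upper <= test_lower) {
      stop("`test_upper` must exceed `test_lower`", call. = FALSE)
    }
    tested <- tested & s$prior < test_upper
  }
  effective <- ifelse(tested, s$posterior, s$prior)
  pre_high <- s$prior >= treat_threshold
  post_high <- effective >= treat_threshold
  pct_up <- mean(!pre_high & post_high)
  pct_down <- mean(pre_high & !post_high)
  # paired test-everyone reference on the same cohort
  all_high <- s$posterior >= treat_threshold
  total <- mean(!pre_high & all_high) + mean(pre_high & !all_high)
  structure(
    list(test_lower = test_lower, test_upper = test_upper,
         treat_threshold = treat_threshold,
         pct_tested = mean(tested),
         pct_up = pct_up, pct_down = pct_down,
         benefit_fraction = if (total > 0) (pct_up + pct_down) / total else 0),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  band <- if (is.null(x$test_upper)) {
    sprintf(">=%.1f%%", 100 * x$test_lower)
  } else {
    sprintf("%.1f-%.1f%%", 100 * x$test_lower, 100 * x$test_upper)
  }
  cat(sprintf(
    "strategy: test priors %s | tested %.1f%% | up %.2f%% down %.2f%% | benefit %.1f%%\n",
    band, 100 * x$pct_tested, 100 * x$pct_up, 100 * x$pct_down,
    100 * x$benefit_fraction))
  invisible(x)
}

#' Benefit curve over a set of testing strategies
#'
#' Evaluates each strategy on the same cohort and returns one row per
#' strategy ordered by the fraction of the population tested. For nested
#' bands the benefit fraction is non-decreasing in the tested fraction.
#'
#' @param cohort a `prs_cohort`.
#' @param strategies list of strategy specs; each element is a list/vector
#'   with `test_lower` and optionally `test_upper`.
#' @param treat_threshold treatment threshold (default 0.03).
#' @return data.frame with columns `test_lower`, `test_upper`,
#'   `pct_tested`, `pct_up`, `pct_down`, `benefit_fraction`, ordered by
#'   `pct_tested`.
#' @export
benefit_curve <- function(cohort, strategies, treat_threshold = 0.03) {
  if (length(strategies) < 1) stop("need at least one strategy", call. = FALSE)
  rows <- lapply(strategies, function(spec) {
    spec <- as.list(spec)
    r <- apply_strategy(cohort, spec$test_lower,
                        spec$test_upper, treat_threshold)
    data.frame(test_lower = r$test_lower,
               test_upper = if (is.null(r$test_upper)) NA_real_ else r$test_upper,
               pct_tested = r$pct_tested, pct_up = r$pct_up,
               pct_down = r$pct_down, benefit_fraction = r$benefit_fraction)
  })
  out <- do.call(rbind, rows)
  out[order(out$pct_tested), , drop = FALSE]
}

#' Proportion above the treatment threshold before and after testing
#'
#' Overall (and optionally per stratum of a logical cohort column such as
#' `fh_positive`) proportion of women at or above the treatment threshold
#' by prior risk and by posterior risk.
#'
#' @param cohort a `prs_cohort`.
#' @param treat_threshold treatment threshold (default 0.03).
#' @param by optional name of a logical column of `cohort$subjects` to
#'   stratify on (e.g. `"fh_positive"`).
#' @return data.frame with columns `stratum`, `n`, `pct_pre`, `pct_post`.
#' @export
summarize_above_threshold <- function(cohort, treat_threshold = 0.03,
                                      by = NULL) {
  stopifnot(inherits(cohort, "prs_cohort"))
  s <- cohort$subjects
  one <- function(rows, label) {
    data.frame(stratum = label, n = length(rows),
               pct_pre = mean(s$prior[rows] >= treat_threshold),
               pct_post = mean(s$posterior[rows] >= treat_threshold))
  }
  out <- one(seq_len(nrow(s)), "all")
  if (!is.null(by)) {
    if (!by %in% names(s) || !is.logical(s[[by]])) {
      stop("`by` must name a logical column of the cohort subjects",
           call. = FALSE)
    }
    out <- rbind(out,
                 one(which(s[[by]]), paste0(by, "=TRUE")),
                 one(which(!s[[by]]), paste0(by, "=FALSE")))
  }
  out
}
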