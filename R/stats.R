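# Normality-gated statistics harness: Shapiro-Wilk gates the choice between
# parametric (Welch/paired/one-sample t, one-way ANOVA) and rank-based tests
# (Wilcoxon signed-rank / rank-sum, Kruskal-Wallis), all two-sided, with
# multiplicity correction selected by the number of comparisons.

#' Choose a test by normality gating
#'
#' Shapiro-Wilk is run on each sample at `alpha`; parametric tests are used
#' only when every sample is deemed normal, otherwise the rank-based
#' counterpart: one sample (change scores vs 0) gives a one-sample t or
#' Wilcoxon signed-rank; two paired samples a paired t or signed-rank; two
#' independent samples a Welch t or rank-sum; three or more groups one-way
#' ANOVA or Kruskal-Wallis.
#'
#' @param samples list of numeric vectors (each n >= 3).
#' @param paired logical (two-sample designs only).
#' @param alpha normality-test level (default 0.05).
#' @return test id: one of `"t.one"`, `"wilcox.one"`, `"t.paired"`,
#'   `"wilcox.paired"`, `"t.welch"`, `"wilcox.ranksum"`, `"anova"`,
#'   `"kruskal"`.
#' @export
chooseTest <- function(samples, paired = FALSE, alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  if (any(vapply(samples, length, 0L) < 3L))
    stop("each sample needs at least 3 observations")
  normal <- all(vapply(samples, function(x) {
    if (length(unique(x)) == 1L) return(FALSE)
    shapiro.test(x)$p.value > alpha
  }, logical(1)))
  k <- length(samples)
  if (k == 1L) return(if (normal) "t.one" else "wilcox.one")
  if (k == 2L) {
    if (paired) return(if (normal) "t.paired" else "wilcox.paired")
    return(if (normal) "t.welch" else "wilcox.ranksum")
  }
  if (normal) "anova" else "kruskal"
}

#' Run a two-sided test
#'
#' Executes the given (or auto-chosen) test. Signed-rank and rank-sum tests
#' use the exact small-sample distribution when n <= 25 and there are no
#' ties (nor zero differences), and the normal approximation with
#' continuity correction otherwise.
#'
#' @param samples list of numeric vectors.
#' @param test a test id from [chooseTest()], or NULL to auto-select.
#' @param paired logical, for two-sample designs.
#' @param mu null value for one-sample designs (default 0).
#' @param alpha normality-gate level used when auto-selecting.
#' @return one-row data.frame: `test_name`, `statistic`, `p_raw`, `n`
#'   (comma-separated group sizes), `paired`.
#' @export
runStatTest <- function(samples, test = NULL, paired = FALSE, mu = 0,
                        alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  if (is.null(test)) test <- chooseTest(samples, paired = paired, alpha = alpha)
  exactRule <- function(x) length(x) <= 25L && !anyDuplicated(abs(x)) &&
    all(x != 0)
  res <- switch(test,
    t.one = t.test(samples[[1]], mu = mu),
    t.paired = t.test(samples[[1]], samples[[2]], paired = TRUE),
    t.welch = t.test(samples[[1]], samples[[2]], var.equal = FALSE),
    wilcox.one = {
      d <- samples[[1]] - mu
      if (all(d == 0)) stop("all differences are zero: signed-rank undefined")
      wilcox.test(samples[[1]], mu = mu, exact = exactRule(d), correct = TRUE)
    },
    wilcox.paired = {
      d <- samples[[1]] - samples[[2]]
      if (all(d == 0)) stop("all differences are zero: signed-rank undefined")
      wilcox.test(samples[[1]], samples[[2]], paired = TRUE,
                  exact = exactRule(d), correct = TRUE)
    },
    wilcox.ranksum = {
      x <- samples[[1]]; y <- samples[[2]]
      noTies <- !anyDuplicated(c(x, y))
      wilcox.test(x, y, exact = noTies && length(x) + length(y) <= 50L,
                  correct = TRUE)
    },
    anova = {
      g <- factor(rep(seq_along(samples), lengths(samples)))
      fit <- aov(unlist(samples) ~ g)
      s <- summary(fit)[[1]]
      list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1],
            method = "one-way ANOVA")
    },
    kruskal = kruskal.test(samples),
    stop("unknown test id: ", test)
  )
  data.frame(test_name = test,
             statistic = unname(res$statistic[1]),
             p_raw = res$p.value,
             n = paste(lengths(samples), collapse = ","),
             paired = paired %in% TRUE || test %in% c("t.paired", "wilcox.paired"))
}

#' Count-dependent multiplicity correction
#'
#' One p-value is returned unchanged; exactly two are Bonferroni-corrected;
#' more than two are Benjamini-Hochberg-corrected (step-up, with
#' monotonicity enforcement), capped at 1.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, with the method name in
#'   `attr(, "correction")`.
#' @export
adjustPvalues <- function(p) {
  if (length(p) == 0L) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  method <- if (length(p) == 1L) "none"
    else if (length(p) == 2L) "bonferroni" else "benjamini_hochberg"
  adj <- switch(method,
    none = p,
    bonferroni = pmin(1, 2 * p),
    benjamini_hochberg = p.adjust(p, method = "BH"))
  attr(adj, "correction") <- method
  adj
}

#' Adjust a results table for multiple testing
#'
#' Adds `p_adjusted` and `correction` columns to a table of
#' [runStatTest()] rows, with the correction chosen from the row count.
#'
#' @param results data.frame with a `p_raw` column.
#' @return the table with `p_adjusted` and `correction` columns.
#' @export
adjustResults <- function(results) {
  stopifnot("p_raw" %in% names(results))
  adj <- adjustPvalues(results$p_raw)
  results$p_adjusted <- as.numeric(adj)
  results$correction <- attr(adj, "correction")
  results
}
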