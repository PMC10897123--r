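# The pipeline's statistical battery: one-way ANOVA across sequences with
# uncorrected post hoc pairwise t-tests (a Bonferroni option exists but
# defaults off), plus one- and two-sample t-tests, all two-tailed at
# alpha = 0.05 by default. Two-sample tests default to the pooled
# (equal-variance) form, the classical post hoc companion of one-way ANOVA;
# Welch and paired modes are available for sensitivity analyses.

test_row <- function(test, statistic, df, p_value, groups, alpha) {
  data.frame(test = test, statistic = statistic, df = df,
             p_value = p_value, groups = groups, alpha = alpha,
             significant = p_value < alpha, stringsAsFactors = FALSE)
}

#' One-way ANOVA across groups
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame: F statistic, "df1,df2" degrees of freedom
#'   with df1 = k-1 and df2 = N-k, p-value, group names.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs >= 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (all(vapply(groups, stats::sd, 1) == 0) &&
      stats::sd(vapply(groups, mean, 1)) > 0)
    stop("zero within-group variance with differing means: F degenerate")
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  test_row("one_way_anova", unname(ft$statistic),
           paste(unname(ft$parameter), collapse = ","),
           unname(ft$p.value), paste(names(groups), collapse = "|"), alpha)
}

#' One-sample, two-sample or paired t-test
#'
#' Two-tailed. Two-sample tests are pooled-variance unless `var_equal =
#' FALSE` (Welch). Zero-variance inputs (e.g. a paired test on identical
#' samples) are an explicit error rather than a silent p-value.
#'
#' @param sample_a Numeric vector.
#' @param sample_b Second sample for two-sample/paired modes (NULL
#'   otherwise).
#' @param mode "one-sample", "two-sample" or "paired".
#' @param mu0 Null-hypothesis mean (one-sample) or mean difference.
#' @param var_equal Pool variances in two-sample mode (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @param label Group label string for the output row.
#' @return One-row data.frame as in [one_way_anova()].
#' @export
t_test <- function(sample_a, sample_b = NULL,
                   mode = c("one-sample", "two-sample", "paired"),
                   mu0 = 0, var_equal = TRUE, alpha = 0.05, label = "") {
  mode <- match.arg(mode)
  if (mode == "one-sample") {
    stopifnot(is.null(sample_b), length(sample_a) >= 2L)
    if (stats::sd(sample_a) == 0) stop("zero variance in sample")
    tt <- stats::t.test(sample_a, mu = mu0)
  } else if (mode == "two-sample") {
    stopifnot(!is.null(sample_b), length(sample_a) >= 2L,
              length(sample_b) >= 2L)
    if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0)
      stop("zero variance in both samples")
    tt <- stats::t.test(sample_a, sample_b, mu = mu0,
                        var.equal = var_equal)
  } else {
    stopifnot(!is.null(sample_b), length(sample_a) == length(sample_b),
              length(sample_a) >= 2L)
    d <- sample_a - sample_b
    if (stats::sd(d) == 0)
      stop("zero variance in paired differences")
    tt <- stats::t.test(d, mu = mu0)
  }
  test_row(paste0("t_", mode), unname(tt$statistic),
           as.character(unname(tt$parameter)), unname(tt$p.value),
           label, alpha)
}

#' Post hoc pairwise t-tests over a set of groups
#'
#' Every unordered pair of groups is compared with a two-sample t-test
#' (pooled by default), uncorrected for multiplicity unless `correction =
#' "bonferroni"`.
#'
#' @inheritParams one_way_anova
#' @param var_equal Pool variances (default TRUE).
#' @param paired Pair observations across groups (requires equal lengths).
#' @param correction "none" (default) or "bonferroni".
#' @return data.frame with one row per pair.
#' @export
posthoc_pairwise_t <- function(groups, alpha = 0.05, var_equal = TRUE,
                               paired = FALSE,
                               correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(is.list(groups), length(groups) >= 2L)
  nm <- names(groups)
  pairs <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    t_test(groups[[i1]], groups[[i2]],
           mode = if (paired) "paired" else "two-sample",
           var_equal = var_equal, alpha = alpha,
           label = paste(nm[i1], nm[i2], sep = "|"))
  })
  out <- do.call(rbind, rows)
  if (correction == "bonferroni") {
    out$p_value <- pmin(1, out$p_value * nrow(out))
    out$significant <- out$p_value < out$alpha
    out$test <- paste0(out$test, "_bonferroni")
  }
  out
}
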