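#' One-way ANOVA across label groups
#'
#' Classic equal-variance one-way ANOVA (the textbook between/within
#' sums-of-squares decomposition), used to test whether nRMSE differs across
#' the Green/Yellow/Red groups. A Welch variant is available by flag.
#'
#' @param groups named list of at least 2 numeric vectors, each of size >= 2.
#' @param var_equal classic pooled-variance ANOVA when `TRUE` (default);
#'   Welch's correction when `FALSE`.
#' @return list with `f_statistic`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups, var_equal = TRUE) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ g, var.equal = var_equal)
  f <- unname(ht$statistic)
  p <- unname(ht$p.value)
  # zero between-group variance: F = 0, p = 1 (oneway.test returns NaN-free
  # values here, but guard the exact-zero numerator explicitly)
  if (!is.finite(f)) {
    stop("ANOVA undefined: zero within-group variance", call. = FALSE)
  }
  list(f_statistic = f, p = p,
       df_between = unname(ht$parameter[1L]),
       df_within = unname(ht$parameter[2L]))
}

#' Pairwise t-tests with Bonferroni-corrected significance
#'
#' Runs the one-way ANOVA and, post hoc, a two-sample t-test for every pair
#' of groups. Significance is judged against `alpha / n_pairs`, rounded to
#' `digits` decimals for reporting (3 labels at alpha 0.05 gives the
#' conventional corrected threshold of 0.017).
#'
#' @inheritParams anova_oneway
#' @param alpha familywise significance level (default 0.05).
#' @param digits decimals used when rounding the corrected alpha for
#'   reporting and comparison (default 3).
#' @return object of class `group_comparison`: `f_statistic`, `anova_p`,
#'   `pairwise` data frame (group1, group2, statistic, p, significant),
#'   `corrected_alpha`, `alpha`, `n_pairs`.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05, var_equal = TRUE,
                                digits = 3L) {
  an <- anova_oneway(groups, var_equal = var_equal)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  n_pairs <- ncol(pairs)
  corrected <- round(alpha / n_pairs, digits)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    tt <- stats::t.test(groups[[i1]], groups[[i2]], var.equal = var_equal)
    data.frame(group1 = nm[i1], group2 = nm[i2],
               statistic = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < corrected)
  }))
  structure(list(f_statistic = an$f_statistic, anova_p = an$p,
                 pairwise = pw, corrected_alpha = corrected,
                 alpha = alpha, n_pairs = n_pairs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> ANOVA F = %.3f, p = %.3g | corrected alpha = %.3f\n",
              x$f_statistic, x$anova_p, x$corrected_alpha))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: p = %.3g%s\n", pw$group1[i], pw$group2[i],
                pw$p[i], ifelse(pw$significant[i], " *", "")))
  }
  invisible(x)
}
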