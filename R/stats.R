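#' Quartile summary of a variable
#'
#' First, second and third quartiles (linear-interpolation convention,
#' type 7), the summary used for all continuous descriptives.
#'
#' @param x numeric values (>= 1).
#' @return Named vector `c(q1, median, q3)`.
#' @examples
#' describe_quartiles(c(0.18, 0.17, 0.19))
#' @export
describe_quartiles <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("need at least one value")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

comparison_result <- function(variable, test, p, extra = list()) {
  structure(c(list(variable = variable, test = test,
                   p_value = p, significant = is.finite(p) && p < 0.05),
              extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s, p = %.4g%s\n", x$variable, x$test, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided rank-sum test. The exact null distribution is used when both
#' groups have at most 10 observations and there are no cross-group ties;
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param variable label for reporting.
#' @return A `comparison_result` with per-group medians and quartiles.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
mann_whitney <- function(a, b, variable = "value") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stopf("need >= 2 values per group")
  use_exact <- length(a) <= 10L && length(b) <= 10L &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE, conf.int = FALSE))
  comparison_result(variable, "Mann-Whitney U", ht$p.value,
                    list(U = unname(ht$statistic),
                         exact = use_exact,
                         a = describe_quartiles(a),
                         b = describe_quartiles(b)))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value by probability summation: with margins fixed, the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one are summed.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts.
#' @param variable label for reporting.
#' @return A `comparison_result`.
#' @examples
#' fisher_exact(matrix(c(7, 4, 2, 2), nrow = 2))$p_value  # 1
#' @export
fisher_exact <- function(tab, variable = "counts") {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    stopf("`tab` must be a 2 x 2 matrix of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("fisher_exact: a margin is zero; p = 1 by convention")
    return(comparison_result(variable, "Fisher exact", 1,
                             list(table = tab)))
  }
  ht <- fisher.test(tab)
  comparison_result(variable, "Fisher exact", ht$p.value,
                    list(table = tab, odds_ratio = unname(ht$estimate)))
}

#' Shapiro-Wilk normality check
#'
#' Used to route continuous variables to the nonparametric comparison; the
#' comparisons themselves are always rank-based.
#'
#' @param x numeric sample, 3 <= n <= 5000, not constant.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L) stopf("need 3 <= n <= 5000")
  if (diff(range(x)) == 0) stopf("values are constant; W undefined")
  ht <- shapiro.test(x)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Compare tissue composition between two treatment arms
#'
#' For each VOI type (TX, CTRL) and tissue class, reports per-arm median and
#' quartiles of the composition fraction, the between-arm difference of
#' medians in percentage points, and the two-sided Mann-Whitney p-value.
#' Comparisons are reported unadjusted at alpha = 0.05 (per-comparison
#' reporting); `adjust = "holm"` applies a Holm correction across the table.
#'
#' @param table data frame with columns `patient`, `arm` (exactly two
#'   levels), `voi` (`"TX"`/`"CTRL"`), `frac_fibro`, `frac_hyaline`,
#'   `frac_remodel`.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `cohort_comparison` data frame (one row per VOI type and tissue
#'   class) with attributes recording the arms.
#' @export
compare_cohort <- function(table, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  need <- c("patient", "arm", "voi", "frac_fibro", "frac_hyaline",
            "frac_remodel")
  if (!all(need %in% names(table)))
    stopf("`table` must have columns: %s", paste(need, collapse = ", "))
  arms <- sort(unique(as.character(table$arm)))
  if (length(arms) != 2L)
    stopf("need exactly two arms; found: %s", paste(arms, collapse = ", "))
  classes <- c(fibrocartilage = "frac_fibro", `hyaline-like` = "frac_hyaline",
               remodeling = "frac_remodel")
  rows <- list()
  for (voi in intersect(c("TX", "CTRL"), unique(table$voi))) {
    sub <- table[table$voi == voi, ]
    for (k in seq_along(classes)) {
      x1 <- sub[sub$arm == arms[1], classes[k]]
      x2 <- sub[sub$arm == arms[2], classes[k]]
      d1 <- describe_quartiles(x1); d2 <- describe_quartiles(x2)
      p <- if (length(x1) >= 2 && length(x2) >= 2)
        mann_whitney(x1, x2)$p_value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        voi = voi, tissue = names(classes)[k],
        arm1 = arms[1], median1 = d1[["median"]], q1_1 = d1[["q1"]],
        q3_1 = d1[["q3"]],
        arm2 = arms[2], median2 = d2[["median"]], q1_2 = d2[["q1"]],
        q3_2 = d2[["q3"]],
        diff_pp = 100 * (d2[["median"]] - d1[["median"]]),
        p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p_value, "holm")
  out$significant <- (if (adjust == "holm") out$p_adj else out$p_value) < 0.05
  attr(out, "arms") <- arms
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' @export
print.cohort_comparison <- function(x, ...) {
  arms <- attr(x, "arms")
  cat(sprintf("Tissue composition by arm (%s vs %s), median (q1-q3):\n",
              arms[1], arms[2]))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("  %-5s %-14s %.2f (%.2f-%.2f) vs %.2f (%.2f-%.2f)  diff %+.0f pp  p = %s%s\n",
                r$voi, r$tissue, r$median1, r$q1_1, r$q3_1,
                r$median2, r$q1_2, r$q3_2, r$diff_pp,
                formatC(r$p_value, digits = 3, format = "g"),
                if (isTRUE(r$significant)) " *" else ""))
  }
  invisible(x)
}
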