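#' Per-group mean and SEM of a statistic
#'
#' Summarises one statistic (density, CC, g1, ...) across the fields or
#' animals of a group as mean +/- SEM, the experimental unit being the field,
#' not the cell.
#'
#' @param values Numeric vector of per-field values (length >= 1).
#' @param label Group label.
#' @return An object of class `group_summary`: `group_label`, `n_fields`,
#'   `mean`, `sem` (sample SD / sqrt(n); 0 with a warning when n = 1) and
#'   `per_field_values`.
#' @examples
#' summarize_group(c(2, 4, 6), "control")
#' @export
summarize_group <- function(values, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("cannot summarise an empty group")
  if (anyNA(values)) stop("values must not contain NA")
  if (length(values) == 1L) {
    warning("group of size 1: SEM set to 0")
    sem <- 0
  } else {
    sem <- stats::sd(values) / sqrt(length(values))
  }
  structure(
    list(group_label = as.character(label), n_fields = length(values),
         mean = mean(values), sem = sem, per_field_values = values),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (mean +/- SEM, n = %d)\n",
              if (nzchar(x$group_label)) x$group_label else "group",
              x$mean, x$sem, x$n_fields))
  invisible(x)
}

#' Two-sample t-test between group summaries
#'
#' Compares two groups of per-field values with a two-sided two-sample
#' t-test. The default is the classical Student's test (pooled variance); a
#' Welch variant is exposed for sensitivity analysis when the group SEMs are
#' very unequal.
#'
#' @param a,b [summarize_group()] objects (or plain numeric vectors), each
#'   with at least 2 values.
#' @param alpha Significance level (default 0.05).
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return An object of class `comparison_result`: `t_statistic`, `p_value`,
#'   `df`, `significant` (`p_value < alpha`), plus the inputs' summaries.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!inherits(a, "group_summary")) a <- summarize_group(a, "a")
  if (!inherits(b, "group_summary")) b <- summarize_group(b, "b")
  if (a$n_fields < 2L || b$n_fields < 2L)
    stop("both groups need at least 2 values for a t-test")
  ht <- stats::t.test(a$per_field_values, b$per_field_values,
                      var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  structure(
    list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), alpha = alpha,
         significant = ht$p.value < alpha, variant = variant,
         group_a = a, group_b = b),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  print(x$group_a)
  print(x$group_b)
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              if (x$variant == "pooled") "Student (pooled)" else "Welch",
              x$t_statistic, x$df, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
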