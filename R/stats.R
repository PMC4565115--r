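#' Mean and standard error of the mean
#'
#' Group results are conventionally reported as mean +/- s.e.m., with
#' s.e.m. = sample SD (n - 1 denominator) / sqrt(n). For n = 1 the s.e.m. is
#' undefined and flagged `NA`.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("empty input")
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Significance star code
#'
#' @param p P value.
#' @return `"ns"`, `"*"` (p < 0.05), `"**"` (p < 0.01) or `"***"`
#'   (p < 0.001).
#' @export
star_code <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Two-sample Student's t-test between genotype groups
#'
#' Classical pooled-variance, two-tailed, unpaired t-test (df =
#' n_a + n_b - 2); the unequal-variance Welch variant is available behind
#' `welch = TRUE`. Significance is annotated with the usual star code
#' (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2 non-missing
#'   values.
#' @param welch Use the Welch (unequal-variance) test instead of the pooled
#'   test? Default `FALSE`.
#' @return An object of class `comparison_result`: list with `t`, `df`, `p`,
#'   `stars`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
students_t_test <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # degenerate: both groups constant and equal; t.test errors here
    res <- list(statistic = c(t = 0),
                parameter = c(df = length(group_a) + length(group_b) - 2),
                p.value = 1)
  } else {
    res <- stats::t.test(group_a, group_b, var.equal = !welch,
                         alternative = "two.sided")
  }
  structure(list(t = unname(res$statistic),
                 df = unname(res$parameter),
                 p = res$p.value,
                 stars = star_code(res$p.value),
                 n_a = length(group_a), n_b = length(group_b),
                 mean_a = mean(group_a), mean_b = mean(group_b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.1f, p = %.4g %s\n", x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Survival fraction
#'
#' @param n_survived,n_total Counts, `0 <= n_survived <= n_total`,
#'   `n_total > 0`.
#' @return List with `pct` (full precision percent) and `pct_int` (rounded
#'   integer percent, the conventional report).
#' @export
survival_fraction <- function(n_survived, n_total) {
  stopifnot(n_total > 0, n_survived >= 0, n_survived <= n_total)
  pct <- 100 * n_survived / n_total
  list(pct = pct, pct_int = round(pct))
}

#' Compare two genotypes stage by stage
#'
#' Runs [students_t_test()] for every parameter at every stage shared by the
#' two parameter tables. No multiple-testing correction is applied by
#' default (raw per-comparison p-values are reported, as is conventional for
#' this kind of stage-wise phenotyping figure); Holm adjustment is available
#' behind `adjust = "holm"`.
#'
#' @param table_a,table_b Data.frames in [param_table_columns()] layout
#'   (group A and group B).
#' @param parameters Parameter columns to compare.
#' @param welch Use Welch's test instead of pooled-variance?
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data.frame with one row per (parameter, stage): `parameter`,
#'   `stage_label`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `stars`. Comparisons with fewer than 2 values in either group carry
#'   `NA` statistics.
#' @export
compare_groups <- function(table_a, table_b,
                           parameters = c("HR_bpm", "CAP_pct", "EDA_um2",
                                          "ESA_um2"),
                           welch = FALSE, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stages <- intersect(unique(table_a$stage_label),
                      unique(table_b$stage_label))
  if (length(stages) == 0) stop("no shared stage labels")
  info <- stage_info()
  stages <- info$stage_label[info$stage_label %in% stages]
  rows <- list()
  for (par in parameters) {
    for (st in stages) {
      a <- table_a[[par]][table_a$stage_label == st]
      b <- table_b[[par]][table_b$stage_label == st]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) >= 2 && length(b) >= 2) {
        r <- students_t_test(a, b, welch = welch)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, stage_label = st,
          n_a = r$n_a, n_b = r$n_b, mean_a = r$mean_a, mean_b = r$mean_b,
          t = r$t, df = r$df, p = r$p, stars = r$stars,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, stage_label = st,
          n_a = length(a), n_b = length(b),
          mean_a = if (length(a)) mean(a) else NA_real_,
          mean_b = if (length(b)) mean(b) else NA_real_,
          t = NA_real_, df = NA_real_, p = NA_real_, stars = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    ok <- !is.na(out$p)
    out$p_adj <- NA_real_
    out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "holm")
  }
  out
}
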