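# Unpaired two-tailed Student's t-test (pooled variance) and the
# significance-star annotation used in the figures.

#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance Student's t-test (the classical equal-variance form, not
#' Welch): `t = (mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))` with
#' `s_p^2` the pooled variance on `n_a + n_b - 2` degrees of freedom, and a
#' two-tailed p-value from the t distribution. Degenerate inputs with zero
#' pooled variance give `t = 0, p = 1` when the means are equal and an
#' error otherwise. Set `var_equal = FALSE` for the Welch variant
#' (delegated to [stats::t.test()]).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pooled-variance Student test if `TRUE` (default);
#'   Welch if `FALSE`.
#' @return Object of class `thickness_ttest`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `stars`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
#' @examples
#' students_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
students_t_test <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need n >= 2")
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  n_a <- length(a); n_b <- length(b)
  if (!var_equal) {
    w <- stats::t.test(a, b, var.equal = FALSE)
    return(new_ttest(unname(w$statistic), unname(w$parameter),
                     w$p.value, mean(a), mean(b), n_a, n_b))
  }
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1) * stats::var(a) + (n_b - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) return(new_ttest(0, df, 1, mean(a), mean(b), n_a, n_b))
    stop("degenerate samples: zero pooled variance with unequal means")
  }
  t_stat <- delta / (sqrt(sp2) * sqrt(1 / n_a + 1 / n_b))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  new_ttest(t_stat, df, p, mean(a), mean(b), n_a, n_b)
}

new_ttest <- function(t_stat, df, p, mean_a, mean_b, n_a, n_b) {
  structure(list(t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p, stars = star_annotation(p),
                 mean_a = mean_a, mean_b = mean_b, n_a = n_a, n_b = n_b),
            class = "thickness_ttest")
}

#' @export
print.thickness_ttest <- function(x, ...) {
  cat(sprintf("Student's t-test: t = %.4f, df = %s, p = %.4g (%s)\n",
              x$t_statistic, format(x$degrees_of_freedom), x$p_value,
              x$stars))
  cat(sprintf("  mean a = %.4f (n = %d), mean b = %.4f (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' GraphPad-style buckets: `ns` for p >= 0.05, then `*` (< 0.05),
#' `**` (< 0.01), `***` (< 0.001), `****` (< 0.0001); the most significant
#' applicable bucket wins.
#'
#' @param p P-value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
#' @examples
#' star_annotation(0.03)   # "*"
#' star_annotation(5e-5)   # "****"
star_annotation <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]")
  }
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Pairwise comparisons of each surrogate model against a reference
#'
#' Runs [students_t_test()] for every (surrogate, layer) combination in a
#' long-form measurement table against the reference model's measurements
#' of the same layer.
#'
#' @param table Measurement table from [measure_sections()].
#' @param reference Reference model id (default `"human"`).
#' @return Data frame with one row per (model, layer): `t_statistic`, `df`,
#'   `p_value`, `stars`.
#' @export
compare_models <- function(table, reference = "human") {
  if (!reference %in% table$model) {
    stop("reference model '", reference, "' absent from table")
  }
  others <- setdiff(unique(table$model), reference)
  layers <- unique(table$layer)
  rows <- list()
  for (m in others) {
    for (l in layers) {
      a <- table$thickness_um[table$model == m & table$layer == l]
      b <- table$thickness_um[table$model == reference & table$layer == l]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- students_t_test(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, reference = reference, layer = l,
        t_statistic = tt$t_statistic, df = tt$degrees_of_freedom,
        p_value = tt$p_value, stars = tt$stars, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
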