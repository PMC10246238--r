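#' Summarise a sample for a two-group comparison
#'
#' @param x numeric sample (length >= 2), or `NULL` when `n`, `mean`, `sd`
#'   are given directly (e.g. when recomputing from published summary
#'   statistics).
#' @param n,mean,sd group size, mean and sample standard deviation (n-1
#'   denominator).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    x <- as.numeric(x)
    if (length(x) < 2L) stopf("need n >= 2 observations per group")
    out <- list(n = length(x), mean = base::mean(x), sd = stats::sd(x))
  } else {
    if (is.null(n) || is.null(mean) || is.null(sd))
      stopf("supply either a sample x or all of n, mean, sd")
    if (n < 2L) stopf("need n >= 2 per group")
    if (sd < 0) stopf("sd must be >= 0")
    out <- list(n = as.integer(n), mean = as.numeric(mean),
                sd = as.numeric(sd))
  }
  structure(out, class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) x else group_summary(x)
}

#' Welch two-sample t-test with Cohen's d
#'
#' Unequal-variance (Welch) t-test between two groups, accepting either raw
#' samples or `group_summary` objects (so published n/mean/sd triplets can
#' be re-tested directly). The standard error is
#' `sqrt(sd_a^2/n_a + sd_b^2/n_b)`; degrees of freedom follow
#' Welch-Satterthwaite. The p-value is computed at the exact (unfloored)
#' df; `df_report` is the floored integer df conventionally printed
#' alongside t. Cohen's d uses the pooled sample SD (classic Cohen, no
#' small-sample correction).
#'
#' @param a,b numeric samples or `group_summary` objects; `a` is the group
#'   hypothesised larger under `alternative = "greater"`.
#' @param alternative `"greater"` (default; one-tailed a > b), `"less"`, or
#'   `"two_sided"`. One- and two-tailed p-values are both always reported:
#'   for `"two_sided"` the reported one-tailed value is the smaller tail.
#' @return object of class `welch_test`: `t`, `df_exact`, `df_report`,
#'   `p_one_tailed`, `p_two_tailed`, `cohens_d`, `alternative`, and the two
#'   `group_summary` inputs.
#' @examples
#' welch_t(group_summary(n = 10, mean = 37, sd = 30),
#'         group_summary(n = 46, mean = 19, sd = 24))
#' @export
welch_t <- function(a, b, alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  if (se == 0) stopf("both groups have zero variance")
  t <- (a$mean - b$mean) / se
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p_upper <- stats::pt(t, df, lower.tail = FALSE)
  p_one <- switch(alternative,
                  greater = p_upper,
                  less = 1 - p_upper,
                  two_sided = min(p_upper, 1 - p_upper))
  pooled_var <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  d <- if (pooled_var == 0) 0 else (a$mean - b$mean) / sqrt(pooled_var)
  structure(list(t = t, df_exact = df, df_report = as.integer(floor(df)),
                 p_one_tailed = p_one,
                 p_two_tailed = 2 * stats::pt(-abs(t), df),
                 cohens_d = d, alternative = alternative,
                 group_a = a, group_b = b),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t(%d) = %.2f (exact df %.2f), p[%s] = %.4g, p[two-tailed] = %.4g, d = %.2f\n",
              x$df_report, x$t, x$df_exact, x$alternative, x$p_one_tailed,
              x$p_two_tailed, x$cohens_d))
  invisible(x)
}

#' Symptom rate in a cohort
#'
#' @param labels binary (0/1 or logical) symptom status vector.
#' @return list with `rate`, `count` (positives) and `n`.
#' @examples
#' cms_rate(c(rep(1, 10), rep(0, 46)))  # 10/56 = 0.179
#' @export
cms_rate <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stopf("empty label vector")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary")
  list(rate = mean(labels), count = sum(labels), n = length(labels))
}

#' Symptom rate by lesion-load bin (dose-response table)
#'
#' Tabulates the positive rate within half-open lesion-load bins
#' `[e_i, e_{i+1})`, the last bin closed at 100, reproducing the
#' dose-response view of symptom rate against ROI lesion load. Empty bins
#' are reported with `n = 0` and `rate = NA`.
#'
#' @param loads lesion-load percentages in `[0, 100]`.
#' @param labels binary status vector, same length.
#' @param edges strictly increasing bin edges covering `[0, 100]` (first
#'   edge 0, last 100). Default `c(0, 1, 25, 50, 75, 100)`: a spared-ROI
#'   bin below 1% then quartile-style involvement bins.
#' @return data.frame of class `rate_by_bin`: `bin_lo`, `bin_hi`, `n`,
#'   `n_positive`, `rate`.
#' @export
rate_by_load_bin <- function(loads, labels,
                             edges = c(0, 1, 25, 50, 75, 100)) {
  loads <- as.numeric(loads)
  labels <- as.integer(labels)
  if (length(loads) != length(labels))
    stopf("loads and labels must have equal length")
  if (any(loads < 0 | loads > 100))
    stopf("lesion loads must lie in [0, 100]")
  if (any(diff(edges) <= 0)) stopf("edges must be strictly increasing")
  if (edges[1] != 0 || edges[length(edges)] != 100)
    stopf("edges must cover [0, 100]")
  bin <- findInterval(loads, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n <- tabulate(bin, nbins = nb)
  npos <- vapply(seq_len(nb), function(b) sum(labels[bin == b]), integer(1))
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    n = n, n_positive = npos,
                    rate = ifelse(n > 0, npos / n, NA_real_))
  class(out) <- c("rate_by_bin", "data.frame")
  out
}
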