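#' Adjusted Fisher-Pearson skewness (G1)
#'
#' `G1 = n^2 / ((n-1)(n-2)) * m3 / s^3` with `m3` the third central moment
#' and `s` the sample standard deviation — the convention used by common
#' desktop statistics packages, so published skewness values computed that
#' way are directly comparable.  Zero for a symmetric distribution;
#' negative when the left tail is longer.
#'
#' @param values numeric vector, `n >= 3`, non-degenerate.
#' @return skewness value.
#' @export
skewness <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  .assert(n >= 3, "skewness needs at least 3 values")
  s <- sd(values)
  .assert(s > 0, "skewness undefined for zero variance")
  m3 <- mean((values - mean(values))^3)
  n^2 / ((n - 1) * (n - 2)) * m3 / s^3
}

#' Summarize a per-copy asymmetry distribution
#'
#' Computes skewness, median, and a histogram over the asymmetry values of
#' non-truncated records (degenerate zero-variance distributions get
#' `skewness = NA` with a warning).
#'
#' @param records `asymmetry_records` data.frame (see
#'   [windowed_asymmetry()]) or a bare numeric vector of asymmetries.
#' @param bins number of histogram bins over `range`, default 21.
#' @param range histogram support, default `c(-1, 1)`.
#' @return list of class `distribution_summary`: `n_values`, `skewness`,
#'   `median`, `histogram` (list with `breaks`, `counts`).
#' @export
summarize_distribution <- function(records, bins = 21, range = c(-1, 1)) {
  values <- if (is.data.frame(records)) {
    records$asymmetry[!records$truncated]
  } else as.numeric(records)
  .assert(length(values) >= 3, "need at least 3 non-flagged records")
  sk <- if (sd(values) > 0) skewness(values) else {
    warning("zero variance: skewness undefined"); NA_real_
  }
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  counts <- graphics::hist(pmin(pmax(values, range[1]), range[2]),
                           breaks = breaks, plot = FALSE)$counts
  structure(list(n_values = length(values), skewness = sk,
                 median = median(values),
                 histogram = list(breaks = breaks, counts = counts)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d, median = %.4f, skewness = %s\n", x$n_values,
              x$median,
              if (is.na(x$skewness)) "undefined" else sprintf("%.4f", x$skewness)))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn pairwise post-hoc comparisons
#'
#' The omnibus test is tie-corrected ([stats::kruskal.test]); Dunn z
#' statistics use the pooled tie-corrected rank variance
#' `N(N+1)/12 - sum(t^3 - t)/(12(N-1))` and Bonferroni-adjusted two-sided
#' normal p-values.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return list with `H`, `p_kw`, and `pairwise` (data.frame `group_i`,
#'   `group_j`, `z`, `p_unadj`, `p_adj`).
#' @export
kruskal_dunn <- function(groups) {
  .assert(is.list(groups) && length(groups) >= 2,
          "need at least two groups")
  .assert(all(vapply(groups, length, integer(1)) >= 1),
          "every group needs at least one value")
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, integer(1))),
              levels = labels)
  kw <- kruskal.test(values, g)

  r <- rank(values)
  N <- length(values)
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(values)
  var_term <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))

  pairs <- utils::combn(labels, 2)
  k <- ncol(pairs)
  z <- p_un <- numeric(k)
  for (i in seq_len(k)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(var_term * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- if (se > 0) (mean_r[[a]] - mean_r[[b]]) / se else 0
    p_un[i] <- 2 * pnorm(-abs(z[i]))
  }
  list(H = unname(kw$statistic), p_kw = kw$p.value,
       pairwise = data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                             z = z, p_unadj = p_un,
                             p_adj = pmin(1, p_un * k),
                             stringsAsFactors = FALSE))
}
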