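# Group-level nonparametric statistics: paired two-tailed Wilcoxon
# signed-rank tests (exact small-sample p, tie-aware), Holm-Bonferroni
# step-down correction, and Pearson correlations of per-participant metrics.

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped before ranking; ties among the absolute
#' differences receive average ranks. The reported statistic `T` is the sum
#' of the ranks of the positive differences ("rank sum above zero"). For
#' `n <= exact_max` remaining pairs the two-tailed p-value is exact,
#' computed from the full sign-flip distribution of the rank sum (dynamic
#' programming over doubled ranks, so tied average ranks stay exact);
#' beyond that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b paired numeric vectors (e.g. per-participant wave V SNRs
#'   under two predictors).
#' @param exact_max largest n for which the exact distribution is used.
#' @return object of class `wilcoxon_result` with fields `T`, `p`, `n`
#'   (pairs after dropping zero differences), `degenerate` (all differences
#'   zero), `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(T = NA_real_, p = 1, n = 0L, degenerate = TRUE,
                          exact = TRUE), class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  T_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_p_exact(r, T_pos)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction
    sigma2 <- sum(r^2) / 4
    z <- (T_pos - mu - sign(T_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(T = T_pos, p = p, n = as.integer(n), degenerate = FALSE,
                 exact = exact), class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<wilcoxon> degenerate: all paired differences zero (p = 1)\n")
  } else {
    cat(sprintf("<wilcoxon> T = %g, p = %.4g (n = %d, %s)\n",
                x$T, x$p, x$n, if (x$exact) "exact" else "normal approx."))
  }
  invisible(x)
}

# Exact two-tailed p for the signed-rank sum given the rank vector (may
# contain average ranks, i.e. half-integers). All 2^n sign assignments are
# equally likely under H0; the distribution of the positive-rank sum is
# built by convolution over doubled (integer) ranks.
signed_rank_p_exact <- function(r, T_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1)   # counts[s+1] = #assignments with doubled sum s
  counts[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), counts[seq_len(total + 1 - rr)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  s_obs <- as.integer(round(2 * T_obs))
  mu <- total / 2
  dev <- abs(s_obs - mu)
  s_all <- 0:total
  p <- sum(probs[abs(s_all - mu) >= dev - 1e-9])
  min(1, p)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Standard step-down correction: with p-values sorted ascending,
#' `p'_(k) = max_{j <= k} min(1, (m - j + 1) p_(j))`, returned in the input
#' order. A thin wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pearson correlation with a t-test p-value
#'
#' Product-moment correlation with the two-tailed p-value from the
#' t-distribution on `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return list with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise predictor comparisons with Holm correction
#'
#' Runs paired Wilcoxon signed-rank tests of a per-participant metric
#' between predictor kinds and applies Holm-Bonferroni correction across
#' the family of contrasts. Participants lacking any of the compared
#' values are excluded pairwise.
#'
#' @param results data.frame with columns `participant`, `kind`, and the
#'   metric column.
#' @param metric metric column name (default `"snr_db"`).
#' @param contrasts list of 2-element character vectors naming the kinds to
#'   compare; defaults to all pairs present.
#' @return data.frame with columns `kind_a`, `kind_b`, `n`, `T`,
#'   `median_a`, `median_b`, `p_raw`, `p_holm`.
#' @export
compare_predictors <- function(results, metric = "snr_db", contrasts = NULL) {
  stopifnot(all(c("participant", "kind", metric) %in% names(results)))
  kinds <- unique(results$kind)
  if (is.null(contrasts)) {
    contrasts <- utils::combn(kinds, 2, simplify = FALSE)
  }
  rows <- lapply(contrasts, function(ct) {
    wide <- merge(
      results[results$kind == ct[1], c("participant", metric)],
      results[results$kind == ct[2], c("participant", metric)],
      by = "participant", suffixes = c("_a", "_b")
    )
    wide <- wide[stats::complete.cases(wide), ]
    a <- wide[[paste0(metric, "_a")]]; b <- wide[[paste0(metric, "_b")]]
    wt <- wilcoxon_signed_rank(a, b)
    data.frame(kind_a = ct[1], kind_b = ct[2], n = nrow(wide),
               T = if (wt$degenerate) NA_real_ else wt$T,
               median_a = stats::median(a), median_b = stats::median(b),
               p_raw = wt$p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}
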