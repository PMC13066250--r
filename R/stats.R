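# Paired nonparametric comparison protocol: Wilcoxon signed-rank tests per
# method pair, Benjamini-Hochberg adjustment within each metric family, plus
# the sample-skewness descriptor used for morphology analysis.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `x - y`. Zero differences are
#' discarded (classic Wilcoxon convention); tied absolute differences receive
#' mean ranks. With at most 25 non-zero pairs the two-sided p-value is exact:
#' the null distribution of the positive-rank sum V over all `2^n` equally
#' likely sign assignments is built by convolution (doubling the possibly
#' half-integer mean ranks makes every mass point an integer), so ties are
#' handled exactly rather than approximately. Beyond 25 pairs the normal
#' approximation with tie correction and continuity correction is used, as
#' in [stats::wilcox.test()]. Two-sided p is `2 * min(P(V <= v), P(V >= v))`
#' capped at 1.
#'
#' @param x,y equal-length numeric vectors of per-case values.
#' @return list with `statistic` (V, the positive-rank sum), `p` (two-sided),
#'   `nPairs` (pairs remaining after zero removal), `exact` (logical).
#' @export
#' @examples
#' wilcoxonSignedRank(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))$p  # 0.03125
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be equal-length vectors with at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("degenerate input: all paired differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  exact <- n <= 25L
  if (exact) {
    w <- as.integer(round(2 * r))        # doubled ranks are integral
    total <- sum(w)
    f <- numeric(total + 1L)             # f[k + 1] = P(2V = k)
    f[1] <- 1
    for (wi in w) {
      shifted <- numeric(total + 1L)
      shifted[(wi + 1L):(total + 1L)] <- f[seq_len(total + 1L - wi)]
      f <- (f + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p <- min(1, 2 * min(sum(f[seq_len(v2 + 1L)]),
                        sum(f[(v2 + 1L):(total + 1L)])))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p = p, nPairs = n, exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: sorted p-values `p_(i)` map to
#' `min_{j >= i} m p_(j) / j`, capped at 1, returned in input order.
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bias-corrected sample skewness
#'
#' Adjusted Fisher-Pearson coefficient
#' `G1 = sqrt(n (n-1)) / (n - 2) * m3 / m2^(3/2)` (moment estimator with
#' small-sample correction), used to characterize the asymmetry of per-case
#' morphology distributions such as tumor solidity.
#'
#' @param values numeric vector, `n >= 3`, non-constant.
#' @return the skewness (negative = left tail).
#' @export
sampleSkewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::var(values) == 0) stop("zero variance: skewness undefined")
  e1071::skewness(values, type = 2)
}

#' Pairwise method comparison with FDR control
#'
#' Builds the comparison set of the evaluation protocol: the STAPLE ensemble
#' against soft voting, STAPLE against each individual rater, and soft
#' voting against each individual rater — `1 + K + K` rows per metric (11
#' for the canonical five raters). Majority voting, if present among the
#' reports, is excluded from testing and reported descriptively only. For
#' each row a paired [wilcoxonSignedRank()] is computed on the per-case
#' metric values (cases matched by `case_id`); rows whose differences are
#' all zero are flagged degenerate and reported as non-significant with
#' `p = NA`. Benjamini-Hochberg adjustment is applied within each metric
#' family independently, over that family's testable rows. HD95 rows use the
#' pairwise-complete case subset (cases where both methods have a defined
#' HD95).
#'
#' @param reports named list of per-method metric tables as produced by
#'   [metricReport()] rows (must contain `case_id` and the metric columns).
#' @param staple,soft names (in `reports`) of the STAPLE and soft-voting
#'   ensembles.
#' @param exclude method names reported descriptively only (default
#'   `"majority"`); all remaining methods are the individual raters.
#' @param metrics metric families to test.
#' @param alpha significance level applied to adjusted p-values.
#' @return `data.frame` with columns `metric, method_a, method_b, n_pairs,
#'   statistic, p_raw, p_adjusted, significant, degenerate`; attribute
#'   `alpha` records the level.
#' @export
compareMethods <- function(reports, staple = "staple", soft = "soft",
                           exclude = "majority",
                           metrics = c("dsc", "ji", "hd95_mm", "precision", "recall"),
                           alpha = 0.05) {
  stopifnot(is.list(reports), !is.null(names(reports)))
  for (nm in c(staple, soft)) {
    if (!nm %in% names(reports))
      stop(sprintf("compareMethods: method '%s' not found in reports", nm))
  }
  individuals <- setdiff(names(reports), c(staple, soft, exclude))
  pairs <- rbind(data.frame(a = staple, b = soft),
                 data.frame(a = staple, b = individuals),
                 data.frame(a = soft, b = individuals))

  one_row <- function(metric, a, b) {
    ta <- reports[[a]]; tb <- reports[[b]]
    ids <- sort(intersect(ta$case_id, tb$case_id))
    va <- ta[[metric]][match(ids, ta$case_id)]
    vb <- tb[[metric]][match(ids, tb$case_id)]
    ok <- is.finite(va) & is.finite(vb)  # pairwise-complete (HD95 NAs drop)
    va <- va[ok]; vb <- vb[ok]
    if (length(va) == 0L || all(va == vb)) {
      return(data.frame(metric = metric, method_a = a, method_b = b,
                        n_pairs = sum(va != vb), statistic = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    w <- wilcoxonSignedRank(va, vb)
    data.frame(metric = metric, method_a = a, method_b = b,
               n_pairs = w$nPairs, statistic = w$statistic, p_raw = w$p,
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(metrics, function(metric) {
    fam <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      one_row(metric, pairs$a[i], pairs$b[i])
    }))
    fam$p_adjusted <- NA_real_
    ok <- !is.na(fam$p_raw)
    fam$p_adjusted[ok] <- bhAdjust(fam$p_raw[ok])
    fam
  }))
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out$degenerate <- is.na(out$p_raw)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
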