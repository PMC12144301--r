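# Differential-abundance statistics: plain and empirical-Bayes moderated
# two-sample tests, BH adjustment, Storey q-values, significance calls.

# Per-feature group summaries for a two-group contrast. x: log2 matrix.
.groupSummaries <- function(x, condition, reference) {
    conds <- unique(condition)
    if (length(conds) != 2L)
        stop("exactly two conditions are required for a contrast",
             call. = FALSE)
    test <- setdiff(conds, reference)
    a <- x[, condition == test, drop = FALSE]   # test group
    b <- x[, condition == reference, drop = FALSE]
    n1 <- unname(rowSums(!is.na(a))); n2 <- unname(rowSums(!is.na(b)))
    m1 <- unname(rowMeans(a, na.rm = TRUE))
    m2 <- unname(rowMeans(b, na.rm = TRUE))
    v1 <- unname(apply(a, 1L, stats::var, na.rm = TRUE))
    v2 <- unname(apply(b, 1L, stats::var, na.rm = TRUE))
    list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, v1 = v1, v2 = v2,
         lfc = m1 - m2, test = test)
}

# Two-sided p for a t statistic; df = Inf uses the normal limit. Zero pooled
# variance is treated as "data essentially constant": p = 0 for a non-zero
# difference, 1 otherwise.
.tTwoSided <- function(t, df) {
    p <- ifelse(is.infinite(df), 2 * stats::pnorm(-abs(t)),
                2 * stats::pt(-abs(t), df))
    p[is.infinite(t)] <- 0
    p
}

#' Plain two-sample t-test per feature
#'
#' Unpaired t-test (pooled variance by default, Welch optionally) of every
#' feature of a log2-scale \linkS4class{QuantExperiment} between the
#' non-reference condition and the reference. Features with fewer than two
#' non-missing values in either group get a missing p-value and are excluded
#' from multiplicity corrections downstream.
#'
#' @param x a log2-scale QuantExperiment with exactly two conditions.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return a \code{DataFrame}: \code{feature_id}, \code{log2fc}
#'   (test minus reference group mean), \code{t_stat}, \code{df},
#'   \code{p_value}.
#' @export
plainTTest <- function(x, welch = FALSE) {
    stopifnot(is(x, "QuantExperiment"))
    if (quantScale(x) != "log2")
        stop("plainTTest expects log2-scale data; see asLog2()", call. = FALSE)
    g <- .groupSummaries(quantValues(x), sampleConditions(x),
                         referenceCondition(x))
    ok <- g$n1 >= 2L & g$n2 >= 2L
    if (welch) {
        se2 <- g$v1 / g$n1 + g$v2 / g$n2
        df <- se2^2 / ((g$v1 / g$n1)^2 / (g$n1 - 1) +
                       (g$v2 / g$n2)^2 / (g$n2 - 1))
        tt <- g$lfc / sqrt(se2)
    } else {
        df <- g$n1 + g$n2 - 2
        s2 <- ((g$n1 - 1) * g$v1 + (g$n2 - 1) * g$v2) / df
        se2 <- s2 * (1 / g$n1 + 1 / g$n2)
        tt <- ifelse(se2 > 0, g$lfc / sqrt(se2),
                     ifelse(g$lfc == 0, 0, Inf * sign(g$lfc)))
    }
    p <- .tTwoSided(tt, df)
    tt[!ok] <- NA_real_; df[!ok] <- NA_real_; p[!ok] <- NA_real_
    DataFrame(feature_id = rownames(x), log2fc = g$lfc, t_stat = tt,
              df = df, p_value = p, tested = ok)
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment estimation of the scaled inverse-chi-squared prior on per-feature
#' variances: with \code{e = log(s^2) - digamma(d/2) + log(d/2)}, the excess
#' spread of \code{e} beyond \code{trigamma(d/2)} determines the prior
#' degrees of freedom \code{d0} by trigamma inversion, and the prior variance
#' \code{s0sq} follows from the mean of \code{e}. When the excess spread is
#' non-positive the prior is degenerate: \code{d0 = Inf} and \code{s0sq} is
#' the mean observed variance.
#'
#' @param s2 per-feature sample variances (log2 squared units).
#' @param df per-feature residual degrees of freedom (scalar or vector).
#' @return list of class \code{"ModeratedPrior"} with \code{d0} and
#'   \code{s0sq}.
#' @export
fitVariancePrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & s2 >= 0 & df >= 1
    s2 <- s2[ok]; df <- df[ok]
    if (length(s2) < 2L)
        stop("need at least two features with df >= 1", call. = FALSE)
    if (all(s2 == 0))
        stop("degenerate data: all variances are zero", call. = FALSE)
    # guard against exact zeros before taking logs
    s2 <- pmax(s2, 1e-5 * stats::median(s2[s2 > 0]))
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0sq <- mean(s2)
    }
    structure(list(d0 = d0, s0sq = s0sq), class = "ModeratedPrior")
}

# Newton solve of trigamma(y) = x.
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

#' Moderated two-sample t-test per feature
#'
#' Shrinks each feature's pooled variance toward the empirical-Bayes prior:
#' \code{s~^2 = (d0 s0^2 + d s^2) / (d0 + d)}; the statistic is the mean
#' difference over \code{s~ sqrt(1/n1 + 1/n2)} with \code{d0 + d} degrees of
#' freedom. \code{d0 = 0} reproduces the plain pooled t-test; \code{d0 = Inf}
#' fixes every variance at \code{s0^2}.
#'
#' @param x a log2-scale QuantExperiment with exactly two conditions.
#' @param prior optional \code{"ModeratedPrior"}; fitted from the data via
#'   [fitVariancePrior()] when \code{NULL}.
#' @return a \code{DataFrame} like [plainTTest()]'s, plus \code{s2_post}.
#' @export
moderatedTTest <- function(x, prior = NULL) {
    stopifnot(is(x, "QuantExperiment"))
    if (quantScale(x) != "log2")
        stop("moderatedTTest expects log2-scale data", call. = FALSE)
    g <- .groupSummaries(quantValues(x), sampleConditions(x),
                         referenceCondition(x))
    dg <- g$n1 + g$n2 - 2
    s2 <- ((g$n1 - 1) * g$v1 + (g$n2 - 1) * g$v2) / dg
    ok <- g$n1 >= 2L & g$n2 >= 2L
    if (is.null(prior))
        prior <- fitVariancePrior(s2[ok], dg[ok])
    d0 <- prior$d0; s0 <- prior$s0sq
    s2post <- if (is.infinite(d0)) rep(s0, length(s2))
              else (d0 * s0 + dg * s2) / (d0 + dg)
    se2 <- s2post * (1 / g$n1 + 1 / g$n2)
    tt <- ifelse(se2 > 0, g$lfc / sqrt(se2),
                 ifelse(g$lfc == 0, 0, Inf * sign(g$lfc)))
    dfTot <- d0 + dg
    p <- .tTwoSided(tt, dfTot)
    tt[!ok] <- NA_real_; p[!ok] <- NA_real_
    DataFrame(feature_id = rownames(x), log2fc = g$lfc, t_stat = tt,
              df = ifelse(ok, dfTot, NA_real_), p_value = p,
              s2_post = s2post, tested = ok)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; missing p-values propagate as missing and are
#' excluded from the correction denominator.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' \code{pi0 = min(1, mean(p > lambda) / (1 - lambda))} at a fixed
#' \code{lambda}, then takes the cumulative minimum (from the largest p) of
#' \code{pi0 * m * p_(i) / i} over the sorted p-values. With \code{pi0 = 1}
#' this equals the BH adjustment. Exact zeros are floored at the smallest
#' positive normal double first; missing p-values propagate as missing.
#'
#' @param p numeric vector of p-values.
#' @param lambda tuning constant in (0, 1) for the pi0 estimate.
#' @return list-free numeric vector of q-values with attribute \code{"pi0"}.
#' @export
storeyQ <- function(p, lambda = 0.5) {
    stopifnot(length(lambda) == 1L, lambda > 0, lambda < 1)
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    pp <- pmax(p[ok], .Machine$double.xmin)
    m <- length(pp)
    if (m == 0L) return(out)
    pi0 <- min(1, mean(pp > lambda) / (1 - lambda))
    o <- order(pp, decreasing = TRUE)
    i <- m:1L
    q <- pmin(1, cummin(pi0 * m * pp[o] / i))[order(o)]
    out[ok] <- q
    attr(out, "pi0") <- pi0
    out
}

#' Significance calls at q and fold-change thresholds
#'
#' Flags features with \code{q < qThreshold} and absolute log2 fold change
#' above \code{lfcThreshold} (defaults: Q < 0.05 and |log2 FC| > 0.58, i.e.
#' 1.5-fold).
#'
#' @param results a \code{DataFrame} with \code{log2fc} and the column named
#'   by \code{on}.
#' @param qThreshold significance threshold on the adjusted statistic.
#' @param lfcThreshold absolute log2 fold-change threshold.
#' @param on which column to threshold (\code{"q_value"} or \code{"adj_p"}).
#' @return \code{results} with a logical \code{significant} column.
#' @export
callSignificance <- function(results, qThreshold = 0.05,
                             lfcThreshold = 0.58, on = "q_value") {
    stopifnot(on %in% colnames(results))
    results$significant <- results[[on]] < qThreshold &
        abs(results$log2fc) > lfcThreshold
    results
}

#' Full differential test with multiplicity control
#'
#' Runs [plainTTest()] or [moderatedTTest()], adds BH-adjusted p-values and
#' Storey q-values, and calls significance. PTM-level analyses
#' conventionally threshold on q; protein-level analyses on \code{adj_p}.
#'
#' @param x a log2-scale QuantExperiment (use [asLog2()] for linear data).
#' @param method \code{"moderated"} or \code{"plain"}.
#' @param qThreshold,lfcThreshold see [callSignificance()].
#' @param on adjusted statistic to threshold.
#' @param lambda Storey pi0 tuning constant.
#' @param welch Welch variant for the plain test.
#' @return a \code{DataFrame} with test columns, \code{adj_p},
#'   \code{q_value}, \code{significant}.
#' @export
diffTest <- function(x, method = c("moderated", "plain"),
                     qThreshold = 0.05, lfcThreshold = 0.58,
                     on = "q_value", lambda = 0.5, welch = FALSE) {
    method <- match.arg(method)
    res <- if (method == "moderated") moderatedTTest(x)
           else plainTTest(x, welch = welch)
    res$adj_p <- bhAdjust(res$p_value)
    q <- storeyQ(res$p_value, lambda = lambda)
    res$q_value <- as.numeric(q)
    S4Vectors::metadata(res)$pi0 <- attr(q, "pi0")
    callSignificance(res, qThreshold, lfcThreshold, on = on)
}

#' Pearson correlation with a two-sided test
#'
#' Product-moment correlation; pairs with any missing value are dropped; the
#' p-value comes from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @return list \code{r}, \code{p_value}, \code{n}.
#' @export
pearsonCorrelation <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
        stop("need at least 3 complete pairs", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Upper-tail hypergeometric overlap test
#'
#' Exact probability of observing at least \code{k} shared elements between
#' two sets of sizes \code{n1} and \code{n2} drawn from a universe of size
#' \code{N}.
#'
#' @param k observed overlap.
#' @param n1,n2 set sizes.
#' @param N universe size.
#' @return p-value \code{P(X >= k)}.
#' @export
hypergeometricOverlap <- function(k, n1, n2, N) {
    stopifnot(k >= 0, n1 >= 0, n2 >= 0, N >= max(n1, n2), k <= min(n1, n2))
    stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
}
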