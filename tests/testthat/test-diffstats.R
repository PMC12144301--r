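test_that("plain pooled t matches the closed form and handles degeneracies", {
    qe <- makeQE(matrix(c(1, 2, 3, 4, 5, 6), 1, 6), 3, scale = "log2")
    res <- plainTTest(qe)
    expect_equal(res$log2fc, 3)
    expect_equal(res$t_stat, 3 / sqrt(1 * (2 / 3)), tolerance = 1e-10)
    expect_equal(res$df, 4)
    # cross-check against stats::t.test
    tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

    same <- makeQE(matrix(rep(c(1, 2, 3), 2), 1, 6), 3, scale = "log2")
    resSame <- plainTTest(same)
    expect_equal(resSame$t_stat, 0)
    expect_equal(resSame$p_value, 1)

    short <- makeQE(matrix(c(1, NA, NA, 4, 5, 6), 1, 6), 3, scale = "log2")
    resShort <- plainTTest(short)
    expect_true(is.na(resShort$p_value))
    expect_false(resShort$tested)
})

test_that("variance prior matches an independent root-finder and limma", {
    # zero excess spread: equal variances, equal dfs
    pr <- fitVariancePrior(rep(2, 10), 4)
    expect_identical(pr$d0, Inf)
    expect_equal(pr$s0sq, 2, tolerance = 1e-12)

    set.seed(71)
    s2 <- rf(200, 4, 6) * 1.5
    pr2 <- fitVariancePrior(s2, 4)
    oracle <- priorOracle(s2, 4)
    expect_equal(pr2$d0, oracle$d0, tolerance = 1e-6)
    expect_equal(pr2$s0sq, oracle$s0sq, tolerance = 1e-6)
    # independent implementation cross-check
    lf <- limma::fitFDist(s2, df1 = 4)
    expect_equal(pr2$d0, lf$df2, tolerance = 1e-6)
    expect_equal(pr2$s0sq, lf$scale, tolerance = 1e-6)

    expect_error(fitVariancePrior(rep(0, 5), 4), "zero")
})

test_that("prior degrees of freedom are recovered from scaled-F variances", {
    set.seed(72)
    s2 <- rf(5000, 4, 4)  # s0^2 = 1, d0 = 4, residual df = 4
    pr <- fitVariancePrior(s2, 4)
    expect_lt(abs(pr$d0 - 4) / 4, 0.2)
    expect_lt(abs(pr$s0sq - 1), 0.2)
})

test_that("moderated t obeys its limit cases and the shrinkage arithmetic", {
    set.seed(73)
    m <- matrix(rnorm(60, 10, 0.5), 10, 6)
    m[, 4:6] <- m[, 4:6] + rep(c(0, 1), 5)
    qe <- makeQE(m, 3, scale = "log2")

    # d0 -> 0 reduces to the plain pooled t
    prior0 <- structure(list(d0 = 1e-12, s0sq = 1), class = "ModeratedPrior")
    expect_equal(moderatedTTest(qe, prior0)$t_stat, plainTTest(qe)$t_stat,
                 tolerance = 1e-5)
    # d0 = Inf forces the posterior variance to s0^2
    priorInf <- structure(list(d0 = Inf, s0sq = 0.33),
                          class = "ModeratedPrior")
    expect_equal(moderatedTTest(qe, priorInf)$s2_post, rep(0.33, 10))

    # hand-worked shrinkage: d0=4, s0^2=1, s^2=2, d=4, diff=1, n=3+3
    a <- c(-sqrt(2), 0, sqrt(2)); b <- a + 1
    qe1 <- makeQE(matrix(c(a, b), 1, 6), 3, scale = "log2")
    prior <- structure(list(d0 = 4, s0sq = 1), class = "ModeratedPrior")
    res <- moderatedTTest(qe1, prior)
    expect_equal(res$s2_post, 1.5, tolerance = 1e-12)
    expect_equal(res$t_stat, 1, tolerance = 1e-12)
    expect_equal(res$df, 8)
    # limma cross-check on the full matrix
    design <- cbind(1, rep(c(0, 1), each = 3))
    fit <- limma::eBayes(limma::lmFit(m, design))
    ours <- moderatedTTest(qe)
    expect_equal(ours$t_stat, fit$t[, 2], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(ours$p_value, fit$p.value[, 2], tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("moderated t approaches the plain t monotonically as d0 shrinks", {
    set.seed(74)
    qe <- makeQE(matrix(rnorm(30, 0, 1), 5, 6), 3, scale = "log2")
    plain <- plainTTest(qe)$t_stat
    prev <- NULL
    for (d0 in c(8, 2, 0.5, 0.01)) {
        cur <- moderatedTTest(qe, structure(list(d0 = d0, s0sq = 0.5),
                                            class = "ModeratedPrior"))$t_stat
        gap <- abs(cur - plain)
        if (!is.null(prev)) expect_true(all(gap <= prev + 1e-12))
        prev <- gap
    }
    expect_lt(max(prev), 0.02)
})

test_that("BH and Storey q-values match their step-up definitions", {
    p <- c(0.01, 0.02, 0.04)
    expect_equal(bhAdjust(p), c(0.03, 0.03, 0.04), tolerance = 1e-12)
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
    expect_equal(bhAdjust(c(0.01, NA, 0.04)),
                 c(0.02, NA, 0.04), tolerance = 1e-12)

    p4 <- c(0.02, 0.5, 0.9, 0.95)
    q <- storeyQ(p4, lambda = 0.5)
    expect_equal(attr(q, "pi0"), 1)
    expect_equal(as.numeric(q), c(0.08, 0.95, 0.95, 0.95), tolerance = 1e-12)
    expect_equal(as.numeric(storeyQ(rep(1, 4))), rep(1, 4))

    set.seed(75)
    pr <- runif(200)^2
    expect_equal(as.numeric(storeyQ(pr)), storeyOracle(pr), tolerance = 1e-12)
    expect_equal(bhAdjust(pr), bhOracle(pr), tolerance = 1e-12)
    # q <= BH pointwise whenever pi0 < 1; equality at pi0 = 1
    qv <- storeyQ(pr)
    if (attr(qv, "pi0") < 1) expect_true(all(qv <= bhAdjust(pr) + 1e-12))
    punif <- c(0.3, 0.6, 0.8, 0.9)
    expect_equal(as.numeric(storeyQ(punif)), bhAdjust(punif),
                 tolerance = 1e-12)
})

test_that("significance needs both the q and the fold-change threshold", {
    res <- S4Vectors::DataFrame(
        feature_id = c("a", "b", "c"),
        log2fc = c(1.0, 0.5, 2.0),
        q_value = c(0.01, 0.01, 0.06))
    out <- callSignificance(res)
    expect_identical(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("Pearson correlation matches the product-moment formula", {
    x <- 1:10
    expect_equal(pearsonCorrelation(x, 2 * x)$r, 1, tolerance = 1e-12)
    xo <- c(-1, 1, -1, 1); yo <- c(-1, -1, 1, 1)
    expect_equal(pearsonCorrelation(xo, yo)$r, 0, tolerance = 1e-12)
    set.seed(76)
    a <- rnorm(10); b <- rnorm(10)
    got <- pearsonCorrelation(a, b)
    r <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    tstat <- r * sqrt(8 / (1 - r^2))
    expect_equal(got$r, r, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
    # missing pairs dropped
    a[3] <- NA
    expect_equal(pearsonCorrelation(a, b)$n, 9)
})

test_that("hypergeometric overlap is the exact upper tail", {
    expect_equal(hypergeometricOverlap(2, 3, 3, 10), 22 / 120,
                 tolerance = 1e-12)
    expect_equal(hypergeometricOverlap(0, 3, 3, 10), 1)
    expect_equal(hypergeometricOverlap(4, 4, 4, 4), 1)
    set.seed(77)
    for (i in 1:10) {
        N <- sample(10:40, 1)
        n1 <- sample(1:N, 1); n2 <- sample(1:N, 1)
        k <- sample(0:min(n1, n2), 1)
        expect_equal(hypergeometricOverlap(k, n1, n2, N),
                     hyperOracle(k, n1, n2, N), tolerance = 1e-10)
    }
})

test_that("tests are invariant to feature and within-group sample order", {
    set.seed(78)
    m <- matrix(rnorm(48, 10, 1), 8, 6)
    qe <- makeQE(m, 3, scale = "log2")
    perm <- makeQE(m[c(5, 1, 8, 2, 7, 3, 6, 4), c(2, 3, 1, 6, 4, 5)], 3,
                   scale = "log2")
    a <- diffTest(qe); b <- diffTest(perm)
    # perm's feature i is original row permRows[i]
    permRows <- c(5, 1, 8, 2, 7, 3, 6, 4)
    ord <- match(seq_len(8), permRows)
    expect_equal(a$t_stat, b$t_stat[ord], tolerance = 1e-12)
    expect_equal(a$q_value, b$q_value[ord], tolerance = 1e-12)
})
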