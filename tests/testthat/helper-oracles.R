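# Independent brute-force oracles used to freeze expected values. These
# deliberately re-derive each quantity from first principles and share no
# code with the implementation under test.

# Smith-Waterman with affine gaps (Gotoh), literal O(nm) recursion.
# Gap of length L costs open + L * ext (BLAST convention).
swOracleScore <- function(q, t, open = 11, ext = 1) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    S <- BLOSUM62
    qc <- strsplit(q, "")[[1]]
    tc <- strsplit(t, "")[[1]]
    n <- length(qc); m <- length(tc)
    M <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)   # gap in query (consume target)
    F_ <- matrix(-Inf, n + 1, m + 1)  # gap in target (consume query)
    best <- 0
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            E[i, j] <- max(M[i, j - 1] - (open + ext), E[i, j - 1] - ext)
            F_[i, j] <- max(M[i - 1, j] - (open + ext), F_[i - 1, j] - ext)
            diag <- max(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
            M[i, j] <- max(0, diag + S[qc[i - 1], tc[j - 1]])
            best <- max(best, M[i, j])
        }
    }
    best
}

# BH step-up, literal definition.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
}

# Storey q-values, literal definition.
storeyOracle <- function(p, lambda = 0.5) {
    m <- length(p)
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
    o <- order(p)
    raw <- pi0 * m * p[o] / seq_len(m)
    q <- rev(cummin(rev(raw)))
    pmin(1, q)[order(o)]
}

# Upper-tail hypergeometric by explicit summation of the pmf.
hyperOracle <- function(k, n1, n2, N) {
    kk <- k:min(n1, n2)
    sum(choose(n1, kk) * choose(N - n1, n2 - kk)) / choose(N, n2)
}

# GSEA enrichment score by a literal walk down the ranking.
gseaEsOracle <- function(scores, set, weight = 1) {
    s <- sort(scores, decreasing = TRUE)
    hit <- names(s) %in% set
    Nh <- sum(hit); N <- length(s)
    wsum <- sum(abs(s[hit])^weight)
    rs <- 0; esBest <- 0
    for (i in seq_len(N)) {
        if (hit[i]) {
            rs <- rs + if (wsum > 0) abs(s[i])^weight / wsum else 1 / Nh
        } else {
            rs <- rs - 1 / (N - Nh)
        }
        if (abs(rs) > abs(esBest)) esBest <- rs
    }
    unname(esBest)
}

# Moment-equation root for the variance prior, solved with uniroot
# (independent of the package's Newton iteration).
priorOracle <- function(s2, df) {
    df <- rep_len(df, length(s2))
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (evar <= 0) return(list(d0 = Inf, s0sq = mean(s2)))
    half <- stats::uniroot(function(y) trigamma(y) - evar,
                           interval = c(1e-8, 1e8), tol = 1e-12)$root
    d0 <- 2 * half
    list(d0 = d0, s0sq = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

# Small builders -----------------------------------------------------------

makeDesign <- function(nPerGroup = 3, conditions = c("young", "old")) {
    data.frame(
        sample_id = unlist(lapply(conditions, function(cd)
            sprintf("%s_%d", cd, seq_len(nPerGroup)))),
        condition = rep(conditions, each = nPerGroup),
        stringsAsFactors = FALSE)
}

# QuantExperiment from per-condition value lists, one feature.
makeQE1 <- function(valuesByCondition, reference = names(valuesByCondition)[1],
                    scale = "linear", featureId = "f1") {
    vals <- unlist(valuesByCondition, use.names = FALSE)
    conds <- rep(names(valuesByCondition), lengths(valuesByCondition))
    design <- data.frame(
        sample_id = sprintf("s%d", seq_along(vals)), condition = conds)
    m <- matrix(vals, nrow = 1,
                dimnames = list(featureId, design$sample_id))
    QuantExperiment(m, design, reference, scale)
}

# QuantExperiment from a matrix and a two-group design.
makeQE <- function(m, nPerGroup, reference = "young",
                   conditions = c("young", "old"), scale = "log2") {
    design <- makeDesign(nPerGroup, conditions)
    colnames(m) <- design$sample_id
    if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
    QuantExperiment(m, design, reference, scale)
}

randomAASeq <- function(n, prob = NULL) {
    aa <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
    paste(sample(aa, n, replace = TRUE, prob = prob), collapse = "")
}
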