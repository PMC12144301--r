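# Rank-based gene-set enrichment: weighted Kolmogorov-Smirnov enrichment
# score with gene-label permutation normalization, and hypergeometric
# over-representation, plus PTM-site -> gene aggregation.

#' Aggregate site-level statistics to gene level
#'
#' Collapses per-site statistics onto genes for preranked enrichment. The
#' default rule keeps, per gene, the site statistic of largest absolute
#' value (preserving sign); \code{mean} and \code{median} are alternatives.
#'
#' @param stats named numeric vector of site-level statistics (names are
#'   site/peptide ids).
#' @param siteGeneMap data.frame with columns \code{site} and \code{gene}.
#' @param rule \code{"max_abs"}, \code{"mean"} or \code{"median"}.
#' @return named numeric vector of gene scores.
#' @export
aggregateSitesToGenes <- function(stats, siteGeneMap,
                                  rule = c("max_abs", "mean", "median")) {
    rule <- match.arg(rule)
    stopifnot(all(c("site", "gene") %in% colnames(siteGeneMap)))
    idx <- siteGeneMap$site %in% names(stats)
    map <- siteGeneMap[idx, , drop = FALSE]
    vals <- stats[map$site]
    agg <- switch(rule,
        max_abs = tapply(vals, map$gene,
                         function(v) v[which.max(abs(v))]),
        mean = tapply(vals, map$gene, mean),
        median = tapply(vals, map$gene, stats::median))
    out <- as.numeric(agg)
    names(out) <- names(agg)
    out
}

# ES for a hit set given |score|^weight at all ranks (sorted desc) and the
# hit positions. Vectorized over the hit positions: extrema of the running
# sum occur immediately after a hit (peak candidates) or just before one
# (trough candidates).
.esFromPositions <- function(absw, idx, N) {
    idx <- sort(idx)
    Nh <- length(idx)
    w <- absw[idx]
    tot <- sum(w)
    missStep <- 1 / (N - Nh)
    if (tot == 0) {  # all hit scores zero: uniform hit steps
        w <- rep(1 / Nh, Nh)
    } else {
        w <- w / tot
    }
    ch <- cumsum(w)
    j <- seq_len(Nh)
    if (N == Nh) return(1)  # no miss steps: running sum peaks at 1
    peak <- ch - (idx - j) * missStep
    trough <- c(0, ch[-Nh]) - (idx - 1 - (j - 1)) * missStep
    top <- max(peak); bot <- min(trough, 0)
    if (top >= -bot) top else bot
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ranked by score descending. Walking down the ranking, the
#' running sum rises by \code{|score|^weight / sum(|score|^weight over set
#' members)} at each set member and falls by \code{1/(N - n_set)} otherwise;
#' the enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed). \code{weight = 0} gives the classic
#' (unweighted) KS statistic.
#'
#' @param scores named numeric vector (gene id -> signed ranking statistic).
#' @param set character vector of member ids; the intersection with
#'   \code{scores} must be non-empty.
#' @param weight exponent on the absolute score (default 1).
#' @return enrichment score in [-1, 1].
#' @export
gseaES <- function(scores, set, weight = 1) {
    if (anyDuplicated(names(scores)))
        stop("gene ids must be unique", call. = FALSE)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    idx <- which(names(s) %in% set)
    if (!length(idx))
        stop("empty intersection between the ranked list and the set",
             call. = FALSE)
    .esFromPositions(abs(s)^weight, idx, length(s))
}

#' Permutation-normalized gene-set enrichment over a collection
#'
#' For every set: the observed enrichment score, a null distribution of
#' scores from permuting gene labels (equivalently, drawing random member
#' positions of the same size), the normalized enrichment score
#' \code{NES = ES / mean(|null ES| of the same sign)}, and a permutation
#' p-value with a +1 pseudo-count. P-values are BH-adjusted across sets.
#' Terms without members in the ranked list are skipped with a message.
#'
#' @param scores named numeric vector of gene scores.
#' @param sets named list of member-id vectors (e.g. from [readGmt()]).
#' @param nPerm number of permutations (> 0).
#' @param weight exponent on the absolute score.
#' @param seed RNG seed; fixed seed makes the result deterministic.
#' @return data.frame: \code{term}, \code{size} (members used), \code{ES},
#'   \code{NES}, \code{p_value}, \code{adj_p}.
#' @export
gseaPermutation <- function(scores, sets, nPerm = 1000L, weight = 1,
                            seed = NULL) {
    if (nPerm < 1L) stop("nPerm must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    absw <- abs(s)^weight
    N <- length(s)
    rows <- list()
    for (term in names(sets)) {
        members <- intersect(sets[[term]], names(s))
        if (!length(members)) {
            message("term '", term, "' has no members in the ranked list; skipped")
            next
        }
        Nh <- length(members)
        es <- .esFromPositions(absw, which(names(s) %in% members), N)
        null <- vapply(seq_len(nPerm), function(i)
            .esFromPositions(absw, sample.int(N, Nh), N), numeric(1))
        sameSign <- null[sign(null) == sign(es)]
        nes <- if (length(sameSign)) es / mean(abs(sameSign)) else NA_real_
        p <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
        rows[[term]] <- data.frame(term = term, size = Nh, ES = es,
                                   NES = nes, p_value = p,
                                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$adj_p <- bhAdjust(out$p_value)
    out
}

#' Hypergeometric over-representation analysis
#'
#' Per term, an upper-tail hypergeometric test of the foreground against the
#' universe of background genes annotated to at least one set in the
#' collection; BH adjustment across terms.
#'
#' @param foreground character vector of genes of interest.
#' @param background character vector of quantified genes.
#' @param sets named list of member-id vectors.
#' @return data.frame: \code{term}, \code{overlap}, \code{set_size},
#'   \code{fg_size}, \code{universe}, \code{p_value}, \code{adj_p}.
#' @export
oraHypergeometric <- function(foreground, background, sets) {
    annotated <- unique(unlist(sets, use.names = FALSE))
    universe <- intersect(unique(background), annotated)
    fg <- intersect(unique(foreground), universe)
    rows <- lapply(names(sets), function(term) {
        K <- length(intersect(sets[[term]], universe))
        k <- length(intersect(sets[[term]], fg))
        p <- if (K == 0L) 1
             else hypergeometricOverlap(k, K, length(fg), length(universe))
        data.frame(term = term, overlap = k, set_size = K,
                   fg_size = length(fg), universe = length(universe),
                   p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$adj_p <- bhAdjust(out$p_value)
    out
}
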