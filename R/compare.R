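# Joining differential results across datasets on matched sites and
# classifying each site: cross-species consistency categories and
# intervention (dietary restriction / re-feeding) response categories.

.CONSISTENCY_LEVELS <- c("consistent_up_strict", "consistent_up_relaxed",
                         "consistent_down_strict", "consistent_down_relaxed",
                         "not_consistent", "unclassified")
.DIET_LEVELS <- c("exacerbated", "reverted_down", "reverted_up",
                  "congruent_trend", "other")

#' Cross-dataset consistency categories
#'
#' Classifies matched sites by agreement of direction and significance:
#' strict consistency requires p < \code{strictP} in both datasets with the
#' same sign, relaxed consistency p < \code{relaxedP} in both; opposite signs
#' at p < \code{relaxedP} in both are \code{not_consistent}; anything with
#' p >= \code{relaxedP} in either dataset is \code{unclassified}.
#'
#' @param lfcA,pA,lfcB,pB vectors of log2 fold changes and p-values for the
#'   two datasets (same orientation: treated/old minus reference).
#' @param strictP,relaxedP thresholds (defaults 0.05 and 0.25).
#' @return factor with levels
#'   \code{consistent_up_strict, consistent_up_relaxed,
#'   consistent_down_strict, consistent_down_relaxed, not_consistent,
#'   unclassified}.
#' @export
classifyConsistency <- function(lfcA, pA, lfcB, pB,
                                strictP = 0.05, relaxedP = 0.25) {
    out <- rep("unclassified", length(lfcA))
    bothRelax <- !is.na(pA) & !is.na(pB) & pA < relaxedP & pB < relaxedP
    bothStrict <- bothRelax & pA < strictP & pB < strictP
    up <- lfcA > 0 & lfcB > 0
    down <- lfcA < 0 & lfcB < 0
    opp <- lfcA * lfcB < 0
    out[bothStrict & up] <- "consistent_up_strict"
    out[bothRelax & !bothStrict & up] <- "consistent_up_relaxed"
    out[bothStrict & down] <- "consistent_down_strict"
    out[bothRelax & !bothStrict & down] <- "consistent_down_relaxed"
    out[bothRelax & opp] <- "not_consistent"
    factor(out, levels = .CONSISTENCY_LEVELS)
}

#' Intervention response categories
#'
#' For sites significant (q below threshold) in at least one of the two
#' matched datasets: \code{exacerbated} — significant in both with the same
#' sign; \code{reverted_down} — age-increased sites significantly decreased
#' by the intervention; \code{reverted_up} — age-decreased sites
#' significantly increased; \code{congruent_trend} — same sign, significant
#' in exactly one; \code{other} — the remainder. The age-side direction is
#' taken from the sign of the age log2 fold change regardless of age-side
#' significance. Sites significant in neither dataset are \code{NA} (they
#' are excluded upstream).
#'
#' @param lfcAge,qAge,lfcDiet,qDiet vectors for the aging and intervention
#'   contrasts.
#' @param qThreshold significance threshold (default 0.05).
#' @return factor with levels \code{exacerbated, reverted_down, reverted_up,
#'   congruent_trend, other}; \code{NA} for sites significant in neither.
#' @export
classifyDietResponse <- function(lfcAge, qAge, lfcDiet, qDiet,
                                 qThreshold = 0.05) {
    sigA <- !is.na(qAge) & qAge < qThreshold
    sigD <- !is.na(qDiet) & qDiet < qThreshold
    included <- sigA | sigD
    same <- lfcAge * lfcDiet > 0
    out <- rep(NA_character_, length(lfcAge))
    out[included] <- "other"
    out[included & same & sigA & sigD] <- "exacerbated"
    out[included & same & xor(sigA, sigD)] <- "congruent_trend"
    out[lfcAge > 0 & sigD & lfcDiet < 0] <- "reverted_down"
    out[lfcAge < 0 & sigD & lfcDiet > 0] <- "reverted_up"
    factor(out, levels = .DIET_LEVELS)
}

#' Overlap of significant sites between two datasets
#'
#' Counts shared and exclusive significant sites over the cross-quantified
#' universe and tests the overlap with the upper-tail hypergeometric test.
#'
#' @param sigA,sigB logical vectors (significant in A / in B) over the same
#'   universe of matched sites.
#' @return list: \code{n_universe}, \code{n_a}, \code{n_b}, \code{n_shared},
#'   \code{n_a_only}, \code{n_b_only}, \code{p_value}.
#' @export
overlapSummary <- function(sigA, sigB) {
    stopifnot(length(sigA) == length(sigB))
    sigA[is.na(sigA)] <- FALSE
    sigB[is.na(sigB)] <- FALSE
    k <- sum(sigA & sigB)
    list(n_universe = length(sigA), n_a = sum(sigA), n_b = sum(sigB),
         n_shared = k, n_a_only = sum(sigA & !sigB),
         n_b_only = sum(sigB & !sigA),
         p_value = hypergeometricOverlap(k, sum(sigA), sum(sigB),
                                         length(sigA)))
}

#' Correlation of fold changes across matched datasets
#'
#' Filters matched sites on a significance threshold in both datasets (or in
#' at least one), then computes the two-sided Pearson correlation of the
#' log2 fold-change pairs.
#'
#' @param lfcA,lfcB log2 fold changes of the matched sites.
#' @param pA,pB the significance statistic to filter on (p or q values).
#' @param threshold filter threshold (default 0.05).
#' @param scope \code{"both"}: the filter must hold in both datasets;
#'   \code{"either"}: in at least one.
#' @return list \code{r}, \code{p_value}, \code{n}.
#' @export
fcCorrelation <- function(lfcA, lfcB, pA = NULL, pB = NULL,
                          threshold = 0.05, scope = c("both", "either")) {
    scope <- match.arg(scope)
    keep <- rep(TRUE, length(lfcA))
    if (!is.null(pA) && !is.null(pB)) {
        inA <- !is.na(pA) & pA < threshold
        inB <- !is.na(pB) & pB < threshold
        keep <- if (scope == "both") inA & inB else inA | inB
    }
    pearsonCorrelation(lfcA[keep], lfcB[keep])
}
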