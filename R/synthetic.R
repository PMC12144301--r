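# Synthetic data generation with recorded ground truth. The generator
# emulates a two-group DIA PTM experiment: log-normal protein abundances
# with condition effects, modified peptides whose quantities track their
# protein times an independent stoichiometry effect, and intensity-dependent
# (left-censored) missingness.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

#' Simulation configuration
#'
#' Study conditions default to the profiled aging design: two groups
#' (young reference vs old), 5 biological replicates per group, log2
#' measurement noise 0.25, and unit (2-fold) planted effects. Site labels are
#' assigned per protein so that a protein is either unchanged, changed in
#' abundance (\code{protein_driven} sites), or carries a stoichiometry change
#' (\code{stoich_driven} sites).
#'
#' @param nProteins number of simulated proteins.
#' @param sitesPerProtein integer length-2 (min, max) sites per protein.
#' @param nPerGroup replicates per condition (>= 2).
#' @param conditions two condition labels; the first is the reference.
#' @param proteinEffect,stoichEffect planted log2 effect magnitudes (random
#'   sign per protein).
#' @param fracProteinDriven,fracStoichDriven,fracNull proportions of proteins
#'   per class; must sum to 1.
#' @param noiseSd log2 measurement noise s.d. (peptide and protein channels
#'   are independent).
#' @param missingRateAtLowIntensity asymptotic missingness proportion at very
#'   low intensity (logistic in log2 intensity).
#' @param missingMidpoint,missingSlope logistic midpoint (log2 intensity at
#'   half the maximal rate) and slope.
#' @param baselineMean,baselineSd log2 protein baseline distribution.
#' @param peptideOffsetMean,peptideOffsetSd log2 offset of modified-peptide
#'   intensity relative to its protein.
#' @param seed RNG seed.
#' @return a validated config list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nProteins = 300L, sitesPerProtein = c(1L, 3L),
                      nPerGroup = 5L, conditions = c("young", "old"),
                      proteinEffect = 1, stoichEffect = 1,
                      fracProteinDriven = 0.2, fracStoichDriven = 0.3,
                      fracNull = 0.5, noiseSd = 0.25,
                      missingRateAtLowIntensity = 0,
                      missingMidpoint = 16, missingSlope = 1,
                      baselineMean = 20, baselineSd = 2,
                      peptideOffsetMean = -2, peptideOffsetSd = 1,
                      seed = 20250606L) {
    frac <- c(fracNull, fracProteinDriven, fracStoichDriven)
    if (any(frac < 0) || any(frac > 1) || abs(sum(frac) - 1) > 1e-9)
        stop("config error: class fractions must lie in [0,1] and sum to 1",
             call. = FALSE)
    if (nPerGroup < 2L) stop("config error: nPerGroup must be >= 2",
                             call. = FALSE)
    if (length(conditions) != 2L)
        stop("config error: exactly two conditions are supported",
             call. = FALSE)
    if (noiseSd < 0 || baselineSd < 0 || peptideOffsetSd < 0)
        stop("config error: standard deviations must be >= 0", call. = FALSE)
    if (missingRateAtLowIntensity < 0 || missingRateAtLowIntensity > 1)
        stop("config error: missing rate must lie in [0,1]", call. = FALSE)
    structure(as.list(environment()), class = "SimConfig")
}

# P(missing | true log2 intensity): logistic left-censoring.
.missingProb <- function(x, cfg) {
    cfg$missingRateAtLowIntensity /
        (1 + exp(cfg$missingSlope * (x - cfg$missingMidpoint)))
}

#' Simulate a protein + modified-peptide quantification experiment
#'
#' Generates a linear-scale protein \linkS4class{QuantExperiment}, a
#' linear-scale modified-peptide QuantExperiment, the matching
#' \linkS4class{PtmSiteTable} and a ground-truth table recording each site's
#' class (\code{null}, \code{protein_driven}, \code{stoich_driven}), its true
#' stoichiometry log2 delta, and its true corrected log2 fold change.
#'
#' Observed linear quantities are \code{2^(true log2 + N(0, noiseSd))};
#' peptide quantity is the protein's true abundance shifted by the site's
#' stoichiometry delta, with measurement noise independent of the protein
#' channel. Missingness is applied cell-wise with a probability that
#' increases logistically as true intensity decreases.
#'
#' @param config a [simConfig()] object.
#' @return list with elements \code{proteins}, \code{peptides}
#'   (QuantExperiments), \code{sites} (PtmSiteTable), \code{truth}
#'   (site-level \code{DataFrame}) and \code{proteinTruth}.
#' @export
simulateQuantExperiment <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    nP <- as.integer(config$nProteins)
    ref <- config$conditions[1L]
    alt <- config$conditions[2L]

    counts <- .apportion(nP, c(config$fracNull, config$fracProteinDriven,
                               config$fracStoichDriven))
    label <- sample(rep(c("null", "protein_driven", "stoich_driven"), counts))
    acc <- sprintf("PROT%04d", seq_len(nP))
    baseline <- stats::rnorm(nP, config$baselineMean, config$baselineSd)
    effSign <- sample(c(-1, 1), nP, replace = TRUE)
    protEffect <- ifelse(label == "protein_driven",
                         effSign * config$proteinEffect, 0)
    stoSign <- sample(c(-1, 1), nP, replace = TRUE)
    stoDelta <- ifelse(label == "stoich_driven",
                       stoSign * config$stoichEffect, 0)

    n <- config$nPerGroup
    design <- data.frame(
        sample_id = c(sprintf("%s_%d", ref, seq_len(n)),
                      sprintf("%s_%d", alt, seq_len(n))),
        condition = rep(c(ref, alt), each = n),
        stringsAsFactors = FALSE)
    isAlt <- design$condition == alt
    nS <- 2L * n

    # protein matrix
    trueProt <- outer(baseline, rep(0, nS), `+`)
    trueProt[, isAlt] <- trueProt[, isAlt] + protEffect
    protObs <- trueProt + stats::rnorm(nP * nS, 0, config$noiseSd)
    dimnames(protObs) <- list(acc, design$sample_id)
    dimnames(trueProt) <- dimnames(protObs)

    # sites
    siteRange <- seq(config$sitesPerProtein[1L], config$sitesPerProtein[2L])
    nSites <- if (length(siteRange) == 1L) rep(siteRange, nP)
              else sample(siteRange, nP, replace = TRUE)
    protIdx <- rep(seq_len(nP), nSites)
    m <- length(protIdx)
    pepId <- sprintf("pep%05d", seq_len(m))
    pos <- unlist(lapply(nSites, function(k) sample(5:500, k)),
                  use.names = FALSE)
    sites <- PtmSiteTable(pepId, as.list(acc[protIdx]), as.list(pos),
                          residue = "K", modification = "GG")

    pepBase <- baseline[protIdx] +
        stats::rnorm(m, config$peptideOffsetMean, config$peptideOffsetSd)
    truePep <- outer(pepBase, rep(0, nS), `+`)
    truePep[, isAlt] <- truePep[, isAlt] + protEffect[protIdx] +
        stoDelta[protIdx]
    pepObs <- truePep + stats::rnorm(m * nS, 0, config$noiseSd)
    dimnames(pepObs) <- list(pepId, design$sample_id)

    if (config$missingRateAtLowIntensity > 0) {
        protObs[stats::runif(length(protObs)) <
                    .missingProb(trueProt, config)] <- NA
        truePepM <- truePep
        dimnames(truePepM) <- dimnames(pepObs)
        pepObs[stats::runif(length(pepObs)) <
                   .missingProb(truePepM, config)] <- NA
    }

    truth <- DataFrame(
        peptide_id = pepId,
        accession = acc[protIdx],
        label = label[protIdx],
        stoichDelta = stoDelta[protIdx],
        proteinEffect = protEffect[protIdx],
        trueCorrectedLfc = stoDelta[protIdx],
        trueRawLfc = protEffect[protIdx] + stoDelta[protIdx])
    proteinTruth <- DataFrame(accession = acc, label = label,
                              proteinEffect = protEffect,
                              baselineLog2 = baseline)

    list(proteins = QuantExperiment(2^protObs, design, ref, "linear"),
         peptides = QuantExperiment(2^pepObs, design, ref, "linear"),
         sites = sites, truth = truth, proteinTruth = proteinTruth)
}

#' Simulate an ortholog of a protein sequence
#'
#' Applies per-residue substitutions and indels while tracking the true
#' source-to-target position correspondence and the fate of every source
#' lysine (\code{conserved}, \code{substituted} or \code{deleted}). Lysines
#' are lost with their own rate (substituted to arginine); other residues are
#' substituted to a random non-lysine residue.
#'
#' @param sequence amino-acid string (length >= 10).
#' @param substitutionRate,indelRate per-residue probabilities.
#' @param lysineLossRate probability a lysine is substituted.
#' @param seed optional RNG seed.
#' @return list: \code{sequence} (mutated string), \code{positionMap}
#'   (integer vector: target position per source position, \code{NA} if
#'   deleted), \code{lysineFates} (data.frame \code{position}, \code{fate}).
#' @export
simulateOrthologPair <- function(sequence, substitutionRate = 0.05,
                                 indelRate = 0.01, lysineLossRate = 0,
                                 seed = NULL) {
    if (nchar(sequence) < 10L)
        stop("sequence must have at least 10 residues", call. = FALSE)
    rates <- c(substitutionRate, indelRate, lysineLossRate)
    if (any(rates < 0) || any(rates > 1))
        stop("rates must lie in [0,1]", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    src <- strsplit(toupper(sequence), "")[[1L]]
    out <- character(0)
    posMap <- rep(NA_integer_, length(src))
    fates <- character(0); fatePos <- integer(0)
    nonK <- setdiff(.AA20, "K")
    for (i in seq_along(src)) {
        if (stats::runif(1) < indelRate / 2)  # insertion before i
            out <- c(out, sample(nonK, 1L))
        isK <- src[i] == "K"
        if (stats::runif(1) < indelRate / 2) {  # deletion
            if (isK) { fates <- c(fates, "deleted"); fatePos <- c(fatePos, i) }
            next
        }
        res <- src[i]
        if (isK) {
            if (stats::runif(1) < lysineLossRate) {
                res <- "R"
                fates <- c(fates, "substituted")
            } else fates <- c(fates, "conserved")
            fatePos <- c(fatePos, i)
        } else if (stats::runif(1) < substitutionRate) {
            res <- sample(setdiff(nonK, src[i]), 1L)
        }
        out <- c(out, res)
        posMap[i] <- length(out)
    }
    if (stats::runif(1) < indelRate / 2)
        out <- c(out, sample(nonK, 1L))
    list(sequence = paste(out, collapse = ""),
         positionMap = posMap,
         lysineFates = data.frame(position = fatePos, fate = fates,
                                  stringsAsFactors = FALSE))
}

#' Simulate a PRM light/heavy intensity table
#'
#' Heavy intensity is a peptide-and-sample-specific response constant times
#' the spiked amount; light intensity is the same constant times the true
#' endogenous amount. Both carry independent log-normal noise with
#' coefficient of variation \code{cv}, so at \code{cv = 0} the light/heavy
#' ratio recovers true/spike exactly.
#'
#' @param panel data.frame with columns \code{peptide}, \code{target},
#'   \code{spike_fmol_per_ug}.
#' @param trueAmounts numeric matrix of true endogenous amounts (fmol/ug),
#'   rows = targets, columns = samples.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param seed optional RNG seed.
#' @return data.frame \code{sample_id}, \code{peptide}, \code{light},
#'   \code{heavy}.
#' @export
simulatePrm <- function(panel, trueAmounts, cv = 0.05, seed = NULL) {
    stopifnot(all(c("peptide", "target", "spike_fmol_per_ug") %in%
                      colnames(panel)))
    if (cv < 0) stop("cv must be >= 0", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    miss <- setdiff(panel$target, rownames(trueAmounts))
    if (length(miss))
        stop("trueAmounts lacks target(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    sdlog <- sqrt(log1p(cv^2))
    samples <- colnames(trueAmounts)
    grid <- expand.grid(p = seq_len(nrow(panel)), s = seq_along(samples))
    const <- stats::rlnorm(nrow(grid), meanlog = log(1e5), sdlog = 1)
    truth <- trueAmounts[cbind(match(panel$target[grid$p],
                                     rownames(trueAmounts)), grid$s)]
    noiseL <- if (cv > 0) stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog) else 1
    noiseH <- if (cv > 0) stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog) else 1
    data.frame(
        sample_id = samples[grid$s],
        peptide = panel$peptide[grid$p],
        light = const * truth * noiseL,
        heavy = const * panel$spike_fmol_per_ug[grid$p] * noiseH,
        stringsAsFactors = FALSE)
}

#' Simulate gene sets with one planted enriched set
#'
#' Builds disjoint gene sets over a synthetic universe; every gene's score is
#' standard normal, and the members of the planted set are shifted by
#' \code{plantedEffect} score units.
#'
#' @param nSets number of sets.
#' @param setSize members per set.
#' @param plantedEffect score shift applied to the first set's members.
#' @param seed optional RNG seed.
#' @return list: \code{sets} (named list), \code{scores} (named numeric),
#'   \code{plantedSet} (name of the shifted set).
#' @export
simulateGenesets <- function(nSets = 50L, setSize = 20L, plantedEffect = 0,
                             seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    genes <- sprintf("g%05d", seq_len(nSets * setSize))
    sets <- split(genes, rep(seq_len(nSets), each = setSize))
    names(sets) <- sprintf("set%03d", seq_len(nSets))
    scores <- stats::setNames(stats::rnorm(length(genes)), genes)
    scores[sets[[1L]]] <- scores[sets[[1L]]] + plantedEffect
    list(sets = sets, scores = scores, plantedSet = names(sets)[1L])
}

#' Simulate a matched pair of contrasts (aging vs dietary intervention)
#'
#' Generates two log2-scale QuantExperiments over the same sites with planted
#' joint response classes: \code{exacerbated} (same-sign delta in both),
#' \code{reverted_down} (age +delta, intervention -delta),
#' \code{reverted_up} (age -delta, intervention +delta) and \code{null}.
#'
#' @param nSites number of sites.
#' @param fracExacerbated,fracRevertedDown,fracRevertedUp,fracNull class
#'   proportions (sum to 1).
#' @param delta planted log2 effect magnitude.
#' @param noiseSd log2 noise s.d.
#' @param nPerGroup replicates per condition.
#' @param seed optional RNG seed.
#' @return list: \code{age}, \code{diet} (log2 QuantExperiments), \code{truth}
#'   (\code{DataFrame} with per-site class and deltas).
#' @export
simulateInterventionPair <- function(nSites = 500L, fracExacerbated = 0.15,
                                     fracRevertedDown = 0.15,
                                     fracRevertedUp = 0.05, fracNull = 0.65,
                                     delta = 1, noiseSd = 0.25,
                                     nPerGroup = 5L, seed = NULL) {
    frac <- c(fracExacerbated, fracRevertedDown, fracRevertedUp, fracNull)
    if (any(frac < 0) || abs(sum(frac) - 1) > 1e-9)
        stop("class fractions must be >= 0 and sum to 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    counts <- .apportion(nSites, frac)
    label <- sample(rep(c("exacerbated", "reverted_down", "reverted_up",
                          "null"), counts))
    s <- sample(c(-1, 1), nSites, replace = TRUE)
    ageDelta <- ifelse(label == "exacerbated", s * delta,
                ifelse(label == "reverted_down", delta,
                ifelse(label == "reverted_up", -delta, 0)))
    dietDelta <- ifelse(label == "exacerbated", s * delta,
                 ifelse(label == "reverted_down", -delta,
                 ifelse(label == "reverted_up", delta, 0)))
    base <- stats::rnorm(nSites, 20, 2)
    sid <- sprintf("site%05d", seq_len(nSites))

    mk <- function(d, ref, alt) {
        n <- nPerGroup
        design <- data.frame(
            sample_id = c(sprintf("%s_%d", ref, 1:n),
                          sprintf("%s_%d", alt, 1:n)),
            condition = rep(c(ref, alt), each = n))
        x <- outer(base, rep(0, 2 * n), `+`)
        x[, design$condition == alt] <-
            x[, design$condition == alt] + d
        x <- x + stats::rnorm(length(x), 0, noiseSd)
        dimnames(x) <- list(sid, design$sample_id)
        QuantExperiment(x, design, ref, "log2")
    }
    list(age = mk(ageDelta, "young", "old"),
         diet = mk(dietDelta, "AL", "RF"),
         truth = DataFrame(site = sid, label = label,
                           ageDelta = ageDelta, dietDelta = dietDelta))
}
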