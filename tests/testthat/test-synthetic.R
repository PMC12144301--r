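test_that("noise-free construction plants exactly the configured effects", {
    # all sites stoichiometry-driven, no noise, no missingness
    cfg <- simConfig(nProteins = 20, sitesPerProtein = c(1, 1),
                     nPerGroup = 3, noiseSd = 0, baselineSd = 0,
                     peptideOffsetSd = 0, fracNull = 0,
                     fracProteinDriven = 0, fracStoichDriven = 1,
                     stoichEffect = 1, seed = 101)
    sim <- simulateQuantExperiment(cfg)
    lp <- log2(quantValues(sim$peptides))
    pp <- log2(quantValues(sim$proteins))
    old <- sampleConditions(sim$peptides) == "old"
    pepLfc <- rowMeans(lp[, old]) - rowMeans(lp[, !old])
    protLfc <- rowMeans(pp[, old]) - rowMeans(pp[, !old])
    expect_equal(unname(pepLfc), sim$truth$stoichDelta, tolerance = 1e-12)
    expect_equal(unname(protLfc), rep(0, 20), tolerance = 1e-12)

    # all-null: peptide fold change equals protein fold change exactly
    cfgN <- simConfig(nProteins = 20, sitesPerProtein = c(1, 1),
                      nPerGroup = 3, noiseSd = 0, fracNull = 1,
                      fracProteinDriven = 0, fracStoichDriven = 0,
                      seed = 102)
    simN <- simulateQuantExperiment(cfgN)
    lpN <- log2(quantValues(simN$peptides))
    ppN <- log2(quantValues(simN$proteins))
    pepLfcN <- rowMeans(lpN[, old]) - rowMeans(lpN[, !old])
    protLfcN <- rowMeans(ppN[, old]) - rowMeans(ppN[, !old])
    expect_equal(unname(pepLfcN), unname(protLfcN), tolerance = 1e-12)
})

test_that("identical config and seed give byte-identical outputs", {
    cfg <- simConfig(nProteins = 30, missingRateAtLowIntensity = 0.3,
                     missingMidpoint = 19, seed = 77)
    f1 <- tempfile(); f2 <- tempfile()
    writeQuantTable(simulateQuantExperiment(cfg)$peptides, f1)
    writeQuantTable(simulateQuantExperiment(cfg)$peptides, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("config validation rejects inconsistent fractions and sizes", {
    expect_error(simConfig(fracNull = 0.5, fracProteinDriven = 0.5,
                           fracStoichDriven = 0.5), "sum to 1")
    expect_error(simConfig(nPerGroup = 1), "nPerGroup")
    expect_error(simConfig(noiseSd = -1), "deviations")
})

test_that("under the global null, observed fold changes are calibrated", {
    cfg <- simConfig(nProteins = 1250, sitesPerProtein = c(2, 2),
                     nPerGroup = 5, fracNull = 1, fracProteinDriven = 0,
                     fracStoichDriven = 0, noiseSd = 0.25,
                     peptideOffsetSd = 0.5, seed = 404)
    sim <- simulateQuantExperiment(cfg)
    lp <- log2(quantValues(sim$peptides))
    old <- sampleConditions(sim$peptides) == "old"
    lfc <- rowMeans(lp[, old]) - rowMeans(lp[, !old])
    expect_gt(length(lfc), 2000)
    theoSd <- 0.25 * sqrt(2 / 5)
    expect_lt(abs(mean(lfc)), 3 * theoSd / sqrt(length(lfc)))
    expect_lt(abs(sd(lfc) / theoSd - 1), 0.05)
})

test_that("ortholog simulation tracks position maps and lysine fates", {
    seqv <- "MKTAYKLLVNKAEDQRSTWY"
    id <- simulateOrthologPair(seqv, 0, 0, 0, seed = 1)
    expect_identical(id$sequence, seqv)
    expect_identical(id$positionMap, seq_len(nchar(seqv)))
    expect_true(all(id$lysineFates$fate == "conserved"))

    lost <- simulateOrthologPair(seqv, 0, 0, lysineLossRate = 1, seed = 1)
    expect_true(all(lost$lysineFates$fate == "substituted"))
    expect_false(grepl("K", lost$sequence))

    # with indels only, the alignment-recovered correspondence agrees with
    # the generator's position map at nearly all surviving positions
    set.seed(42)
    src <- randomAASeq(200)
    mut <- simulateOrthologPair(src, 0, indelRate = 0.02, seed = 9)
    hit <- localAlign(src, mut$sequence)
    surviving <- which(!is.na(mut$positionMap))
    agree <- vapply(surviving, function(i) {
        proj <- projectSite(i, hit)
        !is.na(proj) && proj == mut$positionMap[i]
    }, logical(1))
    expect_gt(mean(agree), 0.95)
})

test_that("PRM simulation reproduces amounts through the light/heavy ratio", {
    panel <- data.frame(peptide = c("pepK48", "pepTOT"),
                        target = c("K48", "total_ub"),
                        spike_fmol_per_ug = c(20, 20))
    amounts <- matrix(c(2, 100, 4, 100), 2, 2,
                      dimnames = list(c("K48", "total_ub"), c("s1", "s2")))
    prm <- simulatePrm(panel, amounts, cv = 0, seed = 1)
    got <- quantifyEndogenous(prm$light, prm$heavy, 20)
    expect_equal(got, amounts[cbind(match(ifelse(prm$peptide == "pepK48",
                                                 "K48", "total_ub"),
                                          rownames(amounts)),
                                    match(prm$sample_id,
                                          colnames(amounts)))],
                 tolerance = 1e-12)

    # doubling true amounts doubles the ratio
    prm2 <- simulatePrm(panel, amounts * 2, cv = 0, seed = 1)
    expect_equal(prm2$light / prm2$heavy, 2 * prm$light / prm$heavy,
                 tolerance = 1e-12)

    # Monte-Carlo recovery at cv = 0.05, n = 3 samples
    am <- matrix(5, 1, 3, dimnames = list("K48", c("a", "b", "c")))
    pan <- panel[1, ]
    prm3 <- simulatePrm(pan, am, cv = 0.05, seed = 21)
    rec <- quantifyEndogenous(prm3$light, prm3$heavy, 20)
    expect_lt(abs(mean(rec) - 5) / 5, 3 * 0.05)
})

test_that("gene-set simulation plants a recoverable enrichment", {
    g0 <- simulateGenesets(20, 15, plantedEffect = 0, seed = 5)
    g3 <- simulateGenesets(20, 15, plantedEffect = 3, seed = 5)
    meanScores <- function(g) vapply(g$sets, function(s)
        mean(g$scores[s]), numeric(1))
    expect_identical(names(which.max(meanScores(g3))), g3$plantedSet)
    # determinism
    g3b <- simulateGenesets(20, 15, plantedEffect = 3, seed = 5)
    expect_identical(g3$scores, g3b$scores)
    # with no effect the planted set is unremarkable (not automatically top)
    ranks <- rank(-meanScores(g0))
    expect_gt(ranks[[g0$plantedSet]], 1)
})

test_that("intervention pairs plant the configured joint responses", {
    pair <- simulateInterventionPair(nSites = 200, fracExacerbated = 0.25,
                                     fracRevertedDown = 0.25,
                                     fracRevertedUp = 0.1, fracNull = 0.4,
                                     delta = 1, noiseSd = 0, nPerGroup = 3,
                                     seed = 8)
    expect_identical(as.integer(table(pair$truth$label)[
        c("exacerbated", "null", "reverted_down", "reverted_up")]),
        c(50L, 80L, 50L, 20L))
    la <- quantValues(pair$age)
    oldCols <- sampleConditions(pair$age) == "old"
    lfcAge <- rowMeans(la[, oldCols]) - rowMeans(la[, !oldCols])
    expect_equal(unname(lfcAge), pair$truth$ageDelta, tolerance = 1e-12)
})
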