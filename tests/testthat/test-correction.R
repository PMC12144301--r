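test_that("correction factors are per-condition median ratios", {
    qe <- makeQE1(list(young = c(100, 120, 110), old = c(220, 240, 230)),
                  featureId = "P1")
    cf <- computeCorrectionFactors(qe)
    expect_equal(correctionFactors(cf)["P1", "old"], 230 / 110,
                 tolerance = 1e-12)
    expect_equal(correctionFactors(cf)["P1", "young"], 1, tolerance = 1e-15)
    expect_false(uncorrectable(cf)[["P1"]])

    same <- makeQE1(list(young = c(50, 60, 70), old = c(70, 60, 50)),
                    featureId = "P2")
    cfSame <- computeCorrectionFactors(same)
    expect_equal(unname(correctionFactors(cfSame)["P2", ]), c(1, 1))

    missing <- makeQE1(list(young = c(NA, NA, NA), old = c(10, 20, 30)),
                       featureId = "P3")
    cfMiss <- computeCorrectionFactors(missing)
    expect_true(uncorrectable(cfMiss)[["P3"]])
    expect_true(all(is.na(correctionFactors(cfMiss)["P3", ])))
})

test_that("multi-protein peptides use the summed-quantity factor", {
    design <- makeDesign(3)
    m <- rbind(P1 = c(100, 100, 100, 100, 100, 100),
               P2 = c(50, 50, 50, 150, 150, 150))
    colnames(m) <- design$sample_id
    prot <- QuantExperiment(m, design, "young", "linear")
    f <- resolveMultiproteinFactor(c("P1", "P2"), prot)
    expect_equal(f[["old"]], 250 / 150, tolerance = 1e-12)  # 5/3
    expect_equal(f[["young"]], 1)

    # both unchanged
    m2 <- rbind(P1 = rep(100, 6), P2 = rep(50, 6))
    colnames(m2) <- design$sample_id
    f2 <- resolveMultiproteinFactor(c("P1", "P2"),
                                    QuantExperiment(m2, design, "young",
                                                    "linear"))
    expect_equal(as.numeric(f2), c(1, 1), tolerance = 1e-15)

    # single-accession site routed through the multi-protein rule matches
    # the per-protein factor table
    f1 <- resolveMultiproteinFactor("P2", prot)
    cf <- computeCorrectionFactors(prot)
    expect_equal(as.numeric(f1), unname(correctionFactors(cf)["P2", ]),
                 tolerance = 1e-15)
})

test_that("applying correction divides by the condition factor and log2s", {
    design <- makeDesign(3)
    prot <- rbind(P1 = c(110, 100, 120, 200, 220, 240))
    colnames(prot) <- design$sample_id
    proteins <- QuantExperiment(prot, design, "young", "linear")
    pep <- rbind(pepA = c(400, 400, 400, 400, 400, 400))
    colnames(pep) <- design$sample_id
    peptides <- QuantExperiment(pep, design, "young", "linear")
    sites <- PtmSiteTable("pepA", list("P1"), list(10L))
    factors <- siteCorrectionFactors(sites, proteins)
    expect_equal(correctionFactors(factors)["P1", "old"], 2, tolerance = 1e-12)
    corr <- applyCorrection(peptides, sites, factors)
    expect_identical(quantScale(corr), "log2")
    old <- sampleConditions(corr) == "old"
    expect_equal(unname(quantValues(corr)["pepA", old]),
                 rep(log2(200), 3), tolerance = 1e-12)
    expect_equal(unname(quantValues(corr)["pepA", !old]),
                 rep(log2(400), 3), tolerance = 1e-12)
    expect_true(rowData(corr)$corrected)
})

test_that("unit factors and uncorrectable sites pass quantities through", {
    design <- makeDesign(2)
    prot <- rbind(P1 = rep(100, 4))
    colnames(prot) <- design$sample_id
    proteins <- QuantExperiment(prot, design, "young", "linear")
    pep <- rbind(pepA = c(10, 20, 30, NA), pepB = c(5, 6, 7, 8))
    colnames(pep) <- design$sample_id
    peptides <- QuantExperiment(pep, design, "young", "linear")
    sites <- PtmSiteTable(c("pepA", "pepB"), list("P1", "PX"),
                          list(10L, 20L))
    factors <- siteCorrectionFactors(sites, proteins)
    expect_true(uncorrectable(factors)[["PX"]])
    corr <- applyCorrection(peptides, sites, factors)
    expect_equal(quantValues(corr), log2(pep), tolerance = 1e-12)
    expect_identical(unname(rowData(corr)$corrected), c(TRUE, FALSE))
    expect_true(is.na(quantValues(corr)["pepA", 4]))
})

test_that("corrected median differences equal raw differences minus the protein ratio", {
    set.seed(31)
    design <- makeDesign(4)
    prot <- matrix(2^rnorm(8, 15, 1), 1, 8,
                   dimnames = list("P1", design$sample_id))
    proteins <- QuantExperiment(prot, design, "young", "linear")
    pep <- matrix(2^rnorm(8, 12, 1), 1, 8,
                  dimnames = list("pepA", design$sample_id))
    peptides <- QuantExperiment(pep, design, "young", "linear")
    sites <- PtmSiteTable("pepA", list("P1"), list(3L))
    corr <- applyCorrection(peptides, sites,
                            siteCorrectionFactors(sites, proteins))
    old <- design$condition == "old"
    rawDiff <- median(log2(pep[1, old])) - median(log2(pep[1, !old]))
    corrDiff <- median(quantValues(corr)[1, old]) -
        median(quantValues(corr)[1, !old])
    protRatio <- median(prot[1, old]) / median(prot[1, !old])
    expect_equal(corrDiff, rawDiff - log2(protRatio), tolerance = 1e-12)
})

test_that("correction is equivariant to condition-wide rescaling", {
    set.seed(32)
    design <- makeDesign(3)
    prot <- matrix(2^rnorm(6, 15, 1), 2, 6,
                   dimnames = list(c("P1", "P2"), design$sample_id))
    pep <- matrix(2^rnorm(6, 12, 1), 2, 6,
                  dimnames = list(c("a", "b"), design$sample_id))
    sites <- PtmSiteTable(c("a", "b"), list("P1", "P2"), list(5L, 9L))
    run <- function(pm, qm) {
        proteins <- QuantExperiment(pm, design, "young", "linear")
        peptides <- QuantExperiment(qm, design, "young", "linear")
        corr <- applyCorrection(peptides, sites,
                                siteCorrectionFactors(sites, proteins))
        old <- design$condition == "old"
        apply(quantValues(corr), 1, function(v)
            median(v[old]) - median(v[!old]))
    }
    base <- run(prot, pep)
    scaleOld <- ifelse(design$condition == "old", 7, 1)
    scaled <- run(sweep(prot, 2, scaleOld, `*`),
                  sweep(pep, 2, scaleOld, `*`))
    expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("noise-free planted effects survive or vanish under correction", {
    cfg <- simConfig(nProteins = 60, sitesPerProtein = c(1, 2),
                     nPerGroup = 3, noiseSd = 0, fracNull = 0.3,
                     fracProteinDriven = 0.4, fracStoichDriven = 0.3,
                     proteinEffect = 1.2, stoichEffect = 0.9, seed = 55)
    sim <- simulateQuantExperiment(cfg)
    corr <- applyCorrection(sim$peptides, sim$sites,
                            siteCorrectionFactors(sim$sites, sim$proteins))
    old <- sampleConditions(corr) == "old"
    lfc <- rowMeans(quantValues(corr)[, old]) -
        rowMeans(quantValues(corr)[, !old])
    expect_equal(unname(lfc), sim$truth$stoichDelta, tolerance = 1e-10)
})
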