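test_that("local alignment reproduces the hand-worked gapped example", {
    hit <- localAlign("MKTAYKLL", "MKTYKLL")
    expect_equal(alignmentScore(hit), 23)
    expect_equal(alignmentScore(hit), swOracleScore("MKTAYKLL", "MKTYKLL"))
    cc <- alignmentColumns(hit)
    # single 1-residue gap in the target opposite the query A
    expect_identical(cc$tpos[cc$qpos == 4 & !is.na(cc$qpos)], NA_integer_)
    expect_identical(projectSite(6, hit), 5L)
})

test_that("self-alignment covers the full length with matched columns", {
    s <- "MKTAYKLLVNQERST"
    hit <- localAlign(s, s)
    cc <- alignmentColumns(hit)
    expect_equal(nrow(cc), nchar(s))
    expect_identical(cc$qpos, cc$tpos)
    expect_identical(projectSite(12, hit), 12L)
})

test_that("disjoint alphabets give an empty zero-score alignment", {
    hit <- localAlign(strrep("A", 12), strrep("W", 12))
    expect_equal(alignmentScore(hit), 0)
    expect_equal(nrow(alignmentColumns(hit)), 0)
    expect_identical(projectSite(3, hit), NA_integer_)
    expect_error(localAlign("", "MKL"), "empty")
})

test_that("alignment scores equal the brute-force DP oracle", {
    set.seed(81)
    for (i in 1:20) {
        q <- randomAASeq(sample(8:30, 1))
        t <- randomAASeq(sample(8:30, 1))
        expect_equal(localAlign(q, t)@score, swOracleScore(q, t),
                     tolerance = 1e-10)
    }
})

test_that("hit ranking orders by score with deterministic ties", {
    query <- "MKTAYKLLVNQERSTWYHID"
    proteome <- c(EXACT = query,
                  PART = substr(query, 3, 14),
                  NOPE = strrep("G", 15))
    hits <- rankHits(query, proteome, k = 10)
    expect_identical(hits[[1]]@target, "EXACT")
    expect_true(length(hits) <= 3)
    # k larger than the proteome returns everything scoring > 0
    expect_identical(vapply(rankHits(query, proteome, k = 99),
                            function(h) h@target, ""),
                     vapply(hits, function(h) h@target, ""))
    one <- rankHits(query, proteome["PART"], k = 10)
    expect_length(one, 1)
})

test_that("projection through an alignment is injective over matched columns", {
    set.seed(82)
    for (i in 1:10) {
        q <- randomAASeq(60)
        t <- simulateOrthologPair(q, 0.1, 0.05, seed = i)$sequence
        cc <- alignmentColumns(localAlign(q, t))
        mapped <- cc$tpos[!is.na(cc$qpos) & !is.na(cc$tpos)]
        expect_false(anyDuplicated(mapped) > 0)
    }
})

test_that("conservation needs a lysine in any of the top hits", {
    # T1 replaces the query lysine with arginine; T2 keeps it. Scores make
    # T1 the better hit, so the supporting hit has rank 2.
    query <- "MAAAKLLVNQERSTWYHIDC"
    t1 <- sub("K", "R", query)                  # rank 1 (longer exact tail)
    t2 <- substr(query, 1, 12)                  # keeps K at 5, lower score
    proteome <- c(T1 = t1, T2 = t2)
    hits <- rankHits(query, proteome, k = 10)
    expect_identical(hits[[1]]@target, "T1")
    call <- callConservation("Q", 5L, hits, proteome)
    expect_true(call$conserved)
    expect_identical(call$target_acc, "T2")
    expect_identical(call$rank, 2L)

    none <- callConservation("Q", 5L, list(), proteome)
    expect_false(none$conserved)
    expect_true(is.na(none$target_pos))

    ident <- callConservation("Q", 5L, rankHits(query, c(SELF = query)),
                              c(SELF = query))
    expect_true(ident$conserved)
    expect_identical(ident$target_pos, 5L)
    expect_identical(ident$rank, 1L)
})

test_that("matched modified sites require the same projected position", {
    proj <- data.frame(query_acc = "QP", query_pos = c(12L, 30L),
                       target_acc = "P1", target_pos = c(12L, 31L),
                       conserved = c(TRUE, TRUE), rank = 1L,
                       peptide_id = c("qpep1", "qpep2"))
    targetSites <- PtmSiteTable(c("tpep1", "tpep2"), list("P1", "P1"),
                                list(12L, 13L))
    pairs <- matchModifiedSites(proj, targetSites)
    expect_equal(nrow(pairs), 1)
    expect_identical(pairs$peptide_id, "qpep1")
    expect_identical(pairs$target_peptide_id, "tpep1")
})

test_that("an identity proteome conserves every modified lysine in place", {
    set.seed(83)
    seqs <- setNames(
        vapply(1:5, function(i)
            randomAASeq(80, prob = c(rep(1, 8), 4, rep(1, 11))), ""),
        sprintf("P%d", 1:5))
    sites <- do.call(rbind, lapply(names(seqs), function(acc) {
        kpos <- which(strsplit(seqs[[acc]], "")[[1]] == "K")
        data.frame(acc = acc, pos = kpos)
    }))
    st <- PtmSiteTable(sprintf("pep%03d", seq_len(nrow(sites))),
                       as.list(sites$acc), as.list(sites$pos))
    proj <- liftoverSites(st, seqs, seqs, k = 10)
    expect_true(all(proj$conserved))
    expect_identical(proj$target_pos, proj$query_pos)
    expect_identical(proj$target_acc, proj$query_acc)
})

test_that("conserved fraction degrades as lysine loss increases", {
    set.seed(84)
    base <- randomAASeq(150, prob = c(rep(1, 8), 5, rep(1, 11)))
    kpos <- which(strsplit(base, "")[[1]] == "K")
    st <- PtmSiteTable(sprintf("pep%02d", seq_along(kpos)),
                       as.list(rep("Q1", length(kpos))), as.list(kpos))
    fracAt <- function(rate) {
        mean(vapply(1:10, function(s) {
            mut <- simulateOrthologPair(base, 0.02, 0.005,
                                        lysineLossRate = rate, seed = s)
            proj <- liftoverSites(st, c(Q1 = base),
                                  c(T1 = mut$sequence), k = 10)
            mean(proj$conserved)
        }, numeric(1)))
    }
    fr <- vapply(c(0, 0.3, 0.8), fracAt, numeric(1))
    expect_true(all(diff(fr) <= 0))
    expect_gt(fr[1], 0.9)
    expect_lt(fr[3], 0.5)
})

test_that("planted lysine substitutions are exactly the non-conserved sites", {
    set.seed(85)
    base <- randomAASeq(120, prob = c(rep(1, 8), 4, rep(1, 11)))
    kpos <- which(strsplit(base, "")[[1]] == "K")
    mut <- simulateOrthologPair(base, 0, 0, lysineLossRate = 0.5, seed = 7)
    st <- PtmSiteTable(sprintf("pep%02d", seq_along(kpos)),
                       as.list(rep("Q1", length(kpos))), as.list(kpos))
    proj <- liftoverSites(st, c(Q1 = base), c(T1 = mut$sequence), k = 10)
    fates <- mut$lysineFates$fate[match(proj$query_pos,
                                        mut$lysineFates$position)]
    expect_identical(proj$conserved, fates == "conserved")
})
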