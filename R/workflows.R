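# Workflow orchestration: the aging PTM analysis (correction + differential
# statistics + protein-explained vs stoichiometry accounting), the
# cross-species conservation workflow, and the dietary-intervention
# comparison. Workflows never mutate their inputs; tables are written (with
# provenance headers) only under the configured output directory.

.writeStage <- function(df, outputDir, name, stage, params) {
    if (is.null(outputDir)) return(invisible(NULL))
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    .writeTsv(as.data.frame(df), file.path(outputDir, name),
              c(sprintf("# stage=%s", stage),
                sprintf("# params=%s", .paramHash(params))))
}

#' Aging PTM workflow
#'
#' Corrects modified-peptide quantities for protein abundance, tests raw
#' peptide, corrected peptide and protein contrasts, and classifies each
#' significant PTM site as protein-explained (its protein's BH-adjusted p
#' below \code{proteinAdjPThreshold}) or stoichiometry-only. PTM-level tests
#' use Storey q-values, protein-level tests BH adjustment — the two
#' multiplicity conventions conventionally used for these data types. When
#' every feature has zero within-group variance (a noise-free scenario) the
#' moderated prior is degenerate and the plain test is used instead.
#'
#' @param proteins,peptides linear-scale \linkS4class{QuantExperiment}s.
#' @param sites the matching \linkS4class{PtmSiteTable}.
#' @param qThreshold,lfcThreshold PTM significance thresholds (Q < 0.05,
#'   |log2 FC| > 0.58 by default).
#' @param proteinAdjPThreshold protein-level significance threshold.
#' @param method test for the PTM tables (\code{"moderated"} or
#'   \code{"plain"}).
#' @param outputDir optional directory for provenance-stamped TSV outputs.
#' @return list: \code{factors}, \code{corrected}, \code{rawResults},
#'   \code{correctedResults}, \code{proteinResults}, \code{classification}
#'   (per significant raw site), \code{summary} (counts and fractions).
#' @export
runAgingWorkflow <- function(proteins, peptides, sites,
                             qThreshold = 0.05, lfcThreshold = 0.58,
                             proteinAdjPThreshold = 0.05,
                             method = c("moderated", "plain"),
                             outputDir = NULL) {
    method <- match.arg(method)
    params <- list(qThreshold = qThreshold, lfcThreshold = lfcThreshold,
                   proteinAdjPThreshold = proteinAdjPThreshold,
                   method = method)
    factors <- siteCorrectionFactors(sites, proteins)
    corrected <- applyCorrection(peptides, sites, factors)

    pickMethod <- function(x, m) {
        if (m == "plain") return("plain")
        g <- .groupSummaries(quantValues(x), sampleConditions(x),
                             referenceCondition(x))
        dg <- g$n1 + g$n2 - 2
        s2 <- ((g$n1 - 1) * g$v1 + (g$n2 - 1) * g$v2) / dg
        ok <- is.finite(s2)
        if (!any(ok) || all(s2[ok] == 0)) "plain" else "moderated"
    }
    rawLog2 <- asLog2(peptides)
    rawRes <- diffTest(rawLog2, method = pickMethod(rawLog2, method),
                       qThreshold = qThreshold,
                       lfcThreshold = lfcThreshold, on = "q_value")
    corrRes <- diffTest(corrected, method = pickMethod(corrected, method),
                        qThreshold = qThreshold,
                        lfcThreshold = lfcThreshold, on = "q_value")
    protLog2 <- asLog2(proteins)
    protRes <- diffTest(protLog2, method = pickMethod(protLog2, method),
                        qThreshold = qThreshold,
                        lfcThreshold = lfcThreshold, on = "adj_p")

    # protein-level significance per site (multi-protein groups: the group
    # is protein-explained if any member protein changes significantly)
    protSig <- stats::setNames(protRes$significant, protRes$feature_id)
    siteAccs <- stats::setNames(as.list(sites$accessions), sites$peptide_id)
    sigIdx <- which(!is.na(rawRes$significant) & rawRes$significant)
    classification <- S4Vectors::DataFrame(
        feature_id = rawRes$feature_id[sigIdx],
        log2fc_raw = rawRes$log2fc[sigIdx],
        q_raw = rawRes$q_value[sigIdx])
    explained <- vapply(classification$feature_id, function(fid) {
        any(unlist(protSig[siteAccs[[fid]]]), na.rm = TRUE)
    }, logical(1), USE.NAMES = FALSE)
    classification$class <- ifelse(explained, "protein_explained",
                                   "stoichiometry_only")

    nSig <- nrow(classification)
    summary <- list(
        n_sites = nrow(rawRes),
        n_significant_raw = nSig,
        n_significant_corrected =
            sum(corrRes$significant, na.rm = TRUE),
        n_protein_explained = sum(explained),
        n_stoichiometry_only = nSig - sum(explained),
        frac_stoichiometry_only = if (nSig) (nSig - sum(explained)) / nSig
                                  else NA_real_,
        n_uncorrectable = sum(uncorrectable(factors)))

    .writeStage(data.frame(group = rownames(correctionFactors(factors)),
                           correctionFactors(factors),
                           uncorrectable = uncorrectable(factors),
                           check.names = FALSE),
                outputDir, "correction_factors.tsv", "correct", params)
    .writeStage(cbind(feature_id = rownames(corrected),
                      as.data.frame(quantValues(corrected))),
                outputDir, "corrected_peptides.tsv", "correct", params)
    .writeStage(rawRes, outputDir, "raw_site_results.tsv", "difftest", params)
    .writeStage(corrRes, outputDir, "corrected_site_results.tsv", "difftest",
                params)
    .writeStage(protRes, outputDir, "protein_results.tsv", "difftest", params)
    .writeStage(classification, outputDir, "site_classification.tsv",
                "classify", params)
    if (!is.null(outputDir))
        jsonlite::write_json(summary,
                             file.path(outputDir, "aging_summary.json"),
                             auto_unbox = TRUE, digits = NA)
    list(factors = factors, corrected = corrected, rawResults = rawRes,
         correctedResults = corrRes, proteinResults = protRes,
         classification = classification, summary = summary)
}

#' Cross-species conservation workflow
#'
#' Lifts the query species' modified lysines onto the target proteome,
#' keeps the sites also modified in the target dataset, joins the two
#' differential result tables on the matched pairs, and classifies each pair
#' by directional consistency.
#'
#' @param querySeqs,targetSeqs proteomes (named character or
#'   \code{AAStringSet}).
#' @param querySites,targetSites \linkS4class{PtmSiteTable}s.
#' @param queryResults,targetResults \code{DataFrame}s with
#'   \code{feature_id}, \code{log2fc}, \code{p_value} (from [diffTest()]).
#' @param k top alignment hits per query protein.
#' @param strictP,relaxedP consistency thresholds.
#' @param outputDir optional output directory.
#' @return list: \code{projections}, \code{matched}, \code{categories}
#'   (factor), \code{summary} (conserved fraction and category counts).
#' @export
runConservationWorkflow <- function(querySeqs, targetSeqs, querySites,
                                    targetSites, queryResults, targetResults,
                                    k = 10L, strictP = 0.05, relaxedP = 0.25,
                                    outputDir = NULL) {
    params <- list(k = k, strictP = strictP, relaxedP = relaxedP)
    proj <- liftoverSites(querySites, querySeqs, targetSeqs, k = k)
    matched <- matchModifiedSites(proj, targetSites)
    qr <- as.data.frame(queryResults[, c("feature_id", "log2fc", "p_value")])
    tr <- as.data.frame(targetResults[, c("feature_id", "log2fc", "p_value")])
    names(qr) <- c("peptide_id", "lfc_query", "p_query")
    names(tr) <- c("target_peptide_id", "lfc_target", "p_target")
    joined <- merge(merge(matched, qr, by = "peptide_id"), tr,
                    by = "target_peptide_id")
    cats <- classifyConsistency(joined$lfc_query, joined$p_query,
                                joined$lfc_target, joined$p_target,
                                strictP = strictP, relaxedP = relaxedP)
    joined$category <- as.character(cats)
    summary <- list(
        n_query_sites = nrow(proj),
        n_conserved = sum(proj$conserved),
        frac_conserved = if (nrow(proj)) mean(proj$conserved) else NA_real_,
        n_matched_modified = nrow(joined),
        categories = as.list(table(cats)))
    .writeStage(proj, outputDir, "site_projections.tsv", "liftover", params)
    .writeStage(joined, outputDir, "matched_site_categories.tsv",
                "consistency", params)
    if (!is.null(outputDir))
        jsonlite::write_json(summary,
                             file.path(outputDir, "conservation_summary.json"),
                             auto_unbox = TRUE, digits = NA)
    list(projections = proj, matched = matched, categories = cats,
         summary = summary)
}

#' Dietary-intervention comparison workflow
#'
#' Joins the aging and intervention differential results on shared sites,
#' summarizes the overlap of significant sites (hypergeometric test),
#' classifies the response of every site significant in at least one
#' dataset, and correlates the fold changes.
#'
#' @param ageResults,dietResults \code{DataFrame}s from [diffTest()] with
#'   \code{feature_id}, \code{log2fc}, \code{q_value}.
#' @param qThreshold significance threshold.
#' @param corScope fold-change correlation filter scope (\code{"either"} or
#'   \code{"both"}).
#' @param outputDir optional output directory.
#' @return list: \code{joined} (with per-site categories), \code{overlap},
#'   \code{correlation}, \code{summary}.
#' @export
runDietWorkflow <- function(ageResults, dietResults, qThreshold = 0.05,
                            corScope = c("either", "both"),
                            outputDir = NULL) {
    corScope <- match.arg(corScope)
    params <- list(qThreshold = qThreshold, corScope = corScope)
    ar <- as.data.frame(ageResults[, c("feature_id", "log2fc", "q_value")])
    dr <- as.data.frame(dietResults[, c("feature_id", "log2fc", "q_value")])
    names(ar) <- c("feature_id", "lfc_age", "q_age")
    names(dr) <- c("feature_id", "lfc_diet", "q_diet")
    joined <- merge(ar, dr, by = "feature_id")
    ov <- overlapSummary(joined$q_age < qThreshold,
                         joined$q_diet < qThreshold)
    cats <- classifyDietResponse(joined$lfc_age, joined$q_age,
                                 joined$lfc_diet, joined$q_diet,
                                 qThreshold = qThreshold)
    joined$category <- as.character(cats)
    corr <- fcCorrelation(joined$lfc_age, joined$lfc_diet,
                          joined$q_age, joined$q_diet,
                          threshold = qThreshold, scope = corScope)
    summary <- list(overlap = ov,
                    categories = as.list(table(cats)),
                    correlation = corr)
    .writeStage(joined, outputDir, "diet_site_categories.tsv", "diet", params)
    if (!is.null(outputDir))
        jsonlite::write_json(summary,
                             file.path(outputDir, "diet_summary.json"),
                             auto_unbox = TRUE, digits = NA)
    list(joined = joined, overlap = ov, categories = cats,
         correlation = corr, summary = summary)
}

#' Read a pipeline configuration (YAML)
#'
#' Reads input paths, the reference condition, thresholds (q, log2 FC,
#' relaxed p), the top-k alignment depth and seeds from a YAML file, filling
#' the conventional defaults for anything omitted.
#'
#' @param path YAML file.
#' @return a named list with validated threshold fields.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(q_threshold = 0.05, lfc_threshold = 0.58,
                     p_relaxed = 0.25, protein_adj_p = 0.05, top_k = 10L,
                     seed = 20250606L)
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    for (nm in c("q_threshold", "p_relaxed", "protein_adj_p"))
        if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
            stop("config error: ", nm, " must lie in (0,1)", call. = FALSE)
    if (cfg$top_k < 1L)
        stop("config error: top_k must be >= 1", call. = FALSE)
    cfg
}
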