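# Protein-abundance correction of modified-peptide quantities. For each
# condition and protein group, the median protein quantity divided by the
# reference-condition median gives a correction factor; modified-peptide
# quantities are divided by the factor of their sample's condition and log2
# transformed, removing protein-abundance changes from PTM fold changes.

# factor rule applied to one per-sample linear profile
.factorsFromProfile <- function(profile, condition, reference) {
    conds <- unique(condition)
    med <- vapply(conds, function(cd) .medianNA(profile[condition == cd]),
                  numeric(1))
    nUsed <- vapply(conds, function(cd) sum(!is.na(profile[condition == cd])),
                    integer(1))
    refMed <- med[[reference]]
    if (is.na(refMed))
        list(factors = stats::setNames(rep(NA_real_, length(conds)), conds),
             nSamples = nUsed, uncorrectable = TRUE)
    else
        list(factors = med / refMed, nSamples = nUsed, uncorrectable = FALSE)
}

#' Per-protein correction factors
#'
#' For every protein, the median quantity over each condition's samples
#' (missing values ignored) divided by the median over the reference
#' condition's samples. Proteins without any non-missing reference value are
#' flagged uncorrectable rather than silently given factor 1.
#'
#' @param proteins a linear-scale protein \linkS4class{QuantExperiment}.
#' @return a \linkS4class{CorrectionFactorTable} keyed by accession.
#' @export
computeCorrectionFactors <- function(proteins) {
    stopifnot(is(proteins, "QuantExperiment"))
    if (quantScale(proteins) != "linear")
        stop("correction factors are computed from linear-scale quantities",
             call. = FALSE)
    q <- quantValues(proteins)
    cond <- sampleConditions(proteins)
    ref <- referenceCondition(proteins)
    conds <- unique(cond)
    rows <- lapply(seq_len(nrow(q)),
                   function(i) .factorsFromProfile(q[i, ], cond, ref))
    new("CorrectionFactorTable",
        factors = matrix(unlist(lapply(rows, `[[`, "factors")),
                         nrow = nrow(q), byrow = TRUE,
                         dimnames = list(rownames(q), conds)),
        nSamples = matrix(as.integer(unlist(lapply(rows, `[[`, "nSamples"))),
                          nrow = nrow(q), byrow = TRUE,
                          dimnames = list(rownames(q), conds)),
        uncorrectable = stats::setNames(
            vapply(rows, `[[`, TRUE, "uncorrectable"), rownames(q)),
        referenceCondition = ref)
}

#' Correction factor for a multi-protein peptide
#'
#' A peptide mapped to two or more proteins is corrected with the factor of
#' the summed quantities of those proteins: per sample, quantities of the
#' proteins present are summed (a sample where all mapped proteins are
#' missing stays missing), and the per-condition median ratio rule is applied
#' to the summed profile. With a single accession this reduces to
#' [computeCorrectionFactors()] for that protein.
#'
#' @param accessions character vector of protein accessions.
#' @param proteins a linear-scale protein QuantExperiment.
#' @return named per-condition factor vector with attributes
#'   \code{"nSamples"} and \code{"uncorrectable"}.
#' @export
resolveMultiproteinFactor <- function(accessions, proteins) {
    stopifnot(is(proteins, "QuantExperiment"))
    if (quantScale(proteins) != "linear")
        stop("correction factors are computed from linear-scale quantities",
             call. = FALSE)
    q <- quantValues(proteins)
    present <- intersect(accessions, rownames(q))
    cond <- sampleConditions(proteins)
    ref <- referenceCondition(proteins)
    if (length(present) == 0L) {
        conds <- unique(cond)
        f <- stats::setNames(rep(NA_real_, length(conds)), conds)
        attr(f, "nSamples") <- stats::setNames(rep(0L, length(conds)), conds)
        attr(f, "uncorrectable") <- TRUE
        return(f)
    }
    sub <- q[present, , drop = FALSE]
    allNA <- colSums(!is.na(sub)) == 0L
    summed <- colSums(sub, na.rm = TRUE)
    summed[allNA] <- NA_real_
    r <- .factorsFromProfile(summed, cond, ref)
    f <- r$factors
    attr(f, "nSamples") <- r$nSamples
    attr(f, "uncorrectable") <- r$uncorrectable
    f
}

#' Correction factors for every site group
#'
#' Resolves one factor set per unique accession group appearing in the site
#' table (multi-accession groups via the summed-quantity rule), keyed by the
#' semicolon-joined accessions.
#'
#' @param sites a \linkS4class{PtmSiteTable}.
#' @param proteins a linear-scale protein QuantExperiment.
#' @return a \linkS4class{CorrectionFactorTable} keyed by accession group.
#' @export
siteCorrectionFactors <- function(sites, proteins) {
    keys <- vapply(sites$accessions, paste, "", collapse = ";")
    uk <- unique(keys)
    cond <- sampleConditions(proteins)
    conds <- unique(cond)
    fs <- matrix(NA_real_, length(uk), length(conds),
                 dimnames = list(uk, conds))
    ns <- matrix(0L, length(uk), length(conds), dimnames = list(uk, conds))
    unc <- stats::setNames(logical(length(uk)), uk)
    for (i in seq_along(uk)) {
        f <- resolveMultiproteinFactor(strsplit(uk[i], ";", fixed = TRUE)[[1L]],
                                       proteins)
        fs[i, names(f)] <- f
        ns[i, names(attr(f, "nSamples"))] <- attr(f, "nSamples")
        unc[i] <- attr(f, "uncorrectable")
    }
    new("CorrectionFactorTable", factors = fs, nSamples = ns,
        uncorrectable = unc,
        referenceCondition = referenceCondition(proteins))
}

#' Apply correction factors to modified-peptide quantities
#'
#' Divides each peptide quantity by its site group's factor for the sample's
#' condition and log2 transforms. Sites whose group is uncorrectable (or has
#' a missing factor for some condition) are passed through as
#' \code{log2(raw)} and flagged; missing quantities stay missing.
#'
#' @param peptides a linear-scale peptide QuantExperiment.
#' @param sites the matching \linkS4class{PtmSiteTable} (peptide_id equals
#'   the peptide feature ids).
#' @param factors a \linkS4class{CorrectionFactorTable} from
#'   [siteCorrectionFactors()].
#' @return a log2-scale QuantExperiment whose \code{rowData} records the
#'   accession \code{group} and a logical \code{corrected} flag.
#' @export
applyCorrection <- function(peptides, sites, factors) {
    stopifnot(is(peptides, "QuantExperiment"),
              is(factors, "CorrectionFactorTable"))
    if (quantScale(peptides) != "linear")
        stop("applyCorrection expects linear-scale peptide quantities",
             call. = FALSE)
    q <- quantValues(peptides)
    cond <- sampleConditions(peptides)
    keys <- stats::setNames(
        vapply(sites$accessions, paste, "", collapse = ";"),
        sites$peptide_id)
    if (!all(rownames(q) %in% names(keys)))
        stop("every peptide feature needs a site entry", call. = FALSE)
    rowKey <- keys[rownames(q)]
    fm <- correctionFactors(factors)
    if (any(fm <= 0, na.rm = TRUE))
        stop("correction factors must be > 0", call. = FALSE)
    known <- rowKey %in% rownames(fm)
    corrected <- known & !uncorrectable(factors)[ifelse(known, rowKey, NA)]
    corrected[is.na(corrected)] <- FALSE
    condFac <- fm[, cond, drop = FALSE]  # group x sample
    div <- matrix(1, nrow(q), ncol(q))
    div[corrected, ] <- condFac[rowKey[corrected], , drop = FALSE]
    # a missing factor for some condition makes the site uncorrectable
    partial <- corrected & apply(is.na(div), 1L, any)
    if (any(partial)) {
        div[partial, ] <- 1
        corrected[partial] <- FALSE
    }
    out <- log2(q / div)
    design <- data.frame(sample_id = colnames(peptides),
                         condition = cond, stringsAsFactors = FALSE)
    res <- QuantExperiment(out, design, referenceCondition(peptides),
                           scale = "log2")
    rowData(res)$group <- unname(rowKey)
    rowData(res)$corrected <- unname(corrected)
    res
}
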