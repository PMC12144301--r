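#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData rowData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.QUANT_SCALES <- c("linear", "log2")
.PTM_MODS <- c("GG", "phospho", "acetyl")

#' QuantExperiment: a quantity matrix with its sample design
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"quant"}
#' (features x samples, positive quantities or log2 values, \code{NA} for
#' missing), a \code{condition} column in \code{colData}, and two metadata
#' entries: \code{scale} (\code{"linear"} or \code{"log2"}) and
#' \code{referenceCondition} (the baseline group, e.g. the young age group,
#' against which fold changes and correction factors are oriented).
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [QuantExperiment()], [quantValues()], [quantScale()],
#'   [referenceCondition()], [sampleConditions()]
#' @export
setClass("QuantExperiment", contains = "SummarizedExperiment")

setValidity("QuantExperiment", function(object) {
    msg <- character()
    if (!"quant" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'quant' is required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!"condition" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'condition' column")
    sc <- metadata(object)$scale
    if (is.null(sc) || !sc %in% .QUANT_SCALES)
        msg <- c(msg, "metadata()$scale must be 'linear' or 'log2'")
    ref <- metadata(object)$referenceCondition
    if (is.null(ref) || !ref %in% colData(object)$condition)
        msg <- c(msg, "metadata()$referenceCondition must be one of the conditions")
    if (length(msg) == 0L && identical(sc, "linear")) {
        q <- assay(object, "quant")
        bad <- which(!is.na(q) & q <= 0)
        if (length(bad))
            msg <- c(msg, sprintf(
                "linear-scale quantities must be > 0 when present (first offender: row %d, col %d)",
                ((bad[1L] - 1L) %% nrow(q)) + 1L, ((bad[1L] - 1L) %/% nrow(q)) + 1L))
    }
    if (length(msg)) msg else TRUE
})

#' PtmSiteTable: identities of modified residues
#'
#' A \code{DataFrame} subclass with one row per modified peptide feature and
#' columns \code{peptide_id} (character, unique), \code{accessions}
#' (\code{CharacterList}: one or more protein accessions), \code{positions}
#' (\code{IntegerList}: 1-based residue positions, parallel to
#' \code{accessions}), \code{residue} (one-letter amino-acid code, \code{"K"}
#' for ubiquitylation) and \code{modification} (one of \code{"GG"},
#' \code{"phospho"}, \code{"acetyl"}).
#'
#' @seealso [PtmSiteTable()], [readSiteTable()]
#' @export
setClass("PtmSiteTable", contains = "DFrame")

setValidity("PtmSiteTable", function(object) {
    msg <- character()
    need <- c("peptide_id", "accessions", "positions", "residue", "modification")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (anyDuplicated(object$peptide_id))
        msg <- c(msg, "peptide_id values must be unique")
    na <- lengths(object$accessions)
    np <- lengths(object$positions)
    if (any(na < 1L))
        msg <- c(msg, "each site needs at least one accession")
    if (any(na != np))
        msg <- c(msg, sprintf(
            "positions count must match accessions count (first offender: peptide_id '%s')",
            object$peptide_id[which(na != np)[1L]]))
    if (any(unlist(object$positions, use.names = FALSE) < 1L))
        msg <- c(msg, "positions must be >= 1")
    if (any(!object$modification %in% .PTM_MODS))
        msg <- c(msg, sprintf("modification must be one of %s",
                              paste(.PTM_MODS, collapse = ", ")))
    if (any(nchar(object$residue) != 1L))
        msg <- c(msg, "residue must be a single one-letter code")
    if (length(msg)) msg else TRUE
})

#' CorrectionFactorTable: per-condition protein-abundance correction factors
#'
#' Holds, per protein accession or semicolon-joined multi-accession group, the
#' per-condition correction factor (median quantity in the condition divided
#' by the median in the reference condition), the number of non-missing
#' samples each median used, and an uncorrectable flag for groups without any
#' non-missing reference-condition value.
#'
#' @slot factors numeric matrix, groups x conditions; reference column is 1.
#' @slot nSamples integer matrix, groups x conditions.
#' @slot uncorrectable named logical vector.
#' @slot referenceCondition character scalar.
#' @seealso [computeCorrectionFactors()], [siteCorrectionFactors()]
#' @export
setClass("CorrectionFactorTable",
    representation(factors = "matrix", nSamples = "matrix",
                   uncorrectable = "logical", referenceCondition = "character"))

setValidity("CorrectionFactorTable", function(object) {
    msg <- character()
    f <- object@factors
    ref <- object@referenceCondition
    if (!ref %in% colnames(f))
        return("reference condition must be a column of the factor matrix")
    if (!identical(dim(f), dim(object@nSamples)))
        msg <- c(msg, "factors and nSamples must have identical dimensions")
    if (length(object@uncorrectable) != nrow(f))
        msg <- c(msg, "uncorrectable flag must have one entry per group")
    ok <- !object@uncorrectable
    if (any(ok) && any(abs(f[ok, ref] - 1) > 1e-12, na.rm = TRUE))
        msg <- c(msg, "reference-condition factors must equal 1")
    if (any(f[ok, ] <= 0, na.rm = TRUE))
        msg <- c(msg, "factors must be > 0")
    if (length(msg)) msg else TRUE
})

#' AlignmentHit: one optimal local alignment
#'
#' Result of a Smith-Waterman local alignment of a query protein against a
#' target protein under an affine gap model. \code{columns} lists the aligned
#' columns in order: \code{qpos}/\code{tpos} are 1-based residue positions,
#' with \code{NA} marking a gap in that sequence.
#'
#' @slot query,target character: sequence identifiers.
#' @slot score numeric: alignment score in substitution-matrix units.
#' @slot columns data.frame with integer columns \code{qpos}, \code{tpos}.
#' @seealso [localAlign()], [projectSite()]
#' @export
setClass("AlignmentHit",
    representation(query = "character", target = "character",
                   score = "numeric", columns = "data.frame"))

setValidity("AlignmentHit", function(object) {
    msg <- character()
    cc <- object@columns
    if (!all(c("qpos", "tpos") %in% colnames(cc)))
        return("columns must have qpos and tpos")
    for (fld in c("qpos", "tpos")) {
        v <- cc[[fld]][!is.na(cc[[fld]])]
        if (length(v) > 1L && any(diff(v) <= 0))
            msg <- c(msg, sprintf("%s must be strictly increasing", fld))
    }
    if (length(object@score) != 1L || object@score < 0)
        msg <- c(msg, "score must be a single non-negative number")
    if (length(msg)) msg else TRUE
})
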