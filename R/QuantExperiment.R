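#' Construct a QuantExperiment
#'
#' @param quant numeric matrix (features x samples) of positive quantities
#'   (linear scale) or log2 values; \code{NA} marks missing measurements.
#' @param design data.frame with columns \code{sample_id} and
#'   \code{condition}; every design sample must be a column of \code{quant}.
#' @param referenceCondition the baseline condition (e.g. \code{"young"}).
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return a \linkS4class{QuantExperiment}.
#' @examples
#' m <- matrix(2^rnorm(6, 10), 3, 2,
#'             dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' d <- data.frame(sample_id = c("s1", "s2"), condition = c("young", "old"))
#' qe <- QuantExperiment(m, d, "young")
#' quantScale(qe)
#' @export
QuantExperiment <- function(quant, design, referenceCondition,
                            scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    design <- .validateDesign(design, referenceCondition)
    quant <- as.matrix(quant)
    storage.mode(quant) <- "double"
    miss <- setdiff(design$sample_id, colnames(quant))
    if (length(miss))
        stop("schema error: sample column(s) missing from quantity table: ",
             paste(miss, collapse = ", "), call. = FALSE)
    quant <- quant[, design$sample_id, drop = FALSE]
    se <- SummarizedExperiment(
        assays = list(quant = quant),
        colData = DataFrame(condition = design$condition,
                            row.names = design$sample_id))
    metadata(se)$scale <- scale
    metadata(se)$referenceCondition <- referenceCondition
    new("QuantExperiment", se)
}

#' @rdname QuantExperiment-class
#' @export
setMethod("quantValues", "QuantExperiment", function(x) assay(x, "quant"))

#' @rdname QuantExperiment-class
#' @export
setMethod("quantScale", "QuantExperiment", function(x) metadata(x)$scale)

#' @rdname QuantExperiment-class
#' @export
setMethod("referenceCondition", "QuantExperiment",
          function(x) metadata(x)$referenceCondition)

#' @rdname QuantExperiment-class
#' @export
setMethod("sampleConditions", "QuantExperiment", function(x) {
    stats::setNames(as.character(colData(x)$condition), colnames(x))
})

setMethod("show", "QuantExperiment", function(object) {
    callNextMethod()
    cat("scale:", quantScale(object),
        "| reference condition:", referenceCondition(object), "\n")
    tab <- table(sampleConditions(object))
    cat("samples per condition:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

# Log2 view of a QuantExperiment (identity if already log2).
#' Convert a linear-scale QuantExperiment to log2
#'
#' @param x a QuantExperiment.
#' @return a QuantExperiment on the log2 scale.
#' @export
asLog2 <- function(x) {
    stopifnot(is(x, "QuantExperiment"))
    if (quantScale(x) == "log2") return(x)
    q <- log2(quantValues(x))
    design <- data.frame(sample_id = colnames(x),
                         condition = sampleConditions(x))
    QuantExperiment(q, design, referenceCondition(x), scale = "log2")
}

#' Construct a PtmSiteTable
#'
#' @param peptide_id character vector of unique peptide/feature ids.
#' @param accessions list (or \code{CharacterList}) of protein accessions per
#'   site; multi-accession peptides keep their order.
#' @param positions list (or \code{IntegerList}) of 1-based residue positions,
#'   parallel to \code{accessions}.
#' @param residue one-letter amino-acid code(s); recycled. \code{"K"} for
#'   ubiquitylated lysines.
#' @param modification \code{"GG"}, \code{"phospho"} or \code{"acetyl"};
#'   recycled.
#' @return a \linkS4class{PtmSiteTable}.
#' @examples
#' PtmSiteTable("pep1", list(c("P1", "P2")), list(c(12L, 15L)))
#' @export
PtmSiteTable <- function(peptide_id, accessions, positions,
                         residue = "K", modification = "GG") {
    n <- length(peptide_id)
    df <- DataFrame(
        peptide_id = as.character(peptide_id),
        accessions = IRanges::CharacterList(accessions),
        positions = IRanges::IntegerList(positions),
        residue = rep_len(as.character(residue), n),
        modification = rep_len(as.character(modification), n))
    new("PtmSiteTable", df)
}

#' Check site residues against protein sequences
#'
#' Validates that every referenced position carries the annotated residue in
#' the supplied sequences; accessions absent from \code{sequences} are
#' skipped.
#'
#' @param sites a PtmSiteTable.
#' @param sequences named character vector or \code{AAStringSet}.
#' @return invisibly \code{TRUE}; errors on the first mismatch.
#' @export
checkSiteResidues <- function(sites, sequences) {
    seqs <- if (is(sequences, "XStringSet")) {
        stats::setNames(as.character(sequences), names(sequences))
    } else sequences
    for (i in seq_len(nrow(sites))) {
        accs <- sites$accessions[[i]]
        pos <- sites$positions[[i]]
        for (j in seq_along(accs)) {
            s <- seqs[accs[j]]
            if (is.na(s)) next
            if (pos[j] > nchar(s) ||
                substr(s, pos[j], pos[j]) != sites$residue[i])
                stop(sprintf(
                    "site '%s': residue at %s:%d is not '%s'",
                    sites$peptide_id[i], accs[j], pos[j], sites$residue[i]),
                    call. = FALSE)
        }
    }
    invisible(TRUE)
}

#' @rdname CorrectionFactorTable-class
#' @export
setMethod("correctionFactors", "CorrectionFactorTable", function(x) x@factors)

#' @rdname CorrectionFactorTable-class
#' @export
setMethod("uncorrectable", "CorrectionFactorTable", function(x) x@uncorrectable)

#' @rdname CorrectionFactorTable-class
#' @export
setMethod("referenceCondition", "CorrectionFactorTable",
          function(x) x@referenceCondition)

setMethod("show", "CorrectionFactorTable", function(object) {
    cat(sprintf("CorrectionFactorTable: %d group(s), conditions: %s\n",
                nrow(object@factors),
                paste(colnames(object@factors), collapse = ", ")))
    cat(sprintf("reference: %s | uncorrectable: %d\n",
                object@referenceCondition, sum(object@uncorrectable)))
})

#' @rdname AlignmentHit-class
#' @export
setMethod("alignmentScore", "AlignmentHit", function(x) x@score)

#' @rdname AlignmentHit-class
#' @export
setMethod("alignmentColumns", "AlignmentHit", function(x) x@columns)

setMethod("show", "AlignmentHit", function(object) {
    cc <- object@columns
    cat(sprintf("AlignmentHit %s vs %s | score %g | %d column(s)\n",
                object@query, object@target, object@score, nrow(cc)))
    if (nrow(cc)) {
        qr <- range(cc$qpos, na.rm = TRUE)
        tr <- range(cc$tpos, na.rm = TRUE)
        cat(sprintf("query span %d-%d | target span %d-%d\n",
                    qr[1], qr[2], tr[1], tr[2]))
    }
})
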