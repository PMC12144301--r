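# TMT-10plex PSM-level filtering, normalization and median summarization
# into a protein quantity matrix.

#' TMT-10plex reporter channel names
#' @return character vector of the 10 channel labels.
#' @export
tmtChannels <- function() {
    c("126", "127N", "127C", "128N", "128C",
      "129N", "129C", "130N", "130C", "131")
}

.psmMeta <- c("psm_id", "peptide_sequence", "protein_group",
              "search_score", "is_reverse", "is_contaminant")

#' Read a PSM-level reporter intensity table (TSV)
#'
#' Columns: \code{psm_id}, \code{peptide_sequence}, \code{protein_group},
#' \code{search_score}, \code{is_reverse}, \code{is_contaminant}, then the
#' ten reporter channels named as in [tmtChannels()]. Empty cells are missing
#' intensities.
#'
#' @param path file path.
#' @return a data.frame of PSM records.
#' @export
readPsmTable <- function(path) {
    df <- .readTsv(path)
    miss <- setdiff(c(.psmMeta, tmtChannels()), colnames(df))
    if (length(miss))
        stop("schema error in '", path, "': missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    for (ch in tmtChannels())
        df[[ch]] <- .asNumericStrict(df[[ch]], paste0("channel '", ch, "'"),
                                     path)
    df$search_score <- .asNumericStrict(df$search_score, "search_score", path)
    df$is_reverse <- as.logical(df$is_reverse)
    df$is_contaminant <- as.logical(df$is_contaminant)
    bad <- which(as.matrix(df[tmtChannels()]) < 0)
    if (length(bad))
        stop("validation error in '", path,
             "': negative reporter intensity", call. = FALSE)
    df
}

#' Filter PSM records
#'
#' Discards PSMs mapping to reverse or contaminant hits, PSMs with a search
#' (Mascot-type) score below \code{scoreMin}, and PSMs whose present reporter
#' intensities are all below \code{intensityFloor} across the ten channels.
#' Filtering is idempotent.
#'
#' @param psm data.frame of PSM records (see [readPsmTable()]).
#' @param scoreMin minimum search score (default 15).
#' @param intensityFloor reporter intensity floor (default 1e3).
#' @return the retained PSM records (possibly zero rows).
#' @export
filterPsms <- function(psm, scoreMin = 15, intensityFloor = 1e3) {
    ints <- as.matrix(psm[tmtChannels()])
    anyAbove <- rowSums(!is.na(ints) & ints >= intensityFloor) > 0L
    keep <- !psm$is_reverse & !psm$is_contaminant &
        psm$search_score >= scoreMin & anyAbove
    psm[keep, , drop = FALSE]
}

#' Log2 transform and channel-median normalization
#'
#' Log2 transforms reporter intensities (zeros become missing) and centers
#' every channel at the grand median: each channel's median is subtracted and
#' the overall median of the log2 matrix added back, so after normalization
#' every channel median equals the grand median.
#'
#' @param mat numeric PSM x channel intensity matrix.
#' @return normalized log2 matrix.
#' @export
normalizeLog2 <- function(mat) {
    mat[!is.na(mat) & mat <= 0] <- NA
    m <- log2(mat)
    chMed <- apply(m, 2L, .medianNA)
    grand <- .medianNA(as.vector(m))
    sweep(m, 2L, chMed - grand, `-`)
}

#' Normalize the reporter channels of PSM records
#'
#' @param psm filtered PSM records.
#' @return the records with channel columns replaced by normalized log2
#'   values.
#' @export
normalizePsms <- function(psm) {
    m <- normalizeLog2(as.matrix(psm[tmtChannels()]))
    psm[tmtChannels()] <- as.data.frame(m)
    psm
}

#' Summarize PSMs into protein group quantities
#'
#' Each peptide's channel value is the median over its PSMs; peptides with
#' more than \code{maxMissingPerPeptide} missing channels are excluded from
#' quantification; each protein group's channel value is the median over its
#' retained peptides. Protein groups identified by fewer than
#' \code{minUniquePeptides} unique peptide sequences are dropped. Medians of
#' an even count are the mean of the two central values; summarization is
#' invariant to PSM row order.
#'
#' @param psm filtered, normalized PSM records (log2 channels).
#' @param minUniquePeptides identification requirement (default 2).
#' @param maxMissingPerPeptide missing-channel tolerance for quantification
#'   (default 1).
#' @return log2 protein group x channel matrix.
#' @export
summarizeProteins <- function(psm, minUniquePeptides = 2L,
                              maxMissingPerPeptide = 1L) {
    chans <- tmtChannels()
    key <- paste(psm$protein_group, psm$peptide_sequence, sep = "\r")
    pepMat <- do.call(rbind, lapply(split(seq_len(nrow(psm)), key),
        function(idx) apply(psm[idx, chans, drop = FALSE], 2L, .medianNA)))
    pepProt <- vapply(strsplit(rownames(pepMat), "\r", fixed = TRUE),
                      `[`, "", 1L)
    nUnique <- table(pepProt)
    keepProt <- names(nUnique)[nUnique >= minUniquePeptides]
    quantOK <- rowSums(is.na(pepMat)) <= maxMissingPerPeptide
    out <- do.call(rbind, lapply(keepProt, function(pg) {
        rows <- pepMat[pepProt == pg & quantOK, , drop = FALSE]
        if (nrow(rows) == 0L) rep(NA_real_, length(chans))
        else apply(rows, 2L, .medianNA)
    }))
    if (is.null(out)) {
        out <- matrix(numeric(0), 0L, length(chans))
    }
    dimnames(out) <- list(keepProt, chans)
    out
}

#' Full TMT summarization pipeline
#'
#' [filterPsms()], then [normalizePsms()], then [summarizeProteins()].
#'
#' @inheritParams filterPsms
#' @inheritParams summarizeProteins
#' @return log2 protein group x channel matrix.
#' @export
summarizeTmt <- function(psm, scoreMin = 15, intensityFloor = 1e3,
                         minUniquePeptides = 2L, maxMissingPerPeptide = 1L) {
    summarizeProteins(normalizePsms(filterPsms(psm, scoreMin, intensityFloor)),
                      minUniquePeptides, maxMissingPerPeptide)
}
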