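#' Read a quantity table (TSV)
#'
#' Expects a tab-delimited file with a \code{feature_id} column plus one
#' column per design sample. Cells may be empty or \code{"NA"} for missing;
#' any other non-numeric cell is a located validation error. The scale is
#' taken from a \code{"# scale=..."} directive line if present, else from the
#' \code{scale} argument.
#'
#' @param path file path.
#' @param design data.frame with \code{sample_id}, \code{condition}.
#' @param referenceCondition baseline condition label.
#' @param scale fallback scale when the file carries no directive.
#' @return a \linkS4class{QuantExperiment}.
#' @seealso [writeQuantTable()]
#' @export
readQuantTable <- function(path, design, referenceCondition,
                           scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    df <- .readTsv(path)
    dir <- grep("^#\\s*scale=", attr(df, "comments"), value = TRUE)
    if (length(dir))
        scale <- match.arg(trimws(sub("^#\\s*scale=", "", dir[1L])),
                           c("linear", "log2"))
    if (!"feature_id" %in% colnames(df))
        stop("schema error in '", path, "': no 'feature_id' column",
             call. = FALSE)
    miss <- setdiff(design$sample_id, colnames(df))
    if (length(miss))
        stop("schema error in '", path, "': missing sample column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$feature_id))
        stop("validation error in '", path, "': duplicate feature ids",
             call. = FALSE)
    q <- vapply(design$sample_id,
                function(s) .asNumericStrict(df[[s]], paste0("column '", s, "'"),
                                             path),
                numeric(nrow(df)))
    if (nrow(df) == 1L)
        q <- matrix(q, nrow = 1L, dimnames = list(NULL, design$sample_id))
    rownames(q) <- df$feature_id
    if (scale == "linear") {
        bad <- which(!is.na(q) & q <= 0, arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf(
                "validation error in '%s': non-positive linear value at row '%s', column '%s'",
                path, rownames(q)[bad[1L, 1L]], colnames(q)[bad[1L, 2L]]),
                call. = FALSE)
    }
    QuantExperiment(q, design, referenceCondition, scale = scale)
}

#' Write a QuantExperiment as TSV
#'
#' Emits \code{"#"}-prefixed version and scale directives, then
#' \code{feature_id} plus one column per sample; missing values become empty
#' cells. Quantities round-trip to at least 12 significant digits.
#'
#' @param x a QuantExperiment.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeQuantTable <- function(x, path) {
    stopifnot(is(x, "QuantExperiment"))
    q <- quantValues(x)
    df <- data.frame(feature_id = rownames(q), q, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path, sprintf("# scale=%s", quantScale(x)))
}

#' Read / write a sample design table
#'
#' TSV with columns \code{sample_id} and \code{condition}.
#'
#' @param path file path.
#' @return \code{readSampleDesign}: a data.frame.
#' @export
readSampleDesign <- function(path) {
    df <- .readTsv(path)
    if (!all(c("sample_id", "condition") %in% colnames(df)))
        stop("schema error in '", path,
             "': need 'sample_id' and 'condition' columns", call. = FALSE)
    data.frame(sample_id = df$sample_id, condition = df$condition,
               stringsAsFactors = FALSE)
}

#' @rdname readSampleDesign
#' @param design a design data.frame.
#' @export
writeSampleDesign <- function(design, path) .writeTsv(design, path)

#' Read a PTM site table (TSV)
#'
#' Columns: \code{peptide_id}, \code{accessions} (semicolon-separated),
#' \code{positions} (semicolon-separated, parallel to accessions),
#' \code{residue}, \code{modification}.
#'
#' @param path file path.
#' @return a \linkS4class{PtmSiteTable}.
#' @export
readSiteTable <- function(path) {
    df <- .readTsv(path)
    need <- c("peptide_id", "accessions", "positions", "residue", "modification")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("schema error in '", path, "': missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    accs <- strsplit(df$accessions, ";", fixed = TRUE)
    accs <- lapply(accs, trimws)
    pos <- lapply(strsplit(df$positions, ";", fixed = TRUE), function(p) {
        as.integer(trimws(p))
    })
    bad <- which(lengths(accs) != lengths(pos))
    if (length(bad))
        stop(sprintf(
            "validation error in '%s': row %d ('%s') has %d accession(s) but %d position(s)",
            path, bad[1L], df$peptide_id[bad[1L]],
            lengths(accs)[bad[1L]], lengths(pos)[bad[1L]]), call. = FALSE)
    PtmSiteTable(df$peptide_id, accs, pos, df$residue, df$modification)
}

#' Write a PtmSiteTable as TSV
#'
#' @param sites a PtmSiteTable.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
    df <- data.frame(
        peptide_id = sites$peptide_id,
        accessions = vapply(sites$accessions, paste, "", collapse = ";"),
        positions = vapply(sites$positions,
                           function(p) paste(p, collapse = ";"), ""),
        residue = sites$residue,
        modification = sites$modification,
        stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read protein sequences from FASTA
#'
#' Accession is the first whitespace-delimited token of the header; UniProt
#' \code{sp|ACC|NAME} headers yield the middle field. Sequences are
#' uppercased; duplicate accessions are an error.
#'
#' @param path FASTA file.
#' @return an \code{AAStringSet} named by accession.
#' @export
readFastaSequences <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
    up <- grepl("^(sp|tr)\\|", acc)
    acc[up] <- vapply(strsplit(acc[up], "|", fixed = TRUE), `[`, "", 2L)
    if (anyDuplicated(acc))
        stop("validation error in '", path, "': duplicate accession(s): ",
             paste(unique(acc[duplicated(acc)]), collapse = ", "),
             call. = FALSE)
    seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
    names(seqs) <- acc
    seqs
}

#' Write protein sequences as FASTA
#'
#' @param sequences named character vector or \code{AAStringSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaSequences <- function(sequences, path) {
    if (!is(sequences, "XStringSet"))
        sequences <- Biostrings::AAStringSet(sequences)
    Biostrings::writeXStringSet(sequences, path)
    invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' GMT: per line, a set name, a description, then tab-separated member ids.
#' Duplicate members within a line are de-duplicated; duplicate set names are
#' an error.
#'
#' @param path GMT file.
#' @return \code{readGmt}: named list of character vectors of member ids,
#'   with a \code{"descriptions"} attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop(sprintf(
            "schema error in '%s': line %d has fewer than 3 fields", path,
            short[1L]), call. = FALSE)
    nm <- vapply(parts, `[`, "", 1L)
    if (anyDuplicated(nm))
        stop("validation error in '", path, "': duplicate set name(s)",
             call. = FALSE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- nm
    attr(sets, "descriptions") <-
        stats::setNames(vapply(parts, `[`, "", 2L), nm)
    sets
}

#' @rdname readGmt
#' @param sets named list of member-id vectors.
#' @param descriptions optional named character vector of descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- attr(sets, "descriptions")
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# ubistoich %s", .pkgVersion()), con)
    for (nm in names(sets))
        writeLines(paste(c(nm, descriptions[[nm]], unique(sets[[nm]])),
                         collapse = "\t"), con)
    invisible(path)
}
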