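# Internal shared helpers.

.pkgVersion <- function() as.character(utils::packageVersion("ubistoich"))

# Polynomial rolling hash of the deparsed parameter list (mod 2^31 - 1);
# provenance stamping only, not cryptographic.
.paramHash <- function(params) {
    s <- paste(deparse(params, control = "all"), collapse = "")
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

# Write a data.frame as TSV with "#"-prefixed provenance header lines.
# Numeric columns are serialized with %.15g so round-trips keep >= 12
# significant digits; NA becomes an empty cell.
.writeTsv <- function(df, path, extraHeader = character()) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(sprintf("# ubistoich %s", .pkgVersion()), extraHeader), con)
    fmt <- vapply(df, function(col) {
        if (is.double(col)) sprintf("%.15g", col)
        else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, colnames(df)))
    fmt[is.na(as.matrix(df))] <- ""
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df))
        writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

# Read a TSV written by .writeTsv (or any plain TSV); returns the table plus
# the "#" directive lines. Cells "" and "NA" are missing. No locale parsing:
# decimal point only.
.readTsv <- function(path, numericCols = NULL) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    isComment <- startsWith(lines, "#")
    comments <- lines[isComment]
    body <- lines[!isComment]
    if (length(body) < 1L)
        stop("schema error in '", path, "': no header row", call. = FALSE)
    df <- utils::read.delim(text = paste(body, collapse = "\n"),
                            check.names = FALSE, colClasses = "character",
                            na.strings = c("", "NA"), stringsAsFactors = FALSE)
    attr(df, "comments") <- comments
    df
}

# Strict numeric conversion of character cells: anything non-numeric and
# non-missing is a located error, never silently coerced to NA.
.asNumericStrict <- function(x, what, path) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
        stop(sprintf("validation error in '%s': non-numeric value '%s' in %s (row %d)",
                     path, x[bad[1L]], what, bad[1L]), call. = FALSE)
    out
}

# Validate a sample design data.frame (sample_id, condition) + reference.
.validateDesign <- function(design, referenceCondition) {
    if (!all(c("sample_id", "condition") %in% colnames(design)))
        stop("design needs 'sample_id' and 'condition' columns", call. = FALSE)
    if (anyDuplicated(design$sample_id))
        stop("sample ids must be unique", call. = FALSE)
    if (!referenceCondition %in% design$condition)
        stop("reference condition '", referenceCondition,
             "' not present in the design", call. = FALSE)
    design
}

# Median that ignores NA and returns NA for all-missing input.
.medianNA <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else stats::median(x)
}

# Largest-remainder apportionment of n items to proportions p (sums to n).
.apportion <- function(n, p) {
    raw <- n * p
    k <- floor(raw)
    rem <- n - sum(k)
    if (rem > 0) {
        ord <- order(raw - k, decreasing = TRUE)
        k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
    }
    as.integer(k)
}
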