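# Cross-species liftover of modified lysines: optimal local alignment of a
# query protein against a target proteome, projection of modified positions
# through the top-k alignments, and the conservation call (a lysine is
# conserved if at least one of the top hits places a lysine at the
# corresponding target position).

.asAAString <- function(x) {
    if (is(x, "XStringSet")) stats::setNames(as.character(x), names(x)) else x
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under an affine gap model (default BLOSUM62 with
#' gap opening 11 and extension 1, protein BLAST's defaults). Delegates the
#' dynamic programming to \code{Biostrings::pairwiseAlignment} and extracts
#' the aligned column list for position projection. A zero-score alignment
#' (e.g. disjoint alphabets) yields an empty column list.
#'
#' @param query,target amino-acid strings (non-empty).
#' @param queryId,targetId identifiers recorded on the hit.
#' @param matrix substitution matrix name (see
#'   \code{Biostrings::pairwiseAlignment}).
#' @param gapOpening,gapExtension affine gap costs.
#' @return an \linkS4class{AlignmentHit}.
#' @examples
#' hit <- localAlign("MKTAYKLL", "MKTYKLL")
#' alignmentScore(hit)  # 23 under BLOSUM62/11/1
#' @export
localAlign <- function(query, target, queryId = "query",
                       targetId = "target", matrix = "BLOSUM62",
                       gapOpening = 11, gapExtension = 1) {
    if (!nzchar(query) || !nzchar(target))
        stop("empty sequence", call. = FALSE)
    aln <- Biostrings::pairwiseAlignment(
        toupper(query), toupper(target), type = "local",
        substitutionMatrix = matrix,
        gapOpening = gapOpening, gapExtension = gapExtension)
    sc <- Biostrings::score(aln)
    if (sc <= 0)
        return(new("AlignmentHit", query = queryId, target = targetId,
                   score = 0,
                   columns = data.frame(qpos = integer(0),
                                        tpos = integer(0))))
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    qoff <- IRanges::start(Biostrings::pattern(aln)) - 1L
    toff <- IRanges::start(Biostrings::subject(aln)) - 1L
    qpos <- ifelse(pa == "-", NA_integer_, qoff + cumsum(pa != "-"))
    tpos <- ifelse(sa == "-", NA_integer_, toff + cumsum(sa != "-"))
    new("AlignmentHit", query = queryId, target = targetId, score = sc,
        columns = data.frame(qpos = as.integer(qpos),
                             tpos = as.integer(tpos)))
}

#' Top-k local alignment hits against a proteome
#'
#' Aligns the query against every target sequence (one optimal local
#' alignment per target), drops zero-score hits, and returns the \code{k}
#' best sorted by score descending with ties broken by target accession.
#'
#' @param query amino-acid string.
#' @param proteome named character vector or \code{AAStringSet}.
#' @param k number of hits to keep (default 10).
#' @param queryId identifier recorded on the hits.
#' @inheritParams localAlign
#' @return list of \linkS4class{AlignmentHit} (possibly fewer than \code{k}).
#' @export
rankHits <- function(query, proteome, k = 10L, queryId = "query",
                     matrix = "BLOSUM62", gapOpening = 11, gapExtension = 1) {
    proteome <- .asAAString(proteome)
    if (is.null(names(proteome)))
        stop("proteome must be named by accession", call. = FALSE)
    hits <- lapply(names(proteome), function(acc)
        localAlign(query, proteome[[acc]], queryId = queryId,
                   targetId = acc, matrix = matrix,
                   gapOpening = gapOpening, gapExtension = gapExtension))
    hits <- hits[vapply(hits, alignmentScore, 0) > 0]
    if (!length(hits)) return(list())
    sc <- vapply(hits, alignmentScore, 0)
    acc <- vapply(hits, function(h) h@target, "")
    hits <- hits[order(-sc, acc)]
    hits[seq_len(min(k, length(hits)))]
}

#' Project a query position through an alignment
#'
#' Returns the target position aligned to the given 1-based query position,
#' or \code{NA} if the position falls in a gap column or outside the local
#' alignment span.
#'
#' @param position 1-based query residue position.
#' @param hit an \linkS4class{AlignmentHit}.
#' @return integer target position or \code{NA}.
#' @export
projectSite <- function(position, hit) {
    cc <- alignmentColumns(hit)
    i <- which(!is.na(cc$qpos) & cc$qpos == position)
    if (length(i) == 0L) return(NA_integer_)
    cc$tpos[i[1L]]
}

#' Conservation call for one modified lysine
#'
#' Projects the site through each hit in rank order; the site is conserved if
#' any hit places it opposite a lysine in the target sequence. The reported
#' target is the highest-ranked hit projecting onto a lysine, else the
#' highest-ranked hit projecting at all.
#'
#' @param queryAcc,position site identity (query accession, 1-based lysine
#'   position).
#' @param hits list of \linkS4class{AlignmentHit} in rank order (from
#'   [rankHits()]).
#' @param targetSeqs named character vector or \code{AAStringSet} with the
#'   target sequences.
#' @return one-row data.frame: \code{query_acc}, \code{query_pos},
#'   \code{target_acc}, \code{target_pos}, \code{conserved}, \code{rank}
#'   (supporting hit rank; \code{NA} when unmapped).
#' @export
callConservation <- function(queryAcc, position, hits, targetSeqs) {
    targetSeqs <- .asAAString(targetSeqs)
    best <- data.frame(query_acc = queryAcc, query_pos = position,
                       target_acc = NA_character_, target_pos = NA_integer_,
                       conserved = FALSE, rank = NA_integer_,
                       stringsAsFactors = FALSE)
    for (r in seq_along(hits)) {
        tp <- projectSite(position, hits[[r]])
        if (is.na(tp)) next
        tacc <- hits[[r]]@target
        res <- substr(targetSeqs[[tacc]], tp, tp)
        if (res == "K") {
            best$target_acc <- tacc; best$target_pos <- tp
            best$conserved <- TRUE; best$rank <- r
            return(best)
        }
        if (is.na(best$rank)) {
            best$target_acc <- tacc; best$target_pos <- tp; best$rank <- r
        }
    }
    best
}

#' Liftover of a table of modified sites
#'
#' For every (accession, position) pair in \code{sites}, ranks the top
#' \code{k} local alignments of the query protein against the target
#' proteome and makes the conservation call. Multi-accession sites are
#' lifted through each accession.
#'
#' @param sites a \linkS4class{PtmSiteTable}.
#' @param querySeqs,targetSeqs named character vectors or \code{AAStringSet}.
#' @param k top hits retained per query protein (default 10).
#' @inheritParams localAlign
#' @return data.frame of site projections with a \code{peptide_id} column.
#' @export
liftoverSites <- function(sites, querySeqs, targetSeqs, k = 10L,
                          matrix = "BLOSUM62", gapOpening = 11,
                          gapExtension = 1) {
    querySeqs <- .asAAString(querySeqs)
    targetSeqs <- .asAAString(targetSeqs)
    accs <- unique(unlist(sites$accessions, use.names = FALSE))
    accs <- intersect(accs, names(querySeqs))
    hitCache <- lapply(stats::setNames(accs, accs), function(a)
        rankHits(querySeqs[[a]], targetSeqs, k = k, queryId = a,
                 matrix = matrix, gapOpening = gapOpening,
                 gapExtension = gapExtension))
    out <- list()
    for (i in seq_len(nrow(sites))) {
        sa <- sites$accessions[[i]]
        sp <- sites$positions[[i]]
        for (j in seq_along(sa)) {
            if (!sa[j] %in% accs) next
            row <- callConservation(sa[j], sp[j], hitCache[[sa[j]]],
                                    targetSeqs)
            row$peptide_id <- sites$peptide_id[i]
            out[[length(out) + 1L]] <- row
        }
    }
    if (!length(out))
        return(data.frame(query_acc = character(0), query_pos = integer(0),
                          target_acc = character(0), target_pos = integer(0),
                          conserved = logical(0), rank = integer(0),
                          peptide_id = character(0)))
    do.call(rbind, out)
}

#' Match lifted sites to modified sites in the target species
#'
#' Emits the pairs where a projected (target accession, target position)
#' coincides with a modified position in the target site table — the
#' cross-species "modified in both" set.
#'
#' @param projections output of [liftoverSites()].
#' @param targetSites a \linkS4class{PtmSiteTable} for the target species.
#' @return data.frame pairing query peptide/site with the target peptide id.
#' @export
matchModifiedSites <- function(projections, targetSites) {
    tkey <- data.frame(
        target_acc = unlist(targetSites$accessions, use.names = FALSE),
        target_pos = unlist(targetSites$positions, use.names = FALSE),
        target_peptide_id = rep(targetSites$peptide_id,
                                lengths(targetSites$accessions)),
        stringsAsFactors = FALSE)
    mapped <- projections[!is.na(projections$target_pos), , drop = FALSE]
    merge(mapped, tkey, by = c("target_acc", "target_pos"))
}
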