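# AQUA spike-in absolute quantification of ubiquitin-chain linkages from
# PRM light/heavy intensities, the derived polyubiquitin fraction, and group
# comparisons.

.UB_TARGETS <- c("M1", "K6", "K11", "K27", "K29", "K33", "K48", "K63",
                 "total_ub")

#' Absolute amount from a light/heavy intensity pair
#'
#' The endogenous amount is the light/heavy intensity ratio times the spiked
#' reference amount. A missing or zero heavy intensity means the assay is
#' below detection (\code{NA}), not amount zero; a zero light intensity is a
#' detected zero.
#'
#' @param light,heavy intensities (vectorized).
#' @param spike spiked reference amount (fmol per ug input protein).
#' @return amounts in fmol/ug; \code{NA} flags below-detection assays.
#' @examples
#' quantifyEndogenous(300, 150, 20)  # 40 fmol/ug
#' @export
quantifyEndogenous <- function(light, heavy, spike) {
    stopifnot(all(spike > 0))
    ifelse(is.na(heavy) | heavy <= 0, NA_real_, light / heavy * spike)
}

#' Polyubiquitin percentage
#'
#' 100 times the summed chain-linkage amounts (every target except
#' \code{total_ub}; below-detection linkages contribute 0) divided by the
#' total-ubiquitin amount.
#'
#' @param amounts named numeric vector of per-target amounts including
#'   \code{total_ub}.
#' @return percentage of the ubiquitin pool present in chains.
#' @export
percentPolyubiquitin <- function(amounts) {
    if (!"total_ub" %in% names(amounts))
        stop("amounts must include 'total_ub'", call. = FALSE)
    tot <- amounts[["total_ub"]]
    if (is.na(tot) || tot <= 0)
        stop("total ubiquitin amount must be present and > 0", call. = FALSE)
    linko <- amounts[setdiff(names(amounts), "total_ub")]
    100 * sum(linko, na.rm = TRUE) / tot
}

#' Per-sample linkage quantification from a PRM run
#'
#' Joins the intensity table with the spike panel, converts every
#' light/heavy pair to an absolute amount, averages multiple peptides of the
#' same target (redundant assays of one analyte), and derives the
#' polyubiquitin percentage per sample.
#'
#' @param intensities data.frame \code{sample_id}, \code{peptide},
#'   \code{light}, \code{heavy} (e.g. from [simulatePrm()]).
#' @param panel data.frame \code{peptide}, \code{target},
#'   \code{spike_fmol_per_ug}; targets are ubiquitin-chain linkages (M1, K6,
#'   K11, K27, K29, K33, K48, K63) and \code{total_ub}. Absent targets (the
#'   K29 assay has no quantifiable peptide) are simply not reported.
#' @return data.frame with \code{sample_id}, one column per panel target
#'   (fmol/ug, \code{NA} below detection) and \code{percent_polyubiquitin}.
#' @export
linkageQuant <- function(intensities, panel) {
    stopifnot(all(c("sample_id", "peptide", "light", "heavy") %in%
                      colnames(intensities)),
              all(c("peptide", "target", "spike_fmol_per_ug") %in%
                      colnames(panel)))
    bad <- setdiff(panel$target, .UB_TARGETS)
    if (length(bad))
        stop("unknown target(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    df <- merge(intensities, panel, by = "peptide")
    df$amount <- quantifyEndogenous(df$light, df$heavy,
                                    df$spike_fmol_per_ug)
    targets <- intersect(.UB_TARGETS, unique(panel$target))
    samples <- unique(intensities$sample_id)
    out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
    for (tg in targets) {
        sub <- df[df$target == tg, , drop = FALSE]
        out[[tg]] <- vapply(samples, function(s) {
            a <- sub$amount[sub$sample_id == s]
            if (!length(a) || all(is.na(a))) NA_real_
            else mean(a, na.rm = TRUE)
        }, numeric(1))
    }
    out$percent_polyubiquitin <- vapply(seq_len(nrow(out)), function(i) {
        amounts <- unlist(out[i, targets])
        if (!"total_ub" %in% targets || is.na(amounts[["total_ub"]]) ||
            amounts[["total_ub"]] <= 0)
            return(NA_real_)
        percentPolyubiquitin(amounts)
    }, numeric(1))
    out
}

#' Group comparison of linkage amounts
#'
#' Per target: an unpaired two-sample pooled t-test between two conditions,
#' and a one-way ANOVA when three or more conditions are present.
#' Below-detection amounts (\code{NA}) are excluded from the statistics.
#'
#' @param quants output of [linkageQuant()].
#' @param design data.frame \code{sample_id}, \code{condition}.
#' @return data.frame per target with group means, \code{t_p_value} (two
#'   conditions) and \code{anova_F}, \code{anova_p} (three or more).
#' @export
groupCompare <- function(quants, design) {
    design <- design[match(quants$sample_id, design$sample_id), ]
    cond <- design$condition
    conds <- unique(cond)
    targets <- setdiff(colnames(quants),
                       c("sample_id", "percent_polyubiquitin"))
    rows <- lapply(targets, function(tg) {
        y <- quants[[tg]]
        ok <- !is.na(y)
        row <- data.frame(target = tg, stringsAsFactors = FALSE)
        for (cd in conds)
            row[[paste0("mean_", cd)]] <- mean(y[ok & cond == cd])
        row$t_p_value <- NA_real_
        row$anova_F <- NA_real_; row$anova_p <- NA_real_
        if (length(conds) == 2L) {
            g1 <- y[ok & cond == conds[1L]]
            g2 <- y[ok & cond == conds[2L]]
            if (length(g1) >= 2L && length(g2) >= 2L) {
                if (stats::var(g1) + stats::var(g2) == 0) {
                    row$t_p_value <- if (mean(g1) == mean(g2)) 1 else 0
                } else {
                    row$t_p_value <- stats::t.test(g1, g2,
                                                   var.equal = TRUE)$p.value
                }
            }
        } else if (length(conds) >= 3L) {
            yy <- y[ok]; gg <- factor(cond[ok])
            if (stats::var(yy) == 0)
                stop("degenerate data: no variance across groups for ",
                     tg, call. = FALSE)
            if (all(tapply(yy, gg, stats::var) == 0)) {
                # groups perfectly separated: zero within-group variance
                row$anova_F <- Inf; row$anova_p <- 0
            } else {
                ow <- stats::oneway.test(yy ~ gg, var.equal = TRUE)
                row$anova_F <- unname(ow$statistic)
                row$anova_p <- ow$p.value
            }
        }
        row
    })
    do.call(rbind, rows)
}
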