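#' Relative quantification by the 2^-ddCt method
#'
#' Collapses replicate wells (arithmetic mean of Ct by default, median via
#' \code{collapse}), corrects each target gene by the reference gene within
#' every condition (dCt = mean Ct_target - mean Ct_reference), references
#' each condition to vehicle (ddCt = dCt_condition - dCt_vehicle) and
#' reports fold change 2^(-ddCt) and log2 fold change -ddCt. Assumes
#' perfect amplification efficiency (one cycle per doubling), the standard
#' ddCt premise. Vehicle maps to fold change exactly 1.
#'
#' @param table a \linkS4class{CtTable}; the vehicle condition must be
#'   present for every gene and the reference gene in every condition
#' @param collapse how replicate Ct values are collapsed, \code{"mean"}
#'   (default) or \code{"median"}
#' @return data.frame with columns gene, condition, delta_delta_ct,
#'   log2fc, fold_change (reference gene excluded)
#' @examples
#' d <- data.frame(
#'     target_gene = rep(c("EGR1", "ACTB"), each = 2),
#'     condition   = rep(c("x10", "vehicle"), 2),
#'     replicate   = 1L,
#'     ct          = c(25, 26, 20, 20))
#' deltaDeltaCt(ctTable(d))  # EGR1 under x10: ddCt -1, fold change 2
#' @export
deltaDeltaCt <- function(table, collapse = c("mean", "median")) {
    collapse <- match.arg(collapse)
    fun <- if (collapse == "mean") mean else median
    d <- table@data
    ref <- table@referenceGene
    veh <- table@vehicle
    genes <- setdiff(unique(d$target_gene), ref)
    conds <- unique(d$condition)
    if (!veh %in% conds) stop("vehicle condition '", veh, "' not in table")
    agg <- aggregate(list(ct = d$ct),
                     by = d[c("target_gene", "condition")], FUN = fun)
    ctOf <- function(gene, cond) {
        v <- agg$ct[agg$target_gene == gene & agg$condition == cond]
        if (!length(v))
            stop("no Ct measurements for gene '", gene, "' in condition '",
                 cond, "'")
        v
    }
    out <- expand.grid(gene = genes, condition = conds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ddct <- mapply(function(g, cond) {
        dct <- ctOf(g, cond) - ctOf(ref, cond)
        dct_veh <- ctOf(g, veh) - ctOf(ref, veh)
        dct - dct_veh
    }, out$gene, out$condition)
    out$delta_delta_ct <- as.numeric(ddct)
    out$log2fc <- -out$delta_delta_ct
    out$fold_change <- 2^out$log2fc
    out
}

#' Remove undetected classifier genes
#'
#' A target gene is a dropout when, in any condition, every replicate well
#' sits at or above the maximum cycle number (no amplicon detected).
#' Dropouts are removed entirely, so they contribute to no compound's
#' score, and reported by name. The reference gene is never allowed to drop
#' out: that is an error.
#'
#' @param table a \linkS4class{CtTable}
#' @return list with \code{table} (clean \linkS4class{CtTable}) and
#'   \code{dropped} (character vector of removed genes)
#' @export
flagDropouts <- function(table) {
    d <- table@data
    mx <- table@maxCycles
    undet <- aggregate(list(all_undetected = d$ct >= mx),
                       by = d[c("target_gene", "condition")], FUN = all)
    bad <- unique(undet$target_gene[undet$all_undetected])
    if (table@referenceGene %in% bad)
        stop("reference gene '", table@referenceGene,
             "' undetected in at least one condition")
    clean <- d[!d$target_gene %in% bad, , drop = FALSE]
    list(table = ctTable(clean, referenceGene = table@referenceGene,
                         vehicle = table@vehicle, maxCycles = mx),
         dropped = bad)
}

#' Fold-change matrix from ddCt results
#'
#' Reshapes the long-format output of \code{\link{deltaDeltaCt}} into a
#' classifier \linkS4class{FoldChangeMatrix} (genes x compounds, provenance
#' "qpcr"), dropping the vehicle column (identically zero by construction).
#'
#' @param ddct data.frame from \code{\link{deltaDeltaCt}}
#' @param vehicle vehicle condition name to drop (default "vehicle")
#' @return a \linkS4class{FoldChangeMatrix}
#' @export
ddctToFoldChanges <- function(ddct, vehicle = "vehicle") {
    keep <- ddct[ddct$condition != vehicle, , drop = FALSE]
    genes <- unique(keep$gene)
    comps <- unique(keep$condition)
    m <- matrix(NA_real_, length(genes), length(comps),
                dimnames = list(genes, comps))
    m[cbind(match(keep$gene, genes), match(keep$condition, comps))] <- keep$log2fc
    if (anyNA(m)) stop("incomplete gene x compound fold-change table")
    foldChangeMatrix(m, provenance = "qpcr")
}
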