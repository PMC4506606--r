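#' Between-array quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference distribution is the vector of row-wise means of the
#' column-sorted input, and each column's values are replaced by the
#' reference value at their rank, preserving within-column order. Entries
#' tied within a column receive the mean of the reference values at their
#' tied ranks. On tie-free data the operation is idempotent and leaves all
#' columns with an identical multiset of values.
#'
#' @param x a numeric matrix (features x samples) or an
#'   \linkS4class{AnalogueExperiment}
#' @return an object of the same class as \code{x} with normalized values
#' @examples
#' m <- cbind(a = c(1, 3), b = c(2, 8))
#' quantileNormalize(m)  # both columns become c(1.5, 5.5)
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
    if (nrow(x) == 0L || ncol(x) == 0L) stop("empty matrix")
    if (!all(is.finite(x))) stop("non-finite values in matrix")
    if (ncol(x) == 1L) return(x)
    ref <- rowMeans(apply(x, 2L, sort))
    out <- x
    for (j in seq_len(ncol(x))) {
        xj <- x[, j]
        v <- numeric(length(xj))
        v[order(xj)] <- ref
        # ties within the column share the mean of their assigned references
        out[, j] <- ave(v, match(xj, xj), FUN = mean)
    }
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "AnalogueExperiment", function(x) {
    SummarizedExperiment::assay(x, "exprs") <-
        quantileNormalize(SummarizedExperiment::assay(x, "exprs"))
    x
})

# One Tukey median polish on a probes x samples block. Returns overall,
# column effects and residuals; convergence when the largest absolute
# change in the residual matrix between sweeps drops below tol.
.medianPolish <- function(z, maxIter = 10L, tol = 0.01) {
    t_all <- 0
    row_eff <- rep(0, nrow(z))
    col_eff <- rep(0, ncol(z))
    for (iter in seq_len(maxIter)) {
        z_prev <- z
        rd <- apply(z, 1L, median)
        z <- z - rd
        row_eff <- row_eff + rd
        cd <- median(col_eff)
        col_eff <- col_eff - cd
        t_all <- t_all + cd
        cd2 <- apply(z, 2L, median)
        z <- sweep(z, 2L, cd2)
        col_eff <- col_eff + cd2
        rd2 <- median(row_eff)
        row_eff <- row_eff - rd2
        t_all <- t_all + rd2
        if (max(abs(z - z_prev)) < tol) break
    }
    list(overall = t_all, row = row_eff, col = col_eff, residuals = z)
}

#' Median-polish probe-set summarization
#'
#' Summarizes probe-level log2 intensities into one value per gene and
#' sample, the probe-set summary step of the RMA chain: for each gene, a
#' Tukey median polish is run on its probes x samples block (alternating
#' row- and column-median sweeps until the largest absolute residual change
#' falls below \code{tol} or \code{maxIter} sweeps) and the gene's summary
#' for sample j is the overall effect plus column effect j. Deterministic;
#' a single-probe gene's summary is the probe row itself.
#'
#' @param probeMatrix numeric matrix, probes x samples, log2 scale
#' @param probeMap data.frame with columns \code{probe_id}, \code{gene_id};
#'   every probe in \code{probeMatrix} must map to exactly one gene
#' @param maxIter maximum number of polish sweeps (default 10)
#' @param tol convergence tolerance on the log2 scale (default 0.01)
#' @return numeric matrix, genes x samples, genes in order of first
#'   appearance in \code{probeMap}
#' @export
medianPolishSummarize <- function(probeMatrix, probeMap, maxIter = 10L,
                                  tol = 0.01) {
    stopifnot(is.matrix(probeMatrix))
    if (!all(c("probe_id", "gene_id") %in% colnames(probeMap)))
        stop("probeMap must have columns probe_id, gene_id")
    if (anyDuplicated(probeMap$probe_id))
        stop("probe(s) mapped more than once: ",
             paste(unique(probeMap$probe_id[duplicated(probeMap$probe_id)]),
                   collapse = ", "))
    unmapped <- setdiff(rownames(probeMatrix), probeMap$probe_id)
    if (length(unmapped))
        stop("probe(s) without mapping: ", paste(unmapped, collapse = ", "))
    probeMap <- probeMap[probeMap$probe_id %in% rownames(probeMatrix), , drop = FALSE]
    genes <- unique(probeMap$gene_id)
    out <- matrix(NA_real_, length(genes), ncol(probeMatrix),
                  dimnames = list(genes, colnames(probeMatrix)))
    for (g in genes) {
        probes <- probeMap$probe_id[probeMap$gene_id == g]
        block <- probeMatrix[probes, , drop = FALSE]
        if (nrow(block) == 1L) {
            out[g, ] <- block[1L, ]
        } else {
            mp <- .medianPolish(block, maxIter = maxIter, tol = tol)
            out[g, ] <- mp$overall + mp$col
        }
    }
    out
}
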