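#' Principal-component scores of samples
#'
#' Gene-centered PCA for dataset QC (the treatment/cell-line separation
#' check): each gene is centered across samples, the sample-space singular
#' value decomposition is taken, and sample scores plus variance-explained
#' fractions are returned. Component signs are fixed by making each
#' component's largest-magnitude gene loading positive, so outputs are
#' reproducible.
#'
#' @param x numeric matrix (features x samples) or an
#'   \linkS4class{AnalogueExperiment}
#' @param nComponents number of components, at most
#'   min(samples - 1, features)
#' @return list with \code{scores} (samples x components),
#'   \code{varianceExplained} (fractions, non-increasing, summing to <= 1)
#'   and \code{loadings} (features x components)
#' @export
pcaScores <- function(x, nComponents = 2L) {
    if (methods::is(x, "AnalogueExperiment")) x <- exprsMatrix(x)
    stopifnot(is.matrix(x))
    maxc <- min(ncol(x) - 1L, nrow(x))
    if (nComponents > maxc)
        stop("nComponents must be <= min(samples - 1, features) = ", maxc)
    centered <- x - rowMeans(x)
    sv <- svd(t(centered))
    total <- sum(sv$d^2)
    varfrac <- if (total > 0) sv$d^2 / total else rep(0, length(sv$d))
    idx <- seq_len(nComponents)
    scores <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], nComponents)
    loadings <- sv$v[, idx, drop = FALSE]
    for (j in idx) {
        if (loadings[which.max(abs(loadings[, j])), j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    dimnames(scores) <- list(colnames(x), paste0("PC", idx))
    dimnames(loadings) <- list(rownames(x), paste0("PC", idx))
    list(scores = scores, varianceExplained = varfrac[idx], loadings = loadings)
}
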