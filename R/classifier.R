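#' Select the mitogenic classifier genes
#'
#' Ranks genes, per time point, on how strongly they separate the highly
#' mitogenic exposures (X10 and IGF1, averaged) from insulin within the
#' IGF1R cell line, and keeps the top \code{k} per time point. The default
#' statistic is the moderated t on the contrast
#' (beta_X10 + beta_IGF1)/2 - beta_insulin (vehicle terms cancel), ranked
#' by p ascending with ties broken by larger |log2FC| then gene id. The
#' alternative \code{"between-treatment-var"} statistic ranks genes by the
#' variance of their three treatment-versus-vehicle fold changes,
#' descending. Glargine is deliberately held out of the selection, so its
#' mitogenic potential can be judged by the resulting classifier.
#'
#' @param fit a \linkS4class{GroupMeanFit} containing the IGF1R cell line
#'   groups
#' @param hyper an \linkS4class{EBayesHyper}
#' @param cellLine cell line used for selection (default "igf1r")
#' @param timePoints time points (hours) to select at; default: all time
#'   points available for \code{cellLine}
#' @param k genes kept per time point (default 10)
#' @param strong the strongly mitogenic treatments (default X10 and IGF1)
#' @param reference the weakly mitogenic reference treatment (default
#'   insulin)
#' @param stat selection statistic, \code{"contrast-t"} (default) or
#'   \code{"between-treatment-var"}
#' @return a \linkS4class{ClassifierSet}
#' @export
selectClassifierGenes <- function(fit, hyper, cellLine = "igf1r",
                                  timePoints = NULL, k = 10L,
                                  strong = c("x10", "igf1"),
                                  reference = "insulin",
                                  stat = c("contrast-t", "between-treatment-var")) {
    stat <- match.arg(stat)
    cellLine <- tolower(cellLine)
    g <- fit@groups
    if (is.null(timePoints))
        timePoints <- sort(unique(g$time_h[g$cell_line == cellLine]))
    rows <- list()
    for (tp in timePoints) {
        need <- groupKey(cellLine, c(strong, reference), tp)
        absent <- setdiff(need, g$group)
        if (length(absent))
            stop("missing treatment group(s) for selection: ",
                 paste(absent, collapse = ", "))
        if (stat == "contrast-t") {
            contrast <- setNames(c(rep(1 / length(strong), length(strong)), -1),
                                 need)
            cr <- moderatedContrast(fit, hyper, contrast,
                                    name = sprintf("%s_strong_vs_%s_%gh",
                                                   cellLine, reference, tp))
            tab <- cr@table
            ord <- order(tab$p, -abs(tab$log2fc), tab$gene)
            top <- tab[ord[seq_len(min(k, nrow(tab)))], ]
            rows[[as.character(tp)]] <- data.frame(
                gene = top$gene, time_h = tp,
                direction = ifelse(top$log2fc >= 0, 1L, -1L),
                log2fc = top$log2fc, stat = top$t, p = top$p,
                stringsAsFactors = FALSE)
        } else {
            veh <- groupKey(cellLine, "vehicle", tp)
            if (!veh %in% g$group) stop("missing vehicle group for ", tp, " h")
            fcs <- sapply(c(strong, reference), function(tr)
                fit@coefficients[, groupKey(cellLine, tr, tp)] -
                fit@coefficients[, veh])
            v <- apply(fcs, 1L, var)
            strong_fc <- rowMeans(fcs[, strong, drop = FALSE]) - fcs[, reference]
            ord <- order(-v, -abs(strong_fc), rownames(fit@coefficients))
            idx <- ord[seq_len(min(k, length(v)))]
            rows[[as.character(tp)]] <- data.frame(
                gene = rownames(fit@coefficients)[idx], time_h = tp,
                direction = ifelse(strong_fc[idx] >= 0, 1L, -1L),
                log2fc = strong_fc[idx], stat = v[idx], p = NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    methods::new("ClassifierSet", table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 k = as.integer(k))
}

#' @describeIn selectClassifierGenes the classifier gene set: the union of
#'   the per-time-point hit lists
#' @param cs a ClassifierSet
#' @export
classifierGenes <- function(cs) unique(cs@table$gene)

#' @describeIn selectClassifierGenes the selection table (one row per gene
#'   and time point)
#' @export
classifierTable <- function(cs) cs@table

#' Classifier fold changes from microarray contrasts
#'
#' Builds the classifier genes x compounds log2 fold-change matrix from a
#' fitted experiment: each gene's fold change versus vehicle is taken at
#' the time point where the gene was selected (for a gene selected at both
#' time points, the one with the smaller selection p value).
#'
#' @param fit a \linkS4class{GroupMeanFit}
#' @param hyper an \linkS4class{EBayesHyper}
#' @param cs a \linkS4class{ClassifierSet}
#' @param cellLine cell line to profile (default "igf1r")
#' @param compounds compounds to include; default every non-vehicle
#'   treatment available for \code{cellLine}
#' @return a \linkS4class{FoldChangeMatrix} with provenance "microarray"
#' @export
classifierFoldChanges <- function(fit, hyper, cs, cellLine = "igf1r",
                                  compounds = NULL) {
    g <- fit@groups
    cellLine <- tolower(cellLine)
    if (is.null(compounds))
        compounds <- setdiff(unique(g$treatment[g$cell_line == cellLine]),
                             "vehicle")
    tab <- classifierTable(cs)
    ord <- order(tab$gene, tab$p, tab$time_h)
    tab <- tab[ord, ]
    tab <- tab[!duplicated(tab$gene), ]       # keep the stronger time point
    ctr <- vehicleContrasts(fit, hyper)
    m <- matrix(NA_real_, nrow(tab), length(compounds),
                dimnames = list(tab$gene, compounds))
    for (cmp in compounds) {
        for (i in seq_len(nrow(tab))) {
            cn <- sprintf("%s_%s_%gh", cellLine, cmp, tab$time_h[i])
            if (is.null(ctr[[cn]]))
                stop("no vehicle contrast available for ", cn)
            ct <- contrastTable(ctr[[cn]])
            m[i, cmp] <- ct$log2fc[match(tab$gene[i], ct$gene)]
        }
    }
    foldChangeMatrix(m, provenance = "microarray")
}

#' Relative mitogenic potential of one compound
#'
#' M(c) = sum over the classifier genes present in the fold-change matrix
#' of |log2 fold change vs vehicle| for compound \code{c}. No weighting and
#' no use of sign: up- and downregulation contribute alike.
#'
#' @param fc a \linkS4class{FoldChangeMatrix}
#' @param compound compound (column) name
#' @return a non-negative number
#' @examples
#' m <- matrix(c(1, -1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "x10"))
#' mitogenicPotentialScore(foldChangeMatrix(m), "x10")  # 4
#' @export
mitogenicPotentialScore <- function(fc, compound) {
    v <- foldChanges(fc)
    if (!compound %in% colnames(v)) stop("unknown compound: ", compound)
    sum(abs(v[, compound]))
}

#' Score and rank all compounds
#'
#' Computes the relative mitogenic potential for every compound column and
#' assigns dense descending ranks (rank 1 = most mitogenic; tied scores
#' share a rank).
#'
#' @param fc a \linkS4class{FoldChangeMatrix}
#' @return a \linkS4class{MitogenicScoreTable}
#' @export
rankCompounds <- function(fc) {
    v <- foldChanges(fc)
    if (ncol(v) < 1L) stop("need >= 1 compound")
    scores <- setNames(colSums(abs(v)), colnames(v))
    ranks <- match(scores, sort(unique(scores), decreasing = TRUE))
    methods::new("MitogenicScoreTable", scores = scores,
                 ranks = setNames(as.integer(ranks), names(scores)))
}

#' @describeIn rankCompounds named score vector
#' @param x a MitogenicScoreTable
#' @export
mitogenicScores <- function(x) x@scores

#' @describeIn rankCompounds named dense ranks (1 = highest score)
#' @export
compoundRanks <- function(x) x@ranks

#' Hierarchical clustering of compounds
#'
#' Agglomerative clustering of the compound columns of the fold-change
#' matrix (Euclidean distance, average linkage by default), serialized as a
#' Newick string with branch lengths. Deterministic for a given input.
#'
#' @param fc a \linkS4class{FoldChangeMatrix} with >= 2 compounds
#' @param metric distance between compound profiles (default
#'   \code{"euclidean"})
#' @param linkage agglomeration method passed to \code{hclust} (default
#'   \code{"average"})
#' @return a Newick string; parse with \code{ape::read.tree} for tree
#'   operations
#' @export
clusterCompounds <- function(fc, metric = "euclidean", linkage = "average") {
    v <- foldChanges(fc)
    if (ncol(v) < 2L) stop("need >= 2 compounds to cluster")
    hc <- hclust(dist(t(v), method = metric), method = linkage)
    ape::write.tree(ape::as.phylo(hc))
}

#' Correlate mitogenic scores with an external mitogenicity index
#'
#' Spearman rank correlation between the classifier-based mitogenic
#' potential and an independently measured index (e.g. proliferation EC50
#' fold change or IGF1R binding affinity), over the compounds shared by
#' both tables. Ties are mid-ranked. Fewer than three shared compounds is
#' an error.
#'
#' @param scores a \linkS4class{MitogenicScoreTable} (or named numeric)
#' @param external named numeric vector, compound -> index value
#' @return list with \code{rho} and \code{n} (shared compounds)
#' @export
correlateExternal <- function(scores, external) {
    s <- if (methods::is(scores, "MitogenicScoreTable")) scores@scores else scores
    shared <- intersect(names(s), names(external))
    if (length(shared) < 3L)
        stop("need >= 3 shared compounds (have ", length(shared), ")")
    list(rho = cor(s[shared], external[shared], method = "spearman"),
         n = length(shared))
}
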