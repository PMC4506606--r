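.genesOf <- function(x) {
    if (methods::is(x, "GeneSet")) x@genes else as.character(x)
}

.asGeneList <- function(sets) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("all sets must be named")
    if (anyDuplicated(names(sets)))
        stop("duplicate set name(s): ",
             paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    lapply(sets, .genesOf)
}

#' Venn partition of gene sets
#'
#' Assigns every gene in the union of 2-4 named sets to exactly one Venn
#' region, labelled by the names of the sets containing it (joined with
#' \code{"&"}). All 2^n - 1 regions are returned, empty ones included, so
#' region sizes always sum to the size of the union.
#'
#' @param sets named list of 2-4 \linkS4class{GeneSet}s or character vectors
#' @return named list of character vectors, one per region
#' @examples
#' vennPartition(list(A = c("a", "b"), B = c("b", "c")))
#' @export
vennPartition <- function(sets) {
    gl <- .asGeneList(sets)
    if (length(gl) < 2L || length(gl) > 4L) stop("need 2-4 sets")
    nm <- names(gl)
    un <- unique(unlist(gl, use.names = FALSE))
    member <- vapply(gl, function(s) un %in% s, logical(length(un)))
    if (length(un) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, nm))
    regions <- list()
    for (k in seq_along(nm)) {
        for (combo in utils::combn(nm, k, simplify = FALSE)) {
            label <- paste(combo, collapse = "&")
            inside <- rowSums(member[, combo, drop = FALSE]) == k &
                      rowSums(member) == k
            regions[[label]] <- un[inside]
        }
    }
    regions
}

#' Fraction of genes shared by all sets
#'
#' Overlap of DEG sets, by default intersection-over-union:
#' |intersection of all sets| / |union of all sets|. The alternative
#' \code{"pairwise-mean"} mode averages the pairwise Jaccard indices. An
#' empty union is an error.
#'
#' @param sets named list of >= 2 GeneSets or character vectors
#' @param mode \code{"iou"} (default) or \code{"pairwise-mean"}
#' @return a number in [0, 1]
#' @export
overlapFraction <- function(sets, mode = c("iou", "pairwise-mean")) {
    mode <- match.arg(mode)
    gl <- .asGeneList(sets)
    if (length(gl) < 2L) stop("need >= 2 sets")
    un <- unique(unlist(gl, use.names = FALSE))
    if (!length(un)) stop("union of sets is empty")
    if (mode == "iou") {
        inter <- Reduce(intersect, gl)
        length(inter) / length(un)
    } else {
        pairs <- utils::combn(seq_along(gl), 2L, simplify = FALSE)
        mean(vapply(pairs, function(ij) {
            a <- gl[[ij[1L]]]; b <- gl[[ij[2L]]]
            u <- union(a, b)
            if (!length(u)) return(NA_real_)
            length(intersect(a, b)) / length(u)
        }, numeric(1)), na.rm = TRUE)
    }
}

#' Mitogenic and metabolic response clusters
#'
#' Partitions DEGs of the four training treatments into the two response
#' clusters: the mitogenic cluster collects genes differentially expressed
#' under IGF1 (alone or together with glargine and/or X10) but not under
#' insulin; the metabolic cluster collects the insulin-specific DEGs (alone
#' or shared with the analogues) that do not respond to IGF1. The two
#' clusters are disjoint by construction. Membership is on gene identity
#' only; DEG direction is ignored.
#'
#' @param degByTreatment named list with components \code{insulin},
#'   \code{glargine}, \code{x10} and \code{igf1}, each a GeneSet or
#'   character vector of DEGs
#' @return list of two \linkS4class{GeneSet}s, \code{mitogenic} and
#'   \code{metabolic}
#' @export
buildResponseClusters <- function(degByTreatment) {
    names(degByTreatment) <- tolower(names(degByTreatment))
    need <- c("insulin", "glargine", "x10", "igf1")
    missing <- setdiff(need, names(degByTreatment))
    if (length(missing))
        stop("missing treatment DEG set(s): ", paste(missing, collapse = ", "))
    gl <- lapply(degByTreatment[need], .genesOf)
    mito <- setdiff(gl$igf1, gl$insulin)
    metab <- setdiff(gl$insulin, gl$igf1)
    list(mitogenic = geneSet(mito, name = "mitogenic"),
         metabolic = geneSet(metab, name = "metabolic"))
}
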