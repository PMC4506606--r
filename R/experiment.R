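#' Construct an AnalogueExperiment
#'
#' Couples a log2 expression matrix with its design table, validating that
#' the two describe exactly the same samples. Treatment and cell-line tokens
#' are canonicalized to lower case.
#'
#' @param exprs numeric matrix, features x samples, log2 scale, with unique
#'   dimnames and no missing values
#' @param design data.frame with columns sample_id, cell_line, treatment,
#'   time_h, replicate (one row per sample)
#' @return an \linkS4class{AnalogueExperiment}
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample_id = paste0("s", 1:4), cell_line = "igf1r",
#'                 treatment = c("vehicle", "vehicle", "x10", "x10"),
#'                 time_h = 1, replicate = c(1, 2, 1, 2))
#' ae <- AnalogueExperiment(m, d)
#' designTable(ae)
#' @export
AnalogueExperiment <- function(exprs, design) {
    stopifnot(is.matrix(exprs))
    design <- .canonicalizeDesign(design)
    if (anyDuplicated(design$sample_id))
        stop("duplicated sample_id in design: ",
             paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
    extra_m <- setdiff(colnames(exprs), design$sample_id)
    extra_d <- setdiff(design$sample_id, colnames(exprs))
    if (length(extra_m) || length(extra_d))
        stop("matrix/design sample mismatch; matrix-only: [",
             paste(extra_m, collapse = ", "), "] design-only: [",
             paste(extra_d, collapse = ", "), "]")
    design <- design[match(colnames(exprs), design$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(design[setdiff(colnames(design), "sample_id")],
                               row.names = design$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd)
    methods::new("AnalogueExperiment", se)
}

.canonicalizeDesign <- function(design) {
    missing <- setdiff(.REQUIRED_DESIGN_COLS, colnames(design))
    if (length(missing))
        stop("design is missing required column(s): ", paste(missing, collapse = ", "))
    design <- as.data.frame(design)
    design$sample_id <- as.character(design$sample_id)
    design$cell_line <- tolower(as.character(design$cell_line))
    design$treatment <- tolower(as.character(design$treatment))
    design$time_h <- as.numeric(design$time_h)
    design$replicate <- as.integer(design$replicate)
    if (any(!is.finite(design$time_h)) || any(design$time_h <= 0))
        stop("time_h must be positive and numeric")
    if (any(is.na(design$replicate)) || any(design$replicate < 1L))
        stop("replicate must be a positive integer")
    design
}

#' @describeIn AnalogueExperiment design table as a plain data.frame, with
#'   sample_id restored as a column
#' @param ae an AnalogueExperiment
#' @export
designTable <- function(ae) {
    cd <- SummarizedExperiment::colData(ae)
    data.frame(sample_id = rownames(cd), as.data.frame(cd),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn AnalogueExperiment the log2 expression matrix
#' @export
exprsMatrix <- function(ae) SummarizedExperiment::assay(ae, "exprs")

#' @describeIn AnalogueExperiment feature identifiers
#' @export
featureIds <- function(ae) rownames(ae)

#' @describeIn AnalogueExperiment sample identifiers
#' @export
sampleIds <- function(ae) colnames(ae)

setMethod("show", "AnalogueExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("AnalogueExperiment:", nrow(object), "features x", ncol(object), "samples\n")
    cat("  cell lines: ", paste(unique(cd$cell_line), collapse = ", "), "\n", sep = "")
    cat("  treatments: ", paste(unique(cd$treatment), collapse = ", "), "\n", sep = "")
    cat("  time points (h): ", paste(sort(unique(cd$time_h)), collapse = ", "), "\n", sep = "")
})

#' Construct a GeneSet
#'
#' @param genes character vector of feature ids (may be empty)
#' @param name set label
#' @param direction optional integer vector of +1/-1 parallel to
#'   \code{genes} (or named by gene)
#' @return a \linkS4class{GeneSet}
#' @export
geneSet <- function(genes, name = NA_character_, direction = integer()) {
    genes <- as.character(genes)
    direction <- as.integer(direction)
    if (length(direction) && !is.null(names(direction)))
        direction <- direction[genes]
    methods::new("GeneSet", name = as.character(name), genes = genes,
                 direction = direction)
}

#' @describeIn geneSet member gene ids
#' @param x a GeneSet
#' @export
geneIds <- function(x) x@genes

#' @describeIn geneSet per-gene directions (named), or empty if unsigned
#' @export
geneDirections <- function(x) {
    if (!length(x@direction)) return(integer())
    setNames(x@direction, x@genes)
}

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@genes), " genes",
        if (length(object@direction)) " (signed)" else "", "\n", sep = "")
    if (length(object@genes))
        cat("  ", paste(head(object@genes, 8), collapse = ", "),
            if (length(object@genes) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "EBayesHyper", function(object) {
    cat("EBayesHyper: d0 =", object@d0, " s0sq =", object@s0sq, "\n")
})

setMethod("show", "GroupMeanFit", function(object) {
    cat("GroupMeanFit:", nrow(object@coefficients), "genes,",
        nrow(object@groups), "groups, residual df =", object@df, "\n")
})

setMethod("show", "ContrastResult", function(object) {
    cat("ContrastResult '", object@name, "': ", nrow(object@table),
        " genes, ", sum(object@table$q < 0.05), " at q < 0.05\n", sep = "")
})

setMethod("show", "ClassifierSet", function(object) {
    cat("ClassifierSet:", length(unique(object@table$gene)), "genes (top",
        object@k, "per time point;", paste(sort(unique(object@table$time_h)),
        collapse = ", "), "h)\n")
})

setMethod("show", "MitogenicScoreTable", function(object) {
    cat("MitogenicScoreTable (", length(object@scores), " compounds)\n", sep = "")
    o <- order(object@ranks, names(object@scores))
    print(data.frame(compound = names(object@scores)[o],
                     score = round(object@scores[o], 3),
                     rank = object@ranks[o], row.names = NULL))
})

setMethod("show", "CtTable", function(object) {
    cat("CtTable:", nrow(object@data), "wells,",
        length(unique(object@data$target_gene)), "genes,",
        length(unique(object@data$condition)), "conditions",
        sprintf("(reference %s, vehicle '%s', max %g cycles)\n",
                object@referenceGene, object@vehicle, object@maxCycles))
})

setMethod("show", "FoldChangeMatrix", function(object) {
    cat("FoldChangeMatrix:", nrow(object@values), "classifier genes x",
        ncol(object@values), "compounds\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@program), "genes (",
        sum(object@program == "mitogenic"), "mitogenic,",
        sum(object@program == "metabolic"), "metabolic )\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes;",
        nrow(object@receptors), "cell lines x", nrow(object@potencies),
        "compounds x", length(object@timePoints), "time points;",
        "reps", object@repsTreated, "(treated) /", object@repsVehicle,
        "(vehicle); d0 =", object@d0, ", s0sq =", object@s0sq, "\n")
})

#' Construct a classifier fold-change matrix
#'
#' @param values numeric matrix of log2 fold changes vs vehicle, classifier
#'   genes x compounds, finite, with unique dimnames
#' @param provenance either one value recycled over compounds or one per
#'   compound; "microarray" or "qpcr"
#' @return a \linkS4class{FoldChangeMatrix}
#' @export
foldChangeMatrix <- function(values, provenance = "microarray") {
    if (length(provenance) == 1L) provenance <- rep(provenance, ncol(values))
    methods::new("FoldChangeMatrix", values = values, provenance = provenance)
}

#' @describeIn foldChangeMatrix the underlying log2FC matrix
#' @param fc a FoldChangeMatrix
#' @export
foldChanges <- function(fc) fc@values

#' Construct a CtTable
#'
#' @param data data.frame with columns target_gene, condition, replicate, ct
#' @param referenceGene housekeeping gene used for normalization (must be
#'   measured in every condition)
#' @param vehicle name of the vehicle condition
#' @param maxCycles maximum cycle number; wells at \code{ct >= maxCycles}
#'   are treated as undetected
#' @return a \linkS4class{CtTable}
#' @export
ctTable <- function(data, referenceGene = "ACTB", vehicle = "vehicle",
                    maxCycles = 40) {
    data <- as.data.frame(data)
    data$target_gene <- as.character(data$target_gene)
    data$condition <- as.character(data$condition)
    methods::new("CtTable", data = data, referenceGene = referenceGene,
                 vehicle = vehicle, maxCycles = maxCycles)
}

#' @describeIn ctTable the well-level data
#' @param x a CtTable
#' @export
ctData <- function(x) x@data
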