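#' @import methods
#' @importFrom stats median pchisq pnorm pt rchisq rlnorm rnorm runif
#'   as.dist cor dist hclust p.adjust quantile sd setNames var ave
#' @importFrom utils read.csv read.delim write.csv write.table head
NULL

.REQUIRED_DESIGN_COLS <- c("sample_id", "cell_line", "treatment", "time_h", "replicate")

#' Expression experiment with an insulin-analogue treatment design
#'
#' An \code{AnalogueExperiment} couples a log2-scale expression matrix
#' (features x samples, assay \code{"exprs"}) with the per-sample factors of
#' a receptor-isoform treatment design: \code{cell_line}, \code{treatment},
#' \code{time_h} (hours) and \code{replicate}. It extends
#' \linkS4class{SummarizedExperiment}, so all the usual accessors
#' (\code{assay}, \code{colData}, subsetting) apply.
#'
#' Validity requires unique, non-missing feature and sample identifiers,
#' all-finite expression values, and the four design columns with
#' lower-case canonical treatment and cell-line tokens.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass AnalogueExperiment
setClass("AnalogueExperiment", contains = "SummarizedExperiment")

setValidity("AnalogueExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        x <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(x)) msg <- c(msg, "assay 'exprs' must be numeric")
        else if (!all(is.finite(x))) msg <- c(msg, "assay 'exprs' contains non-finite values")
    }
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    need <- setdiff(c("cell_line", "treatment", "time_h", "replicate"), colnames(cd))
    if (length(need))
        msg <- c(msg, paste0("missing design column(s): ", paste(need, collapse = ", ")))
    else {
        if (!is.numeric(cd$time_h) || any(cd$time_h <= 0))
            msg <- c(msg, "time_h must be positive")
        if (any(cd$treatment != tolower(cd$treatment)))
            msg <- c(msg, "treatment tokens must be canonical lower case")
    }
    if (length(msg)) msg else TRUE
})

#' Gene set, optionally signed
#'
#' A named collection of feature identifiers, optionally carrying a
#' per-gene direction (+1 upregulated / -1 downregulated). Empty sets are
#' legal (a contrast may call no DEGs).
#'
#' @slot name single descriptive string
#' @slot genes character vector of unique feature ids
#' @slot direction integer vector in \{-1, +1\}; either empty (unsigned
#'   set) or parallel to \code{genes}
#' @exportClass GeneSet
setClass("GeneSet",
    representation(name = "character", genes = "character", direction = "integer"),
    prototype(name = NA_character_, genes = character(), direction = integer()))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
    if (length(object@direction) &&
        (length(object@direction) != length(object@genes) ||
         !all(object@direction %in% c(-1L, 1L))))
        msg <- c(msg, "direction must cover all genes with values in {-1, +1}")
    if (length(msg)) msg else TRUE
})

#' Gene-wise group-mean linear model fit
#'
#' One coefficient per (cell_line, treatment, time_h) stratum, the closed-form
#' least-squares fit for a pure group-means design: coefficients are group
#' means and the residual variance is the pooled within-group variance on
#' \code{n - k} degrees of freedom, identical across genes for a given design.
#'
#' @slot coefficients genes x groups matrix of group means (log2 units)
#' @slot sigma2 per-gene pooled residual variance
#' @slot df residual degrees of freedom (scalar; balanced across genes)
#' @slot groups data.frame with columns group, cell_line, treatment, time_h, n
#' @exportClass GroupMeanFit
setClass("GroupMeanFit",
    representation(coefficients = "matrix", sigma2 = "numeric",
                   df = "numeric", groups = "data.frame"))

setValidity("GroupMeanFit", function(object) {
    msg <- character()
    if (object@df < 1) msg <- c(msg, "residual df must be >= 1")
    if (any(object@sigma2 < 0)) msg <- c(msg, "sigma2 must be non-negative")
    if (ncol(object@coefficients) != nrow(object@groups))
        msg <- c(msg, "coefficient columns must match group table rows")
    if (length(msg)) msg else TRUE
})

#' Empirical-Bayes variance prior hyperparameters
#'
#' The scaled inverse-chi-square prior on gene-wise residual variances:
#' \code{d0} prior degrees of freedom (may be \code{Inf}, meaning all gene
#' variances are shrunk completely to \code{s0sq}) and \code{s0sq} the prior
#' variance. \code{d0 = 0} is admitted as the no-moderation limit, in which
#' the moderated t reduces to the ordinary pooled t.
#'
#' @slot d0 prior degrees of freedom, >= 0, possibly \code{Inf}
#' @slot s0sq prior residual variance, > 0
#' @exportClass EBayesHyper
setClass("EBayesHyper", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("EBayesHyper", function(object) {
    msg <- character()
    if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0)
        msg <- c(msg, "d0 must be a single value >= 0 (Inf allowed)")
    if (length(object@s0sq) != 1L || !is.finite(object@s0sq) || object@s0sq <= 0)
        msg <- c(msg, "s0sq must be a single positive finite value")
    if (length(msg)) msg else TRUE
})

#' Result of one moderated-t contrast
#'
#' Per-gene log2 fold change, moderated t statistic, total degrees of
#' freedom, two-sided p value and BH-adjusted q value for one named linear
#' contrast of group means.
#'
#' @slot name contrast label
#' @slot table data.frame with columns gene, log2fc, t, df, p, q
#' @exportClass ContrastResult
setClass("ContrastResult",
    representation(name = "character", table = "data.frame"))

setValidity("ContrastResult", function(object) {
    need <- c("gene", "log2fc", "t", "df", "p", "q")
    msg <- character()
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste0("table must have columns ", paste(need, collapse = ", ")))
    else {
        if (!all(is.finite(object@table$log2fc))) msg <- c(msg, "log2fc must be finite")
        if (any(object@table$q < 0 | object@table$q > 1)) msg <- c(msg, "q must lie in [0,1]")
    }
    if (length(msg)) msg else TRUE
})

#' Selected mitogenic classifier genes
#'
#' The top-k genes per time point separating the strongly mitogenic
#' exposures (X10, IGF1) from insulin in the IGF1R cell line, with the
#' selection statistic and direction of regulation. A gene picked at both
#' time points appears once per time point in the table; the classifier set
#' proper is the union over time points (\code{classifierGenes}).
#'
#' @slot table data.frame with columns gene, time_h, direction, log2fc,
#'   stat, p
#' @slot k genes retained per time point
#' @exportClass ClassifierSet
setClass("ClassifierSet",
    representation(table = "data.frame", k = "integer"))

setValidity("ClassifierSet", function(object) {
    msg <- character()
    need <- c("gene", "time_h", "direction", "log2fc", "stat", "p")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste0("table must have columns ", paste(need, collapse = ", ")))
    else {
        per <- table(object@table$time_h)
        if (length(per) && any(per > object@k))
            msg <- c(msg, "more than k genes stored for a time point")
        if (anyDuplicated(object@table[c("gene", "time_h")]))
            msg <- c(msg, "duplicate (gene, time) entries")
    }
    if (length(msg)) msg else TRUE
})

#' Classifier-gene log2 fold changes per compound
#'
#' Classifier genes x compounds matrix of log2 fold changes versus vehicle,
#' with a per-column provenance flag (microarray or qpcr).
#'
#' @slot values numeric matrix, genes x compounds, all finite
#' @slot provenance character per compound column, "microarray" or "qpcr"
#' @exportClass FoldChangeMatrix
setClass("FoldChangeMatrix",
    representation(values = "matrix", provenance = "character"))

setValidity("FoldChangeMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v) || !all(is.finite(v))) msg <- c(msg, "values must be finite numeric")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "compound names must be present and unique")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "gene names must be present and unique")
    if (length(object@provenance) != ncol(v) ||
        !all(object@provenance %in% c("microarray", "qpcr")))
        msg <- c(msg, "provenance must give 'microarray' or 'qpcr' per compound")
    if (length(msg)) msg else TRUE
})

#' Relative mitogenic potential scores
#'
#' Per-compound score M(c) = sum over classifier genes of |log2FC vs
#' vehicle|, with dense descending ranks (ties share a rank).
#'
#' @slot scores named numeric vector, all >= 0
#' @slot ranks named integer vector, dense ranks, 1 = most mitogenic
#' @exportClass MitogenicScoreTable
setClass("MitogenicScoreTable",
    representation(scores = "numeric", ranks = "integer"))

setValidity("MitogenicScoreTable", function(object) {
    msg <- character()
    if (any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
    if (!identical(names(object@scores), names(object@ranks)))
        msg <- c(msg, "scores and ranks must share names")
    o <- order(object@ranks)
    if (is.unsorted(rev(object@scores[o])))
        msg <- c(msg, "ranks must be consistent with descending scores")
    if (length(msg)) msg else TRUE
})

#' Long-format qPCR cycle-threshold table
#'
#' Rows of (target_gene, condition, replicate, ct) plus the metadata needed
#' for relative quantification: the reference gene (beta-actin by default),
#' the vehicle condition name, and the maximum cycle number (wells at
#' \code{ct >= maxCycles} are "undetected").
#'
#' @slot data data.frame with columns target_gene, condition, replicate, ct
#' @slot referenceGene reference (housekeeping) gene name
#' @slot vehicle name of the vehicle condition
#' @slot maxCycles maximum cycle number, default 40
#' @exportClass CtTable
setClass("CtTable",
    representation(data = "data.frame", referenceGene = "character",
                   vehicle = "character", maxCycles = "numeric"))

setValidity("CtTable", function(object) {
    msg <- character()
    need <- c("target_gene", "condition", "replicate", "ct")
    if (!all(need %in% colnames(object@data)))
        return(paste0("data must have columns ", paste(need, collapse = ", ")))
    d <- object@data
    if (any(!is.finite(d$ct)) || any(d$ct <= 0) || any(d$ct > object@maxCycles))
        msg <- c(msg, sprintf("ct values must lie in (0, %g]", object@maxCycles))
    conds <- unique(d$condition)
    refconds <- unique(d$condition[d$target_gene == object@referenceGene])
    missing_ref <- setdiff(conds, refconds)
    if (length(missing_ref))
        msg <- c(msg, paste0("reference gene '", object@referenceGene,
                             "' not measured in condition(s): ",
                             paste(missing_ref, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic analogue experiment
#'
#' Encodes the study conditions the generator emulates: gene programs with
#' planted log2 effect sizes, compound potencies (mitogenic m_c and
#' metabolic b_c in [0,1]), per-cell-line receptor responsiveness, the
#' replicate arity (triplicate treated, quadruplicate vehicle), time points,
#' and the scaled inverse-chi-square variance prior (d0, s0sq) the
#' empirical-Bayes model assumes.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nGenes = "integer", programs = "data.frame",
                   potencies = "data.frame", receptors = "data.frame",
                   timePoints = "numeric", timeWeights = "matrix",
                   earlyFraction = "numeric",
                   repsTreated = "integer", repsVehicle = "integer",
                   d0 = "numeric", s0sq = "numeric",
                   baselineMean = "numeric", baselineSd = "numeric",
                   varianceContamination = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (sum(object@programs$size) > object@nGenes)
        msg <- c(msg, "program gene counts sum beyond nGenes")
    pot <- object@potencies
    if (any(pot$mitogenic < 0 | pot$mitogenic > 1 | pot$metabolic < 0 | pot$metabolic > 1))
        msg <- c(msg, "potencies must lie in [0,1]")
    if (!"vehicle" %in% pot$compound) msg <- c(msg, "a vehicle compound is required")
    if (object@d0 <= 0 || object@s0sq <= 0) msg <- c(msg, "d0 and s0sq must be positive")
    if (object@repsTreated < 2L || object@repsVehicle < 2L)
        msg <- c(msg, "replicate arities must be >= 2")
    if (!identical(sort(rownames(object@timeWeights)),
                   sort(c("mitogenic_early", "mitogenic_late", "metabolic"))))
        msg <- c(msg, "timeWeights rows must be mitogenic_early, mitogenic_late, metabolic")
    if (!identical(colnames(object@timeWeights), as.character(object@timePoints)))
        msg <- c(msg, "timeWeights columns must match timePoints")
    if (object@earlyFraction < 0 || object@earlyFraction > 1)
        msg <- c(msg, "earlyFraction must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic experiment
#'
#' Per-gene program label (mitogenic / metabolic / null), temporal subclass
#' for mitogenic genes (immediate-early vs late), signed log2 loading and
#' true residual variance; plus the program-level mean-shift table Delta per
#' (compound, cell_line, time_h) and the configured potencies. The shift of
#' gene g under a condition is Delta[subclass of g] * loading(g); null genes
#' have loading 0 and vehicle rows are identically 0.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(program = "character", subclass = "character",
                   loading = "numeric", sigma2 = "numeric",
                   delta = "data.frame", potencies = "data.frame"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (any(object@loading[object@program == "null"] != 0))
        msg <- c(msg, "null genes must have zero loading")
    veh <- object@delta[object@delta$compound == "vehicle",
                        c("mitogenic_early", "mitogenic_late", "metabolic")]
    if (nrow(veh) && any(as.matrix(veh) != 0))
        msg <- c(msg, "vehicle shifts must be identically zero")
    if (any(object@sigma2 <= 0)) msg <- c(msg, "true variances must be positive")
    if (length(msg)) msg else TRUE
})
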