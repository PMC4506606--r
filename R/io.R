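#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature identifiers
#' and whose header row holds sample identifiers. Values must be numeric and
#' complete: a missing or non-numeric cell is an error reported with its
#' row/column coordinates (missing values are rejected rather than imputed,
#' matching RMA-style input which contains none).
#'
#' @param path file path
#' @return numeric matrix with feature ids as rownames and sample ids as
#'   colnames, in file order
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE)
    if (ncol(raw) < 2L) stop("expected a feature id column plus >= 1 sample column")
    ids <- raw[[1L]]
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(ids))
        stop("duplicate feature id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(samples))
        stop("duplicate sample id(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) | vals %in% c("NA", ""), arr.ind = TRUE)
    if (nrow(bad)) {
        b <- bad[1L, ]
        stop(sprintf(
            "missing or non-numeric value '%s' at feature '%s' (row %d), sample '%s' (column %d)",
            vals[b[1L], b[2L]], ids[b[1L]], b[1L], samples[b[2L]], b[2L]))
    }
    if (!all(is.finite(num))) stop("non-finite value in expression matrix")
    dimnames(num) <- list(ids, samples)
    num
}

#' Write a log2 expression matrix as TSV
#'
#' Inverse of \code{readExpressionMatrix}: first column \code{feature_id},
#' full double precision ("." decimal separator).
#'
#' @param mat numeric matrix with dimnames
#' @param path output path
#' @export
writeExpressionMatrix <- function(mat, path) {
    df <- data.frame(feature_id = rownames(mat),
                     format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a design table from CSV
#'
#' Requires columns sample_id, cell_line, treatment, time_h, replicate.
#' Treatment and cell-line tokens are normalized to canonical lower case
#' ("X10" and "x10" load identically).
#'
#' @param path file path
#' @return data.frame with the five canonical columns
#' @export
readDesignTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    d <- read.csv(path, stringsAsFactors = FALSE)
    d <- .canonicalizeDesign(d)
    if (anyDuplicated(d$sample_id))
        stop("duplicated sample_id: ",
             paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
    d[.REQUIRED_DESIGN_COLS]
}

#' @rdname readDesignTable
#' @param design design data.frame
#' @param path output path
#' @export
writeDesignTable <- function(design, path) {
    write.csv(design[.REQUIRED_DESIGN_COLS], path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Validate an expression matrix against a design table
#'
#' Checks that the matrix and design describe the same samples (a mismatch
#' is an error listing the offending ids) and reports the replicate count of
#' every (cell_line, treatment, time_h) group. Groups with fewer than two
#' replicates, and strata that lack a vehicle group, are recorded as
#' failures: every downstream contrast needs >= 2 replicates per group and a
#' matched vehicle.
#'
#' @param mat numeric expression matrix (features x samples)
#' @param design design data.frame
#' @return list with elements \code{groups} (data.frame: cell_line,
#'   treatment, time_h, n), \code{failures} (character, empty when clean)
#'   and \code{ok} (logical)
#' @export
validateDataset <- function(mat, design) {
    design <- .canonicalizeDesign(design)
    extra_m <- setdiff(colnames(mat), design$sample_id)
    extra_d <- setdiff(design$sample_id, colnames(mat))
    if (length(extra_m) || length(extra_d))
        stop("matrix/design sample mismatch; matrix-only: [",
             paste(extra_m, collapse = ", "), "] design-only: [",
             paste(extra_d, collapse = ", "), "]")
    grp <- aggregate(list(n = design$sample_id),
                     by = design[c("cell_line", "treatment", "time_h")],
                     FUN = length)
    failures <- character()
    low <- grp[grp$n < 2L, , drop = FALSE]
    if (nrow(low))
        failures <- c(failures, sprintf(
            "group (%s, %s, %g h) has %d replicate(s); >= 2 required",
            low$cell_line, low$treatment, low$time_h, low$n))
    strata <- unique(grp[c("cell_line", "time_h")])
    for (i in seq_len(nrow(strata))) {
        sub <- grp[grp$cell_line == strata$cell_line[i] &
                   grp$time_h == strata$time_h[i], ]
        if (!"vehicle" %in% sub$treatment && any(sub$treatment != "vehicle"))
            failures <- c(failures, sprintf(
                "no vehicle group for stratum (%s, %g h)",
                strata$cell_line[i], strata$time_h[i]))
    }
    list(groups = grp, failures = failures, ok = length(failures) == 0L)
}

#' @importFrom stats aggregate
NULL

#' Read and write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated \code{name}, description,
#' then gene ids. Signed sets append a \code{"+"} or \code{"-"} suffix to
#' each gene id; the suffix is parsed back into the per-gene direction.
#'
#' @param path file path
#' @return \code{readGMT}: named list of \linkS4class{GeneSet}
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        if (length(f) < 2L) stop("malformed GMT line: ", l)
        ids <- f[-(1:2)]
        ids <- ids[nzchar(ids)]
        signed <- length(ids) && all(grepl("[+-]$", ids))
        if (signed) {
            dir <- ifelse(substring(ids, nchar(ids)) == "+", 1L, -1L)
            ids <- substring(ids, 1L, nchar(ids) - 1L)
            geneSet(ids, name = f[1L], direction = dir)
        } else geneSet(ids, name = f[1L])
    })
    names(sets) <- vapply(sets, function(s) s@name, character(1))
    sets
}

#' @rdname readGMT
#' @param sets a GeneSet or list of GeneSets
#' @param description description field (second GMT column)
#' @export
writeGMT <- function(sets, path, description = "") {
    if (methods::is(sets, "GeneSet")) sets <- list(sets)
    lines <- vapply(sets, function(s) {
        ids <- s@genes
        if (length(s@direction))
            ids <- paste0(ids, ifelse(s@direction > 0L, "+", "-"))
        paste(c(s@name, description, ids), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
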