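# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards (no hidden state leaks).
.withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.defaultPotencies <- function() {
    data.frame(
        compound  = c("vehicle", "insulin", "glargine", "x10", "igf1"),
        mitogenic = c(0,         0.15,      0.75,       0.85,  1.00),
        metabolic = c(0,         1.00,      0.90,       0.95,  0.30),
        stringsAsFactors = FALSE)
}

.defaultReceptors <- function() {
    data.frame(cell_line = c("ira", "irb", "igf1r"),
               igf1r = c(0.10, 0.10, 1.00),
               insr  = c(1.00, 1.00, 0.15),
               stringsAsFactors = FALSE)
}

#' Configure a synthetic analogue experiment
#'
#' Defaults encode the study layout the generator emulates: three
#' receptor-isoform cell lines (IRA, IRB, IGF1R) x five treatments
#' (vehicle, insulin, glargine, X10, IGF1) x two time points (1 h, 6 h),
#' triplicate treated and quadruplicate vehicle samples. Gene-wise
#' variances follow a scaled inverse-chi-square prior (d0, s0sq), the
#' assumption under which the moderated t is exact, so hyperparameter
#' recovery is a meaningful test; \code{varianceContamination} mixes in a
#' log-normal fraction to probe robustness. Mitogenic genes split into an
#' immediate-early subclass (stronger at 1 h) and a late subclass
#' (stronger at 6 h), and metabolic responses are broader at 6 h, via
#' \code{timeWeights}.
#'
#' @param nGenes number of genes (default 20000)
#' @param programs data.frame(program, size, effect): planted gene
#'   programs; \code{effect} is the absolute log2 loading of member genes;
#'   genes outside all programs are null
#' @param potencies data.frame(compound, mitogenic, metabolic) with
#'   potencies in [0, 1]; must include a zero-potency vehicle
#' @param receptors data.frame(cell_line, igf1r, insr) receptor
#'   responsiveness weights
#' @param timePoints time points in hours (default 1 and 6)
#' @param timeWeights 3 x length(timePoints) matrix, rows mitogenic_early,
#'   mitogenic_late, metabolic
#' @param earlyFraction fraction of mitogenic genes in the immediate-early
#'   subclass (default 0.5)
#' @param repsTreated,repsVehicle replicates per treated / vehicle group
#' @param d0,s0sq variance prior: prior degrees of freedom and prior
#'   variance (log2^2 units)
#' @param baselineMean,baselineSd gene baseline distribution on the log2
#'   scale
#' @param varianceContamination fraction of genes whose variance is drawn
#'   log-normal instead of from the prior (default 0)
#' @param seed integer seed; identical seeds give bit-identical output
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(nGenes = 20000,
                             programs = data.frame(
                                 program = c("mitogenic", "metabolic"),
                                 size = c(200L, 300L),
                                 effect = c(1.0, 0.8)),
                             potencies = .defaultPotencies(),
                             receptors = .defaultReceptors(),
                             timePoints = c(1, 6),
                             timeWeights = NULL,
                             earlyFraction = 0.5,
                             repsTreated = 3L, repsVehicle = 4L,
                             d0 = 4, s0sq = 0.04,
                             baselineMean = 7, baselineSd = 1.5,
                             varianceContamination = 0,
                             seed = 1L) {
    if (is.null(timeWeights)) {
        timeWeights <- rbind(mitogenic_early = c(1.0, 0.15),
                             mitogenic_late  = c(0.15, 1.0),
                             metabolic       = c(0.5, 1.0))[, seq_along(timePoints), drop = FALSE]
        colnames(timeWeights) <- as.character(timePoints)
    }
    potencies$compound <- tolower(potencies$compound)
    receptors$cell_line <- tolower(receptors$cell_line)
    methods::new("SimulationConfig", nGenes = as.integer(nGenes),
                 programs = programs, potencies = potencies,
                 receptors = receptors, timePoints = timePoints,
                 timeWeights = timeWeights, earlyFraction = earlyFraction,
                 repsTreated = as.integer(repsTreated),
                 repsVehicle = as.integer(repsVehicle),
                 d0 = d0, s0sq = s0sq, baselineMean = baselineMean,
                 baselineSd = baselineSd,
                 varianceContamination = varianceContamination,
                 seed = as.integer(seed))
}

# Program-level mean-shift table: one row per (compound, cell line, time),
# columns give the shift multiplier for each gene subclass; a gene's mean
# shift is multiplier x its signed loading.
.deltaTable <- function(config) {
    grid <- expand.grid(compound = config@potencies$compound,
                        cell_line = config@receptors$cell_line,
                        time_h = config@timePoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- config@potencies$mitogenic[match(grid$compound, config@potencies$compound)]
    b <- config@potencies$metabolic[match(grid$compound, config@potencies$compound)]
    wI <- config@receptors$igf1r[match(grid$cell_line, config@receptors$cell_line)]
    wN <- config@receptors$insr[match(grid$cell_line, config@receptors$cell_line)]
    tw <- config@timeWeights[, as.character(grid$time_h), drop = FALSE]
    grid$mitogenic_early <- m * wI * tw["mitogenic_early", ]
    grid$mitogenic_late  <- m * wI * tw["mitogenic_late", ]
    grid$metabolic       <- b * wN * tw["metabolic", ]
    grid
}

#' Simulate a full analogue experiment
#'
#' Generates a log2 expression matrix under the generative model the
#' downstream statistics assume: value(g, s) = mu0_g + Delta(compound,
#' cell line, time) * loading_g + noise, with gene variances drawn from the
#' scaled inverse-chi-square prior sigma_g^2 ~ s0sq * d0 / chisq(d0). The
#' mean shift of a mitogenic gene scales with the compound's mitogenic
#' potency times the cell line's IGF1R weight (modulated by the
#' immediate-early/late time profile); a metabolic gene's shift scales with
#' the metabolic potency times the INSR weight. Identical seeds give
#' bit-identical output, and the caller's RNG state is left untouched.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with \code{experiment} (an
#'   \linkS4class{AnalogueExperiment}) and \code{truth} (a
#'   \linkS4class{SyntheticTruth})
#' @export
simulateExperiment <- function(config) {
    methods::validObject(config)
    .withSeed(config@seed, {
        n <- config@nGenes
        genes <- sprintf("G%05d", seq_len(n))
        program <- rep("null", n)
        subclass <- rep("null", n)
        loading <- numeric(n)
        at <- 1L
        for (i in seq_len(nrow(config@programs))) {
            pr <- config@programs$program[i]
            sz <- config@programs$size[i]
            if (sz == 0L) next
            idx <- at:(at + sz - 1L)
            program[idx] <- pr
            loading[idx] <- config@programs$effect[i] *
                sample(c(-1, 1), sz, replace = TRUE)
            if (pr == "mitogenic") {
                nEarly <- round(sz * config@earlyFraction)
                subclass[idx] <- rep(c("mitogenic_early", "mitogenic_late"),
                                     c(nEarly, sz - nEarly))
            } else if (pr == "metabolic") {
                subclass[idx] <- "metabolic"
            }
            at <- at + sz
        }
        sigma2 <- config@s0sq * config@d0 / rchisq(n, df = config@d0)
        if (config@varianceContamination > 0) {
            nc <- round(n * config@varianceContamination)
            if (nc > 0) {
                idx <- sample.int(n, nc)
                sigma2[idx] <- rlnorm(nc, meanlog = log(config@s0sq), sdlog = 1)
            }
        }
        mu0 <- rnorm(n, config@baselineMean, config@baselineSd)
        delta <- .deltaTable(config)
        design <- do.call(rbind, lapply(seq_len(nrow(delta)), function(i) {
            reps <- if (delta$compound[i] == "vehicle") config@repsVehicle
                    else config@repsTreated
            data.frame(sample_id = sprintf("%s_%s_%gh_r%d", delta$cell_line[i],
                                           delta$compound[i], delta$time_h[i],
                                           seq_len(reps)),
                       cell_line = delta$cell_line[i],
                       treatment = delta$compound[i],
                       time_h = delta$time_h[i], replicate = seq_len(reps),
                       stringsAsFactors = FALSE)
        }))
        condIdx <- match(groupKey(design$cell_line, design$treatment, design$time_h),
                         groupKey(delta$cell_line, delta$compound, delta$time_h))
        shiftBySub <- rbind(mitogenic_early = delta$mitogenic_early,
                            mitogenic_late = delta$mitogenic_late,
                            metabolic = delta$metabolic,
                            null = 0)
        x <- matrix(NA_real_, n, nrow(design),
                    dimnames = list(genes, design$sample_id))
        sdg <- sqrt(sigma2)
        for (s in seq_len(nrow(design))) {
            mult <- shiftBySub[subclass, condIdx[s]]
            x[, s] <- mu0 + loading * mult + rnorm(n, 0, sdg)
        }
        truth <- methods::new("SyntheticTruth",
            program = setNames(program, genes),
            subclass = setNames(subclass, genes),
            loading = setNames(loading, genes),
            sigma2 = setNames(sigma2, genes),
            delta = delta, potencies = config@potencies)
        list(experiment = AnalogueExperiment(x, design), truth = truth)
    })
}

#' Planted mean shift of one gene under one condition
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param gene,compound,cellLine,timeH the gene and condition
#' @return the true mean log2 shift of \code{gene}
#' @export
trueShift <- function(truth, gene, compound, cellLine, timeH) {
    row <- which(truth@delta$compound == tolower(compound) &
                 truth@delta$cell_line == tolower(cellLine) &
                 truth@delta$time_h == timeH)
    if (!length(row)) stop("no such condition in truth table")
    sub <- truth@subclass[gene]
    mult <- if (sub == "null") 0 else truth@delta[row, sub]
    unname(mult * truth@loading[gene])
}

#' Simulate a long-format qPCR Ct table
#'
#' Mirrors the qPCR measurement model under perfect amplification
#' efficiency: one log2 fold change equals one cycle, so the Ct of a target
#' gene under a condition is its baseline Ct minus the planted mean shift,
#' plus well noise. The reference gene is unaffected by treatment. Each
#' (gene, condition) gets \code{replicates} wells. Genes listed in
#' \code{undetected} yield Ct = maxCycles in every well (no amplicon).
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param genes character vector (or GeneSet) of target genes; must exist
#'   in the truth object and must not contain the reference gene
#' @param referenceGene housekeeping gene name (default "ACTB")
#' @param cellLine,timeH condition stratum the panel is measured in
#' @param compounds compounds to measure; default: every compound in the
#'   truth table (vehicle included)
#' @param replicates wells per (gene, condition); default 3
#' @param noiseSd well-level Ct noise in cycles (default 0.15; 0 gives
#'   exact recovery of planted fold changes)
#' @param ct0Range baseline Ct range targets are drawn from
#' @param refCt0 baseline Ct of the reference gene
#' @param undetected genes reported as undetected (Ct = maxCycles)
#' @param maxCycles maximum cycle number (default 40)
#' @param seed integer seed
#' @return a \linkS4class{CtTable}
#' @export
simulateCtTable <- function(truth, genes, referenceGene = "ACTB",
                            cellLine = "igf1r", timeH = 1,
                            compounds = NULL, replicates = 3L,
                            noiseSd = 0.15, ct0Range = c(22, 28),
                            refCt0 = 17, undetected = character(),
                            maxCycles = 40, seed = 1L) {
    genes <- .genesOf(genes)
    if (referenceGene %in% genes)
        stop("reference gene '", referenceGene, "' must not be a target gene")
    unknown <- setdiff(genes, names(truth@loading))
    if (length(unknown))
        stop("gene(s) not in truth: ", paste(unknown, collapse = ", "))
    if (is.null(compounds))
        compounds <- unique(truth@delta$compound)
    compounds <- union("vehicle", tolower(compounds))
    .withSeed(seed, {
        ct0 <- setNames(runif(length(genes), ct0Range[1L], ct0Range[2L]), genes)
        rows <- list()
        for (g in genes) {
            for (cmp in compounds) {
                shift <- trueShift(truth, g, cmp, cellLine, timeH)
                ct <- if (g %in% undetected) rep(maxCycles, replicates)
                      else ct0[g] - shift + rnorm(replicates, 0, noiseSd)
                rows[[length(rows) + 1L]] <- data.frame(
                    target_gene = g, condition = cmp,
                    replicate = seq_len(replicates), ct = ct,
                    stringsAsFactors = FALSE)
            }
        }
        for (cmp in compounds) {
            rows[[length(rows) + 1L]] <- data.frame(
                target_gene = referenceGene, condition = cmp,
                replicate = seq_len(replicates),
                ct = refCt0 + rnorm(replicates, 0, noiseSd),
                stringsAsFactors = FALSE)
        }
        d <- do.call(rbind, rows)
        d$ct <- pmin(pmax(d$ct, 1e-3), maxCycles)
        ctTable(d, referenceGene = referenceGene, vehicle = "vehicle",
                maxCycles = maxCycles)
    })
}

#' Deterministic compound potency fixture
#'
#' A fixed 18-gene x 10-compound log2 fold-change matrix emulating the
#' validated classifier panel measured across the commercial insulin
#' analogue set. Potencies are planted in the order IGF1 > glargine > X10 >
#' lispro > insulin > aspart > M2 > M1 > glulisine > detemir. Gene rows
#' carry the panel members the study names (EGR1-EGR4, TNFRSF11B, SLC1A2,
#' FHL2, NR4A3, CTGF, POLQ, RBM6, MALL, PHLDA1) plus synthetic stand-in
#' immediate-early genes completing the 18; SLC1A2, POLQ and RBM6 are the
#' downregulated members. The three high-potency compounds additionally
#' share a saturating IGF1R-specific program over seven genes, which the
#' weakly mitogenic analogues barely touch, so hierarchical clustering
#' groups glargine with IGF1 and X10. The fixture contains no randomness.
#'
#' @return list with \code{foldChanges} (a \linkS4class{FoldChangeMatrix},
#'   provenance "qpcr"), \code{expectedOrder} (compounds, most to least
#'   mitogenic as planted) and \code{potencies} (the planted graded
#'   potencies)
#' @export
makePotencyFixture <- function() {
    graded <- c(EGR1 = 2.6, EGR2 = 2.1, EGR3 = 1.9, EGR4 = 2.4, MALL = 1.1,
                PHLDA1 = 1.3, DUSP4 = 1.0, SGK1 = 0.9, BTG2 = 0.8,
                ARC = 1.2, FOSB = 1.4)
    saturating <- c(TNFRSF11B = 1.6, SLC1A2 = -1.8, FHL2 = 1.4, NR4A3 = 1.7,
                    CTGF = 1.5, POLQ = -1.2, RBM6 = -1.0)
    potency <- c(igf1 = 1.00, glargine = 0.60, x10 = 0.46, lispro = 0.30,
                 insulin = 0.285, aspart = 0.27, m2 = 0.20, m1 = 0.155,
                 glulisine = 0.125, detemir = 0.105)
    satFactor <- c(igf1 = 1.00, glargine = 0.92, x10 = 0.85)
    b <- ifelse(names(potency) %in% names(satFactor),
                satFactor[names(potency)], 0.18 * potency)
    m <- rbind(outer(graded, potency),
               outer(saturating, setNames(b, names(potency))))
    list(foldChanges = foldChangeMatrix(m, provenance = "qpcr"),
         expectedOrder = names(potency),
         potencies = potency)
}
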