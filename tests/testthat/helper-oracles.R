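# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct implementation-by-definition, kept free of any
# package internals so it can stand as an independent route.

# Benjamini-Hochberg step-up, literally: q_(i) = min_{j>=i} p_(j) * m / j,
# capped at 1, mapped back to input order.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        suffix <- vapply(i:m, function(j) (m / j) * p[o[j]], numeric(1))
        q[o[i]] <- min(1, suffix)
    }
    q
}

# Direct-sweep Tukey median polish; returns per-sample summaries
# (overall + column effects). No shortcuts, tight convergence.
medianPolishOracle <- function(z, maxiter = 1000L, eps = 1e-13) {
    t_all <- 0
    row_eff <- rep(0, nrow(z))
    col_eff <- rep(0, ncol(z))
    for (iter in seq_len(maxiter)) {
        before <- z
        rd <- apply(z, 1, median)
        z <- z - rd
        row_eff <- row_eff + rd
        d <- median(col_eff); col_eff <- col_eff - d; t_all <- t_all + d
        cd <- apply(z, 2, median)
        z <- sweep(z, 2, cd)
        col_eff <- col_eff + cd
        d <- median(row_eff); row_eff <- row_eff - d; t_all <- t_all + d
        if (max(abs(z - before)) < eps) break
    }
    t_all + col_eff
}

# Sample PCA by brute-force eigendecomposition of the sample Gram matrix
# of the gene-centered data.
pcaOracle <- function(x, nComponents) {
    y <- t(x - rowMeans(x))                  # samples x genes
    C <- y %*% t(y)
    e <- eigen(C, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    scores <- e$vectors[, seq_len(nComponents), drop = FALSE] %*%
        diag(sqrt(lam[seq_len(nComponents)]), nComponents)
    list(scores = scores, varianceExplained = lam / sum(lam))
}

# A minimal two-group experiment from explicit per-group values.
makeTwoGroupExperiment <- function(values_a, values_b, gene_ids = NULL) {
    stopifnot(is.matrix(values_a), is.matrix(values_b),
              nrow(values_a) == nrow(values_b))
    if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(values_a)))
    na <- ncol(values_a); nb <- ncol(values_b)
    m <- cbind(values_a, values_b)
    dimnames(m) <- list(gene_ids, sprintf("s%02d", seq_len(na + nb)))
    d <- data.frame(sample_id = colnames(m), cell_line = "igf1r",
                    treatment = rep(c("vehicle", "x10"), c(na, nb)),
                    time_h = 1, replicate = c(seq_len(na), seq_len(nb)))
    AnalogueExperiment(m, d)
}

# Single-stratum simulation config (one cell line, one time point, flat
# time profile) used where the test wants direct control of effect sizes.
singleStratumConfig <- function(nGenes, nMitogenic = 0L, effect = 1,
                                treatments = c("vehicle", "insulin", "x10", "igf1"),
                                mitogenicPotency = c(vehicle = 0, insulin = 0,
                                                     x10 = 1, igf1 = 1),
                                repsTreated = 3L, repsVehicle = 4L,
                                d0 = 4, s0sq = 0.04, seed = 1L) {
    pots <- data.frame(compound = treatments,
                       mitogenic = unname(mitogenicPotency[treatments]),
                       metabolic = 0)
    tw <- matrix(1, 3, 1, dimnames = list(
        c("mitogenic_early", "mitogenic_late", "metabolic"), "1"))
    simulationConfig(
        nGenes = nGenes,
        programs = data.frame(program = "mitogenic", size = as.integer(nMitogenic),
                              effect = effect),
        potencies = pots,
        receptors = data.frame(cell_line = "igf1r", igf1r = 1, insr = 0),
        timePoints = 1, timeWeights = tw,
        repsTreated = repsTreated, repsVehicle = repsVehicle,
        d0 = d0, s0sq = s0sq, seed = seed)
}

# The classifier-training conditions: one IGF1R line, the three training
# treatments plus vehicle, two time points with transient immediate-early /
# late mitogenic programs, triplicate treated samples.
classifierTrainingConfig <- function(nGenes = 5000, nMitogenic = 20L,
                                     effect = 1.5, seed = 1L) {
    tw <- rbind(mitogenic_early = c(1, 0.15), mitogenic_late = c(0.15, 1),
                metabolic = c(0.5, 1))
    colnames(tw) <- c("1", "6")
    simulationConfig(
        nGenes = nGenes,
        programs = data.frame(program = "mitogenic", size = as.integer(nMitogenic),
                              effect = effect),
        potencies = data.frame(compound = c("vehicle", "insulin", "x10", "igf1"),
                               mitogenic = c(0, 0, 1, 1), metabolic = 0),
        receptors = data.frame(cell_line = "igf1r", igf1r = 1, insr = 0),
        timePoints = c(1, 6), timeWeights = tw,
        repsTreated = 3L, repsVehicle = 4L,
        d0 = 4, s0sq = 0.04, seed = seed)
}

classifierRecovery <- function(seed, nGenes = 5000, nMitogenic = 20L) {
    sim <- simulateExperiment(classifierTrainingConfig(nGenes, nMitogenic,
                                                       seed = seed))
    fit <- fitGroupMeans(sim$experiment)
    hy <- estimateEBayesHyper(fit)
    cs <- selectClassifierGenes(fit, hy, k = 10)
    planted <- names(sim$truth@program)[sim$truth@program == "mitogenic"]
    length(intersect(classifierGenes(cs), planted))
}

randomGeneSets <- function(nSets, universe = sprintf("g%02d", 1:20)) {
    sets <- lapply(seq_len(nSets), function(i)
        sample(universe, sample.int(length(universe), 1)))
    names(sets) <- LETTERS[seq_len(nSets)]
    sets
}
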