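test_that("mitogenic potential score is the sum of absolute fold changes", {
    m <- matrix(c(0, 0, 0, 1, -1, 2), 3, 2,
                dimnames = list(paste0("g", 1:3), c("veh_like", "x10")))
    fc <- foldChangeMatrix(m)
    expect_equal(mitogenicPotentialScore(fc, "veh_like"), 0)
    expect_equal(mitogenicPotentialScore(fc, "x10"), 4)
    expect_error(mitogenicPotentialScore(fc, "nope"), "unknown compound")
})

test_that("score properties: sign/order invariance, exact additivity, homogeneity", {
    set.seed(41)
    for (i in 1:50) {
        ng <- sample(4:12, 1); nc <- sample(2:5, 1)
        m <- matrix(rnorm(ng * nc), ng, nc,
                    dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc)))
        fc <- foldChangeMatrix(m)
        s <- mitogenicScores(rankCompounds(fc))
        # sign flips and gene reordering leave scores unchanged
        flip <- sample(c(-1, 1), ng, replace = TRUE)
        perm <- sample(ng)
        fc2 <- foldChangeMatrix((m * flip)[perm, , drop = FALSE])
        expect_equal(mitogenicScores(rankCompounds(fc2)), s)
        # exact additivity over a disjoint gene split
        half <- seq_len(floor(ng / 2))
        sA <- colSums(abs(m[half, , drop = FALSE]))
        sB <- colSums(abs(m[-half, , drop = FALSE]))
        expect_equal(unname(s), unname(sA + sB))
        # homogeneity: doubling fold changes doubles scores, ranks unchanged
        dbl <- rankCompounds(foldChangeMatrix(2 * m))
        expect_equal(mitogenicScores(dbl), 2 * s)
        expect_identical(compoundRanks(dbl), compoundRanks(rankCompounds(fc)))
    }
})

test_that("tied compounds share a dense rank", {
    m <- cbind(a = c(1, 2), b = c(-1, -2), c = c(3, 3))
    rownames(m) <- c("g1", "g2")
    st <- rankCompounds(foldChangeMatrix(m))
    expect_identical(unname(compoundRanks(st)[c("a", "b")]), c(2L, 2L))
    expect_identical(unname(compoundRanks(st)[["c"]]), 1L)
})

test_that("the potency fixture reproduces the planted compound ordering", {
    fx <- makePotencyFixture()
    st <- rankCompounds(fx$foldChanges)
    expect_identical(names(sort(compoundRanks(st))), fx$expectedOrder)
    expect_identical(names(which(compoundRanks(st) == 1L)), "igf1")
    expect_identical(fx$expectedOrder[1:3], c("igf1", "glargine", "x10"))
    expect_true(all(compoundRanks(st)[c("glulisine", "detemir")] >= 9L))
    # the panel carries the named validated genes
    expect_true(all(c(paste0("EGR", 1:4), "TNFRSF11B", "SLC1A2", "FHL2",
                      "NR4A3", "CTGF", "POLQ", "RBM6") %in%
                    rownames(foldChanges(fx$foldChanges))))
    expect_identical(nrow(foldChanges(fx$foldChanges)), 18L)
    # deterministic: identical across calls
    expect_identical(foldChanges(makePotencyFixture()$foldChanges),
                     foldChanges(fx$foldChanges))
    # and perfectly rank-correlated with the planted potencies
    expect_equal(correlateExternal(st, fx$potencies)$rho, 1)
})

test_that("compound clustering merges near profiles first and is serialized as newick", {
    m <- cbind(a = c(0, 0), b = c(1, 0), c = c(0.99, 0.14), d = c(10, 10))
    rownames(m) <- c("g1", "g2")
    nw <- clusterCompounds(foldChangeMatrix(m))
    tr <- ape::read.tree(text = nw)
    expect_setequal(tr$tip.label, colnames(m))
    # b and c (distance ~0.17) are sisters
    bc <- ape::getMRCA(tr, c("b", "c"))
    expect_setequal(ape::extract.clade(tr, bc)$tip.label, c("b", "c"))
    # identical columns merge at height zero
    m2 <- cbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
    rownames(m2) <- c("g1", "g2")
    tr2 <- ape::read.tree(text = clusterCompounds(foldChangeMatrix(m2)))
    ab <- ape::getMRCA(tr2, c("a", "b"))
    edge_len <- tr2$edge.length[tr2$edge[, 1] == ab]
    expect_equal(edge_len, c(0, 0))
    expect_error(clusterCompounds(foldChangeMatrix(m2[, 1, drop = FALSE])),
                 ">= 2 compounds")
})

test_that("fixture clustering puts glargine with IGF1 and X10 at the first split", {
    fx <- makePotencyFixture()
    tr <- ape::read.tree(text = clusterCompounds(fx$foldChanges))
    root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
    clades <- lapply(root_children, function(node)
        if (node <= ape::Ntip(tr)) tr$tip.label[node]
        else ape::extract.clade(tr, node)$tip.label)
    strong <- c("igf1", "glargine", "x10")
    expect_true(any(vapply(clades, function(cl) setequal(cl, strong), logical(1))))
})

test_that("external correlation handles perfect, reversed and sparse overlaps", {
    s <- setNames(c(5, 4, 3, 2), c("a", "b", "c", "d"))
    expect_equal(correlateExternal(s, s)$rho, 1)
    expect_equal(correlateExternal(s, setNames(rev(unname(s)), names(s)))$rho, -1)
    expect_equal(correlateExternal(s, s[1:3])$n, 3L)
    expect_error(correlateExternal(s, s[1:2]), ">= 3 shared")
})

test_that("classifier selection recovers planted mitogenic genes", {
    rec <- vapply(71:73, classifierRecovery, numeric(1), nGenes = 2000)
    expect_gte(median(rec), 18)
    cfg <- classifierTrainingConfig(nGenes = 2000, seed = 71L)
    sim <- simulateExperiment(cfg)
    fit <- fitGroupMeans(sim$experiment)
    cs <- selectClassifierGenes(fit, estimateEBayesHyper(fit), k = 10)
    tab <- classifierTable(cs)
    expect_lte(nrow(tab), 20)
    expect_identical(ifelse(tab$log2fc >= 0, 1L, -1L), tab$direction)
})

test_that("glargine is held out: perturbing it cannot change the selection", {
    cfg <- singleStratumConfig(
        nGenes = 500, nMitogenic = 10, effect = 1.5,
        treatments = c("vehicle", "insulin", "glargine", "x10", "igf1"),
        mitogenicPotency = c(vehicle = 0, insulin = 0, glargine = 0.7,
                             x10 = 1, igf1 = 1),
        seed = 73L)
    sim <- simulateExperiment(cfg)
    fit <- fitGroupMeans(sim$experiment)
    hy <- estimateEBayesHyper(fit)
    cs1 <- selectClassifierGenes(fit, hy, timePoints = 1)
    fit2 <- fit
    gl <- groupKey("igf1r", "glargine", 1)
    fit2@coefficients[, gl] <- fit2@coefficients[, gl] + 5   # scramble glargine
    cs2 <- selectClassifierGenes(fit2, hy, timePoints = 1)
    expect_identical(classifierTable(cs1), classifierTable(cs2))
})

test_that("selection is invariant to gene order, with deterministic tie-breaks", {
    cfg <- singleStratumConfig(nGenes = 300, nMitogenic = 8, effect = 1.5, seed = 79L)
    sim <- simulateExperiment(cfg)
    fit <- fitGroupMeans(sim$experiment)
    hy <- estimateEBayesHyper(fit)
    perm <- sample(nrow(fit@coefficients))
    fit_p <- fit
    fit_p@coefficients <- fit@coefficients[perm, ]
    fit_p@sigma2 <- fit@sigma2[perm]
    cs1 <- selectClassifierGenes(fit, hy, timePoints = 1)
    cs2 <- selectClassifierGenes(fit_p, hy, timePoints = 1)
    expect_setequal(classifierGenes(cs1), classifierGenes(cs2))
})

test_that("missing required treatments are reported by name", {
    cfg <- singleStratumConfig(nGenes = 100, treatments = c("vehicle", "insulin", "x10"),
                               mitogenicPotency = c(vehicle = 0, insulin = 0, x10 = 1))
    sim <- simulateExperiment(cfg)
    fit <- fitGroupMeans(sim$experiment)
    expect_error(selectClassifierGenes(fit, eBayesHyper(4, 0.04), timePoints = 1),
                 "igf1")
})

test_that("two disjoint hit lists give a 20-gene union; k bounds hold", {
    cfg <- singleStratumConfig(nGenes = 2000, nMitogenic = 20, effect = 1.5, seed = 83L)
    # two time points with distinct early/late responders
    tw <- rbind(mitogenic_early = c(1, 0.3), mitogenic_late = c(0.3, 1),
                metabolic = c(1, 1))
    colnames(tw) <- c("1", "6")
    cfg@timePoints <- c(1, 6); cfg@timeWeights <- tw
    sim <- simulateExperiment(cfg)
    fit <- fitGroupMeans(sim$experiment)
    hy <- estimateEBayesHyper(fit)
    cs <- selectClassifierGenes(fit, hy, timePoints = c(1, 6), k = 10)
    expect_lte(length(classifierGenes(cs)), 20)
    per_tp <- table(classifierTable(cs)$time_h)
    expect_true(all(per_tp == 10))
})

test_that("between-treatment-variance statistic is available and sane", {
    rec <- vapply(89:91, function(s) {
        cfg <- singleStratumConfig(nGenes = 500, nMitogenic = 10, effect = 1.5,
                                   seed = s)
        sim <- simulateExperiment(cfg)
        fit <- fitGroupMeans(sim$experiment)
        cs <- selectClassifierGenes(fit, eBayesHyper(4, 0.04), timePoints = 1,
                                    stat = "between-treatment-var")
        planted <- names(sim$truth@program)[sim$truth@program == "mitogenic"]
        length(intersect(classifierGenes(cs), planted))
    }, numeric(1))
    expect_gte(median(rec), 7)   # noisier than the contrast-t, still informative
})
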