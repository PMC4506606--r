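#' Fit gene-wise group means
#'
#' Fits, for every gene, the linear model with one coefficient per
#' experimental group (the full crossing cell_line x treatment x time_h).
#' For this pure group-means design the least-squares solution is closed
#' form: coefficients are the group sample means and the residual variance
#' is the pooled within-group variance on \code{n - k} degrees of freedom
#' (identical for all genes). Any group with a single replicate is an
#' error, since it contributes no residual information.
#'
#' @param ae an \linkS4class{AnalogueExperiment}
#' @return a \linkS4class{GroupMeanFit}
#' @export
fitGroupMeans <- function(ae) {
    x <- exprsMatrix(ae)
    d <- designTable(ae)
    key <- groupKey(d$cell_line, d$treatment, d$time_h)
    groups <- unique(data.frame(group = key, cell_line = d$cell_line,
                                treatment = d$treatment, time_h = d$time_h,
                                stringsAsFactors = FALSE))
    groups <- groups[order(groups$cell_line, groups$time_h, groups$treatment), ]
    groups$n <- as.integer(table(key)[groups$group])
    if (any(groups$n < 2L))
        stop("group(s) with a single replicate: ",
             paste(groups$group[groups$n < 2L], collapse = ", "))
    k <- nrow(groups)
    n <- ncol(x)
    df <- n - k
    if (df < 1L) stop("no residual degrees of freedom (n - k < 1)")
    # indicator / n gives group means in one multiply
    ind <- outer(key, groups$group, "==") + 0
    beta <- x %*% sweep(ind, 2L, groups$n, "/")
    colnames(beta) <- groups$group
    fitted <- beta %*% t(ind)
    sigma2 <- rowSums((x - fitted)^2) / df
    methods::new("GroupMeanFit", coefficients = beta, sigma2 = sigma2,
                 df = df, groups = groups)
}

#' @describeIn fitGroupMeans canonical key identifying one experimental
#'   group within the fit
#' @param cellLine,treatment,timeH group factors
#' @export
groupKey <- function(cellLine, treatment, timeH) {
    paste(tolower(cellLine), tolower(treatment), format(timeH), sep = "|")
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments estimation of (d0, s0sq) from the gene-wise residual
#' variances, on the log scale: the mean and variance of log(s_g^2) are
#' matched to their theoretical values under the scaled
#' inverse-chi-square prior, using digamma/trigamma identities. The
#' trigamma equation for d0 is solved by monotone bisection on
#' (0.01, 1e6]; if the between-gene spread of log variances does not
#' exceed the chi-square sampling spread, or the root lies beyond the
#' bracket, d0 = Inf is returned (complete shrinkage). Fewer than 50
#' usable genes, or all-zero variances, is an error: the estimates would
#' be unstable.
#'
#' @param fit a \linkS4class{GroupMeanFit}
#' @return an \linkS4class{EBayesHyper}
#' @export
estimateEBayesHyper <- function(fit) {
    s2 <- fit@sigma2
    if (all(s2 == 0)) stop("all residual variances are zero; degenerate data")
    if (any(s2 == 0)) {
        warning(sum(s2 == 0), " gene(s) with zero residual variance excluded",
                " from hyperparameter estimation")
        s2 <- s2[s2 > 0]
    }
    if (length(s2) < 50L)
        stop("need >= 50 genes with positive residual variance to estimate",
             " the variance prior (have ", length(s2), ")")
    d <- fit@df
    z <- log(s2)
    zbar <- mean(z)
    evar <- var(z) - trigamma(d / 2)
    if (evar <= 0) {
        d0 <- Inf
        s0sq <- exp(zbar - digamma(d / 2) + log(d / 2))
    } else {
        lo <- 0.01; hi <- 1e6
        if (trigamma(hi / 2) >= evar) {
            d0 <- Inf
            s0sq <- exp(zbar - digamma(d / 2) + log(d / 2))
            return(methods::new("EBayesHyper", d0 = d0, s0sq = s0sq))
        }
        if (trigamma(lo / 2) <= evar) {
            d0 <- lo
        } else {
            for (i in 1:200) {        # trigamma is strictly decreasing
                mid <- (lo + hi) / 2
                if (trigamma(mid / 2) > evar) lo <- mid else hi <- mid
                if (hi - lo < 1e-10 * hi) break
            }
            d0 <- (lo + hi) / 2
        }
        s0sq <- exp(zbar - digamma(d / 2) + log(d / 2) +
                    digamma(d0 / 2) - log(d0 / 2))
    }
    methods::new("EBayesHyper", d0 = d0, s0sq = s0sq)
}

#' @rdname estimateEBayesHyper
#' @param d0,s0sq explicit hyperparameter values (d0 may be 0, meaning no
#'   moderation, or Inf, meaning complete shrinkage to s0sq)
#' @export
eBayesHyper <- function(d0, s0sq) methods::new("EBayesHyper", d0 = d0, s0sq = s0sq)

#' Moderated-t contrast of group means
#'
#' Tests a named linear combination of group coefficients with the
#' empirical-Bayes moderated t statistic: the gene variance is shrunk to
#' the posterior value s~^2 = (d0 s0^2 + d s^2) / (d0 + d) (for d0 = Inf,
#' s~^2 = s0^2; for d0 = 0 the ordinary pooled variance, so the statistic
#' reduces to the classical pooled t), the standard error uses the exact
#' group arities, and p values come from a Student t on d + d0 degrees of
#' freedom (normal when d0 = Inf). q values are BH-adjusted within the
#' contrast.
#'
#' @param fit a \linkS4class{GroupMeanFit}
#' @param hyper an \linkS4class{EBayesHyper}
#' @param contrast named numeric vector of weights over group keys (see
#'   \code{\link{groupKey}}); for a difference contrast the weights sum
#'   to 0
#' @param name contrast label stored in the result
#' @return a \linkS4class{ContrastResult}
#' @export
moderatedContrast <- function(fit, hyper, contrast, name = "contrast") {
    unknown <- setdiff(names(contrast), fit@groups$group)
    if (length(unknown))
        stop("unknown group(s) in contrast: ", paste(unknown, collapse = ", "))
    cvec <- setNames(numeric(nrow(fit@groups)), fit@groups$group)
    cvec[names(contrast)] <- contrast
    lfc <- drop(fit@coefficients %*% cvec)
    sef <- sqrt(sum(cvec^2 / fit@groups$n))
    d0 <- hyper@d0; s0sq <- hyper@s0sq; d <- fit@df
    s2post <- if (is.infinite(d0)) rep(s0sq, length(lfc))
              else (d0 * s0sq + d * fit@sigma2) / (d0 + d)
    dft <- d + d0
    if (sef == 0) {
        tmod <- rep(0, length(lfc))
        p <- rep(1, length(lfc))
    } else {
        tmod <- lfc / (sqrt(s2post) * sef)
        tmod[lfc == 0] <- 0          # 0/0 when the posterior variance is 0
        p <- if (is.infinite(dft)) 2 * pnorm(-abs(tmod)) else 2 * pt(-abs(tmod), df = dft)
    }
    tab <- data.frame(gene = rownames(fit@coefficients), log2fc = lfc,
                      t = tmod, df = dft, p = p, q = benjaminiHochberg(p),
                      row.names = NULL, stringsAsFactors = FALSE)
    methods::new("ContrastResult", name = name, table = tab)
}

#' @describeIn moderatedContrast result table as a data.frame
#' @param x a ContrastResult
#' @export
contrastTable <- function(x) x@table

#' All exposure-versus-vehicle contrasts
#'
#' Builds, for every non-vehicle group in the fit, the contrast against the
#' vehicle group of the same (cell_line, time_h) stratum ("each exposure
#' compared with the corresponding vehicle control") and runs the moderated
#' t on each.
#'
#' @param fit a \linkS4class{GroupMeanFit}
#' @param hyper an \linkS4class{EBayesHyper}
#' @return named list of \linkS4class{ContrastResult}, names
#'   \code{"<cell_line>_<treatment>_<time>h"}
#' @export
vehicleContrasts <- function(fit, hyper) {
    g <- fit@groups
    res <- list()
    for (i in which(g$treatment != "vehicle")) {
        veh <- g$group[g$treatment == "vehicle" &
                       g$cell_line == g$cell_line[i] & g$time_h == g$time_h[i]]
        if (!length(veh)) next
        cn <- sprintf("%s_%s_%gh", g$cell_line[i], g$treatment[i], g$time_h[i])
        contrast <- setNames(c(1, -1), c(g$group[i], veh))
        res[[cn]] <- moderatedContrast(fit, hyper, contrast, name = cn)
    }
    res
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) * m / j, capped
#' at 1 and mapped back to input order (ties handled stably).
#'
#' @param p numeric vector of p values in [0, 1]
#' @return vector of q values, same length and order
#' @export
benjaminiHochberg <- function(p) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
        stop("p values must be numeric in [0, 1] with no missing values")
    p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Genes with BH q below \code{alpha}, signed by the direction of the log2
#' fold change. No fold-change cutoff is applied.
#'
#' @param result a \linkS4class{ContrastResult}
#' @param alpha FDR threshold in (0, 1); default 0.05
#' @return a signed \linkS4class{GeneSet} (possibly empty)
#' @export
callDEGs <- function(result, alpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1)
    tab <- result@table
    hit <- tab$q < alpha
    geneSet(tab$gene[hit], name = result@name,
            direction = ifelse(tab$log2fc[hit] >= 0, 1L, -1L))
}
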