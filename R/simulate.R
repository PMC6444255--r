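# Self-contained simulation framework: alternating- and monotonic-effect
# designs plus a configurable generic generator and a replicate runner.

#' Construct a simulation design
#'
#' Per subject, every gene's time course is drawn from a standard-normal
#' process (iid across time, or AR(1) with correlation \code{rho} and standard
#' normal marginals), genes are re-standardized to pooled mean 0 / sd 1, and
#' the phenotype is Bernoulli with
#' \code{logit = intercept + sum(coef * x[gene, timeIndex])} over the causal
#' map.
#'
#' @param causal data.frame with columns \code{gene}, \code{timeIndex},
#'   \code{coef}.
#' @param nSubjects subjects per replicate (default 97, the trauma cohort
#'   size).
#' @param nNoise number of noise genes (default 998).
#' @param times time grid (default the cohort days 0.5, 1, 4, 7, 14).
#' @param intercept logit intercept (default 0: ~50\% prevalence).
#' @param rho AR(1) within-gene temporal correlation (default 0.7).
#' @param covModel \code{"ar1"} or \code{"iid"}.
#' @param dropout per-subject probability of a truncated time course
#'   (default 0: all subjects complete).
#' @return a \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(causal, nSubjects = 97, nNoise = 998,
                             times = c(0.5, 1, 4, 7, 14), intercept = 0,
                             rho = 0.7, covModel = c("ar1", "iid"),
                             dropout = 0) {
    covModel <- match.arg(covModel)
    noise <- sprintf("noise%04d", seq_len(nNoise))
    genes <- c(unique(causal$gene), noise)
    new("SimulationDesign", nSubjects = nSubjects, geneIDs = genes,
        times = times, causal = causal, intercept = intercept, rho = rho,
        covModel = covModel, dropout = dropout)
}

#' Alternating-effect simulation design
#'
#' Two causal genes among 1000: the phenotype logit is
#' \code{0.57 * F13A1_t3 - 0.73 * GSTM1_t2 + 0.38 * GSTM1_t4}, so GSTM1's two
#' causal time points carry opposite-signed coefficients (the alternating
#' effect that defeats a plain mean summary).
#'
#' @param ... overrides passed to [simulationDesign()] (e.g. \code{nSubjects},
#'   \code{rho}).
#' @return a \linkS4class{SimulationDesign}.
#' @export
makeDesignSim1 <- function(...) {
    causal <- data.frame(gene = c("F13A1", "GSTM1", "GSTM1"),
                         timeIndex = c(3L, 2L, 4L),
                         coef = c(0.57, -0.73, 0.38))
    simulationDesign(causal, ...)
}

#' Monotonic-effect simulation design
#'
#' Two causal genes among 1000 with coefficients changing by 0.10 per time
#' step: F13A1 at 0.57, 0.67, 0.77, 0.87, 0.97 and GSTM1 at -1.02, -0.92,
#' -0.82, -0.72, -0.62 across the five time points.
#'
#' @param ... overrides passed to [simulationDesign()].
#' @return a \linkS4class{SimulationDesign}.
#' @export
makeDesignSim2 <- function(...) {
    causal <- data.frame(
        gene = rep(c("F13A1", "GSTM1"), each = 5),
        timeIndex = rep(1:5, 2),
        coef = c(seq(0.57, 0.97, by = 0.10), seq(-1.02, -0.62, by = 0.10)))
    simulationDesign(causal, ...)
}

#' @describeIn simulationDesign the causal coefficient map.
#' @param design a \code{SimulationDesign}.
#' @export
causalMap <- function(design) design@causal

#' @describeIn simulationDesign the causal gene identifiers.
#' @export
causalGenes <- function(design) unique(design@causal$gene)

#' @describeIn simulationDesign phenotype logit for a genes x times covariate
#'   matrix of one subject.
#' @param xmat genes x times matrix (rownames = gene ids).
#' @export
designLogit <- function(design, xmat) {
    design@intercept + sum(design@causal$coef *
        xmat[cbind(match(design@causal$gene, rownames(xmat)),
                   design@causal$timeIndex)])
}

setMethod("show", "SimulationDesign", function(object) {
    cat(sprintf(paste0("SimulationDesign: %d subjects, %d genes ",
                       "(%d causal), %d time points, %s covariates"),
                object@nSubjects, length(object@geneIDs),
                length(causalGenes(object)), length(object@times),
                object@covModel))
    if (object@covModel == "ar1") cat(sprintf(" (rho=%.2f)", object@rho))
    cat("\n")
})

#' Simulate one longitudinal dataset from a design
#'
#' Covariates are drawn per the design's model, each gene is standardized to
#' pooled mean 0 / sd 1 (sample sd) over all subjects and time points, and
#' labels are Bernoulli at the design's logit evaluated on the standardized
#' values. All subjects are complete unless \code{dropout > 0}, in which case
#' an affected subject keeps a random prefix of at least one time point.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param seed integer seed; the same seed reproduces the dataset.
#' @return a \linkS4class{LongitudinalExpressionSet}.
#' @export
simulateDataset <- function(design, seed = 1) {
    G <- length(design@geneIDs); n <- design@nSubjects
    T <- length(design@times)
    withLocalSeed(seed, {
        arr <- array(rnorm(G * n * T), c(G, n, T))
        if (design@covModel == "ar1" && T > 1) {
            rho <- design@rho
            for (t in 2:T)
                arr[, , t] <- rho * arr[, , t - 1] +
                    sqrt(1 - rho^2) * arr[, , t]
        }
        # pooled per-gene standardization (subjects x times)
        flat <- matrix(arr, G, n * T)
        arr <- array((flat - rowMeans(flat)) / apply(flat, 1, sd), c(G, n, T))
        ci <- match(design@causal$gene, design@geneIDs)
        logit <- rep(design@intercept, n)
        for (r in seq_len(nrow(design@causal)))
            logit <- logit + design@causal$coef[r] *
                arr[ci[r], , design@causal$timeIndex[r]]
        y <- rbinom(n, 1, plogis(logit))
        # both classes are required downstream; redraw in the (vanishingly
        # rare) degenerate case
        tries <- 0
        while (length(unique(y)) < 2 && tries < 100) {
            y <- rbinom(n, 1, plogis(logit)); tries <- tries + 1
        }
        keep <- matrix(TRUE, n, T)
        if (design@dropout > 0 && T > 1) {
            drop <- runif(n) < design@dropout
            lastT <- ifelse(drop, sample(seq_len(T - 1), n, replace = TRUE), T)
            for (i in which(drop)) keep[i, (lastT[i] + 1):T] <- FALSE
        }
        subj <- sprintf("S%03d", seq_len(n))
        idx <- which(t(keep))            # (time within subject) order
        tcol <- rep(seq_len(T), n)[idx]
        scol <- rep(seq_len(n), each = T)[idx]
        m <- matrix(0, G, length(idx), dimnames = list(design@geneIDs, NULL))
        for (j in seq_along(idx)) m[, j] <- arr[, scol[j], tcol[j]]
        LongitudinalExpressionSet(m, subj[scol], design@times[tcol],
                                  stats::setNames(y, subj))
    })
}

#' Run a replicate study: simulate, split, fit, evaluate
#'
#' Per replicate: simulate a dataset from the design, split subjects 3:2
#' (stratified), fit the requested pipeline on the training set and evaluate
#' on the test set. The aggregate mirrors the simulation benchmark columns:
#' mean final-model size, pairwise-Jaccard Rand index across the replicate
#' gene lists, per-causal-gene selection frequency (\%), and mean test error
#' rate, BCM and AUPR.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param summarizer summary tag (ignored for \code{strategy = "separate"}).
#' @param solver \code{"cd_lasso"} or \code{"tgdr"}.
#' @param nReps number of replicates (default 50).
#' @param seed integer master seed; per-replicate seeds are derived from it.
#' @param strategy \code{"pseudogene"} (one model on the summary matrix) or
#'   \code{"separate"} (one model per time point, probabilities averaged).
#' @param config pipeline configuration as in [fitPipeline()];
#'   \code{testFraction} (default 0.4) controls the split.
#' @return a \linkS4class{ReplicateSummary}.
#' @export
runReplicates <- function(design, summarizer = "sign_average",
                          solver = c("tgdr", "cd_lasso"), nReps = 50,
                          seed = 1, strategy = c("pseudogene", "separate"),
                          config = list()) {
    solver <- match.arg(solver)
    strategy <- match.arg(strategy)
    config <- defaultConfig(config)
    seeds <- withLocalSeed(seed, sample.int(.Machine$integer.max - 1, 2 * nReps))
    cg <- causalGenes(design)
    rows <- vector("list", nReps)
    lists <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        ds <- simulateDataset(design, seeds[2 * r - 1])
        sp <- splitTrainTest(ds, config$testFraction, seeds[2 * r])
        ytest <- phenoLabels(sp$test)
        if (strategy == "pseudogene") {
            fp <- fitPipeline(sp$train, summarizer, solver,
                              config = c(config, list(seed = seeds[2 * r])))
            pred <- applyPipeline(fp, sp$test)
            sel <- selectedGenes(fp@model)
        } else {
            fit <- separateTimepoints(sp$train, sp$test, solver,
                                      config = c(config,
                                                 list(seed = seeds[2 * r])))
            pred <- fit[c("prob", "class")]
            sel <- fit$selected
        }
        y <- as.numeric(ytest[names(pred$prob)])
        met <- metricsReport(pred$prob, y)
        # baseline: empty model predicting the training majority class
        ytr <- phenoLabels(sp$train)
        nullCall <- as.integer(mean(ytr) > 0.5)
        rows[[r]] <- data.frame(
            rep = r, size = length(sel), error_rate = met$error_rate,
            null_error = mean(y != nullCall),
            bcm = met$bcm, aupr = met$aupr,
            t(stats::setNames(as.numeric(cg %in% sel), cg)),
            check.names = FALSE)
        lists[[r]] <- sel
    }
    per <- do.call(rbind, rows)
    agg <- c(list(size = mean(per$size),
                  rand_index = randIndex(lists),
                  error_rate = mean(per$error_rate),
                  null_error = mean(per$null_error),
                  bcm = mean(per$bcm), aupr = mean(per$aupr)),
             stats::setNames(lapply(cg, function(g) 100 * mean(per[[g]])),
                             paste0("freq_", cg)))
    new("ReplicateSummary", perReplicate = per, geneLists = lists,
        causalGenes = cg, aggregate = agg)
}

#' @describeIn runReplicates named list of aggregate summary columns.
#' @param rs a \code{ReplicateSummary}.
#' @export
replicateAggregate <- function(rs) rs@aggregate

#' @describeIn runReplicates per-replicate results table.
#' @export
replicateTable <- function(rs) rs@perReplicate

#' @describeIn runReplicates selection frequency (\%) of one gene across
#'   replicates.
#' @param gene gene identifier.
#' @export
selectionFrequency <- function(rs, gene) {
    100 * mean(vapply(rs@geneLists, function(l) gene %in% l, logical(1)))
}

setMethod("show", "ReplicateSummary", function(object) {
    a <- object@aggregate
    cat(sprintf("ReplicateSummary: %d replicates\n", nrow(object@perReplicate)))
    cat(sprintf("  mean size %.2f | Rand %.4f | error %.4f | BCM %.4f | AUPR %.4f\n",
                a$size, a$rand_index, a$error_rate, a$bcm, a$aupr))
    for (g in object@causalGenes)
        cat(sprintf("  %s selected in %.0f%% of replicates\n", g,
                    a[[paste0("freq_", g)]]))
})
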