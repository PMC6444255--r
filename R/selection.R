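# Cross-validated tuning and end-to-end pipelines.

defaultConfig <- function(config = list()) {
    def <- list(folds = 5, seed = 1, tau = 1, dnu = 0.01, maxSteps = 2000,
                kStep = 10, nlambda = 100, lambdaMinRatio = 0.01,
                tol = 1e-7, testFraction = 0.4)
    def[names(config)] <- config
    def
}

# Stratified fold assignment: within each class, shuffled subjects are dealt
# round-robin, so fold class counts differ by at most one.
stratifiedFolds <- function(y, folds, seed) {
    if (min(table(y)) < folds)
        stop("each class needs at least as many subjects as folds")
    f <- integer(length(y))
    withLocalSeed(seed, {
        for (cls in unique(y)) {
            idx <- sample(which(y == cls))
            f[idx] <- rep_len(seq_len(folds), length(idx))
        }
    })
    f
}

# Fit a regularization path and return original-scale snapshots.
pathFit <- function(X, y, solver, grid, config) {
    if (solver == "cd_lasso")
        cdLassoPath(X, y, grid, tol = config$tol)
    else
        tgdrPath(X, y, tau = config$tau, dnu = config$dnu, ks = grid)
}

pathPredict <- function(path, X) {
    eta <- sweep(X %*% path$beta, 2, path$a0, "+")
    plogis(eta)
}

#' Cross-validated tuning of a sparse logistic solver
#'
#' Stratified k-fold cross-validation on a subjects x features matrix: for
#' each grid value the solver is fit on the other folds and misclassified
#' subjects (0.5 probability threshold) in the held-out fold are counted; the
#' counts are summed over folds and the grid value with the smallest total is
#' chosen. Ties are broken toward the sparser setting (larger penalty for
#' cd_lasso, smaller step count for tgdr). Both solvers are evaluated along a
#' single fitted path per fold.
#'
#' @param X numeric matrix, subjects x features.
#' @param y binary 0/1 response.
#' @param solver \code{"cd_lasso"} or \code{"tgdr"}.
#' @param grid tuning grid: descending lambdas (cd_lasso) or ascending step
#'   counts (tgdr); default per [lambdaGrid()] or
#'   \code{seq(0, maxSteps, kStep)}.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param config list overriding solver defaults (\code{tau}, \code{dnu},
#'   \code{maxSteps}, \code{kStep}, \code{nlambda}, \code{lambdaMinRatio},
#'   \code{tol}).
#' @return a \linkS4class{CVResult}.
#' @export
cvSelect <- function(X, y, solver = c("cd_lasso", "tgdr"), grid = NULL,
                     folds = 5, seed = 1, config = list()) {
    solver <- match.arg(solver)
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    checkBinaryResponse(y)
    config <- defaultConfig(config)
    if (is.null(grid)) {
        grid <- if (solver == "cd_lasso")
            lambdaGrid(X, y, config$nlambda, config$lambdaMinRatio)
        else seq(0, config$maxSteps, by = config$kStep)
    }
    f <- stratifiedFolds(y, folds, seed)
    errs <- numeric(length(grid))
    foldSel <- vector("list", folds)
    for (k in seq_len(folds)) {
        tr <- f != k
        path <- pathFit(X[tr, , drop = FALSE], y[tr], solver, grid, config)
        pr <- pathPredict(path, X[!tr, , drop = FALSE])
        calls <- pr > 0.5
        errs <- errs + colSums(calls != y[!tr])
        foldSel[[k]] <- path$beta
    }
    # grids are ordered sparsest-first (descending lambda / ascending k),
    # so the first minimizer is the sparsity-favoring tie-break
    chosenIdx <- which.min(errs)
    chosen <- grid[chosenIdx]
    lists <- lapply(foldSel, function(B)
        rownames(B)[B[, chosenIdx] != 0])
    new("CVResult", grid = as.numeric(grid), cvErrors = errs,
        chosen = as.numeric(chosen), foldGeneLists = lists, folds = f,
        solver = solver)
}

#' @describeIn cvSelect chosen tuning value.
#' @param cv a \code{CVResult}.
#' @export
chosenTuning <- function(cv) cv@chosen

#' @describeIn cvSelect misclassification totals per grid value.
#' @export
cvErrors <- function(cv) stats::setNames(cv@cvErrors, cv@grid)

#' @describeIn cvSelect per-fold selected gene lists at the chosen tuning.
#' @export
foldGeneLists <- function(cv) cv@foldGeneLists

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult (%s): %d-value grid, chosen %s (%d misclassified)\n",
                object@solver, length(object@grid), format(object@chosen),
                as.integer(min(object@cvErrors))))
})

#' Fit a full pipeline: summarizer + cross-validated sparse solver
#'
#' On the training set: estimates the sign profile (sign average only), builds
#' the pseudogene matrix, tunes the solver by stratified cross-validation and
#' refits the final model on the full training matrix at the chosen tuning.
#' Signs are estimated on training data only and frozen for later test-set
#' summarization, so no test label ever enters the fit.
#'
#' @param train a \linkS4class{LongitudinalExpressionSet}.
#' @param summarizer one of \code{"sign_average"}, \code{"mean"},
#'   \code{"median"}, \code{"pc1"}.
#' @param solver \code{"cd_lasso"} or \code{"tgdr"}.
#' @param config list: \code{folds} (5), \code{seed} (1), solver settings as
#'   in [cvSelect()].
#' @return a \linkS4class{FittedPipeline}.
#' @export
fitPipeline <- function(train,
                        summarizer = c("sign_average", "mean", "median", "pc1"),
                        solver = c("cd_lasso", "tgdr"), config = list()) {
    summarizer <- match.arg(summarizer)
    solver <- match.arg(solver)
    config <- defaultConfig(config)
    profile <- if (summarizer == "sign_average") estimateSigns(train) else NULL
    pm <- pseudogenes(train, summarizer, profile)
    X <- scoreMatrix(pm)
    y <- as.numeric(phenoLabels(train)[rownames(X)])
    cv <- cvSelect(X, y, solver, folds = config$folds, seed = config$seed,
                   config = config)
    model <- if (solver == "cd_lasso")
        fitCDLasso(X, y, lambda = cv@chosen, tol = config$tol)
    else
        fitTGDR(X, y, tau = config$tau, dnu = config$dnu, steps = cv@chosen)
    new("FittedPipeline", summarizer = summarizer, profile = profile,
        model = model, cv = cv, config = config)
}

#' @describeIn fitPipeline final model accessor.
#' @param fp a \code{FittedPipeline}.
#' @export
pipelineModel <- function(fp) fp@model

#' @describeIn fitPipeline training-derived sign profile (or NULL).
#' @export
pipelineProfile <- function(fp) fp@profile

setMethod("show", "FittedPipeline", function(object) {
    cat(sprintf("FittedPipeline: %s + %s, %d genes selected\n",
                object@summarizer, object@model@solver,
                length(selectedGenes(object@model))))
})

#' Apply a fitted pipeline to new longitudinal data
#'
#' Test pseudogenes are built with the training-derived sign profile (sign
#' average) or the label-free summarizer; labels in \code{newdata} are never
#' read.
#'
#' @param fp a \linkS4class{FittedPipeline}.
#' @param newdata a \linkS4class{LongitudinalExpressionSet} whose genes cover
#'   the model's.
#' @return list with \code{prob} (named class-1 probabilities) and
#'   \code{class} (0/1 calls at threshold 0.5).
#' @export
applyPipeline <- function(fp, newdata) {
    pm <- pseudogenes(newdata, fp@summarizer, fp@profile)
    pr <- predictProb(fp@model, scoreMatrix(pm))
    names(pr) <- rownames(scoreMatrix(pm))
    list(prob = pr, class = as.integer(pr > 0.5))
}

#' Separate-per-time-point comparator strategy
#'
#' Fits one cross-validation-tuned sparse logistic model per time point on
#' that time point's expression matrix (training subjects measured there). A
#' test subject's membership probability is the mean of the per-time-point
#' posterior probabilities over its available (modeled) time points; a gene
#' counts as selected if its coefficient is nonzero at one or more time
#' points. Training time points lacking one class are skipped with a warning.
#'
#' @param train,test \linkS4class{LongitudinalExpressionSet}s.
#' @param solver \code{"cd_lasso"} or \code{"tgdr"}.
#' @param config as in [fitPipeline()].
#' @return list: \code{models} (per-time-point), \code{prob}, \code{class},
#'   \code{selected} (union gene list).
#' @export
separateTimepoints <- function(train, test, solver = c("cd_lasso", "tgdr"),
                               config = list()) {
    solver <- match.arg(solver)
    config <- defaultConfig(config)
    lab <- phenoLabels(train)
    tg <- timeGrid(train)
    models <- list()
    for (t in tg) {
        m <- exprAt(train, t)
        yt <- as.numeric(lab[colnames(m)])
        if (length(unique(yt)) < 2) {
            warning(sprintf("time point %s has one class only; skipped",
                            format(t)))
            next
        }
        Xt <- t(m)
        cv <- cvSelect(Xt, yt, solver, folds = config$folds,
                       seed = config$seed, config = config)
        models[[as.character(t)]] <- if (solver == "cd_lasso")
            fitCDLasso(Xt, yt, lambda = cv@chosen, tol = config$tol)
        else
            fitTGDR(Xt, yt, tau = config$tau, dnu = config$dnu,
                    steps = cv@chosen)
    }
    if (!length(models)) stop("no time point with both classes")
    subj <- subjectIDs(test)
    probs <- matrix(NA_real_, length(subj), length(models),
                    dimnames = list(subj, names(models)))
    for (t in names(models)) {
        mt <- exprAt(test, as.numeric(t))
        if (!ncol(mt)) next
        probs[colnames(mt), t] <- predictProb(models[[t]], t(mt))
    }
    pr <- rowMeans(probs, na.rm = TRUE)
    if (anyNA(pr))
        warning("test subject(s) with no modeled time point: NA probability")
    selected <- unique(unlist(lapply(models, selectedGenes)))
    list(models = models, prob = pr, class = as.integer(pr > 0.5),
         selected = selected)
}
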