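# Sparse logistic regression: soft-threshold operator, coordinate-descent
# LASSO, threshold gradient descent regularization, prediction.

#' Soft-threshold operator
#'
#' \code{S(x, y) = x - y} if \code{x > 0} and \code{y < |x|};
#' \code{x + y} if \code{x < 0} and \code{y < |x|}; 0 if \code{y >= |x|}.
#' The elementary update behind each coordinate-descent step.
#'
#' @param x numeric vector.
#' @param y nonnegative threshold (scalar).
#' @return thresholded values, same shape as \code{x}.
#' @examples
#' softThreshold(c(3, -3, 0.5), 1)  # 2, -2, 0
#' @export
softThreshold <- function(x, y) {
    if (length(y) != 1L || is.na(y) || y < 0) stop("threshold y must be >= 0")
    sign(x) * pmax(abs(x) - y, 0)
}

checkBinaryResponse <- function(y) {
    if (!all(y %in% c(0, 1))) stop("response must be 0/1")
    if (length(unique(y)) < 2) stop("both classes required in the response")
}

# Internal standardization; zero-variance columns become all-zero (their
# coefficients stay 0). Sample sd (n - 1).
standardizeX <- function(X) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- Inf
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    list(X = Xs, center = ctr, scale = scl)
}

# Map standardized-scale path coefficients back to the original feature scale.
destandardize <- function(a0, B, ctr, scl) {
    Borig <- B / scl
    list(a0 = a0 - colSums(Borig * ctr), beta = Borig)
}

#' Smallest L1 penalty with an all-zero model
#'
#' \code{max_j |(1/n) sum_i x_ij (y_i - ybar)|} on the internally standardized
#' design; at or above this value every penalized coefficient is zero.
#'
#' @param X numeric matrix, subjects x features.
#' @param y binary 0/1 response.
#' @return the null-model penalty threshold.
#' @export
lambdaMax <- function(X, y) {
    checkBinaryResponse(y)
    st <- standardizeX(as.matrix(X))
    max(abs(crossprod(st$X, y - mean(y)) / length(y)))
}

#' Default descending log-spaced penalty grid
#'
#' @param X,y as in [lambdaMax()].
#' @param nlambda grid length (default 100).
#' @param lambdaMinRatio smallest grid value as a fraction of the null-model
#'   threshold (default 0.01).
#' @return decreasing numeric vector of penalties.
#' @export
lambdaGrid <- function(X, y, nlambda = 100, lambdaMinRatio = 0.01) {
    lmax <- lambdaMax(X, y)
    if (lmax <= 0) stop("all features are constant; no penalty grid")
    exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nlambda))
}

# Full CD path on original-scale X over a descending lambda sequence.
# Returns list(a0 = numeric(L), beta = p x L matrix) on the original scale.
cdLassoPath <- function(X, y, lambdas, tol = 1e-7, maxSweeps = 1000,
                        maxIRLS = 100) {
    X <- as.matrix(X); checkBinaryResponse(y)
    stopifnot(all(lambdas >= 0), !is.unsorted(rev(lambdas)))
    st <- standardizeX(X)
    fit <- cd_lasso_path_cpp(st$X, as.numeric(y), as.numeric(lambdas),
                             tol, as.integer(maxSweeps), as.integer(maxIRLS))
    out <- destandardize(fit$a0, fit$beta, st$center, st$scale)
    rownames(out$beta) <- colnames(X)
    out
}

makeModel <- function(a0, beta, featureNames, solver, tuning, ctr, scl) {
    new("SparseLogisticModel", intercept = unname(a0),
        coefficients = stats::setNames(as.numeric(beta), featureNames),
        solver = solver, tuning = tuning,
        center = stats::setNames(ctr, featureNames),
        scale = stats::setNames(scl, featureNames))
}

#' Fit an L1-penalized logistic model by cyclic coordinate descent
#'
#' Minimizes \code{(1/n) * negative Bernoulli log-likelihood +
#' lambda * ||beta||_1} on the internally standardized design (unpenalized
#' intercept) by iteratively reweighted least squares with cyclic
#' soft-threshold coordinate updates, warm-started along a descending penalty
#' path down to \code{lambda}. At convergence the KKT conditions hold:
#' \code{|score_j| <= lambda + tol} for zero coefficients and
#' \code{|score_j - lambda * sign(beta_j)| <= tol} for nonzero ones.
#' Reported coefficients are mapped back to the original feature scale.
#'
#' @param X numeric matrix, subjects x features (column names become feature
#'   names).
#' @param y binary 0/1 response vector.
#' @param lambda nonnegative penalty.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep.
#' @param maxSweeps,maxIRLS iteration caps for the inner/outer loops.
#' @return a \linkS4class{SparseLogisticModel}.
#' @export
fitCDLasso <- function(X, y, lambda, tol = 1e-7, maxSweeps = 1000,
                       maxIRLS = 100) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    checkBinaryResponse(y)
    if (length(y) != nrow(X)) stop("X and y dimensions disagree")
    if (is.na(lambda) || lambda < 0) stop("lambda must be >= 0")
    st <- standardizeX(X)
    lmax <- max(abs(crossprod(st$X, y - mean(y)) / length(y)))
    if (lambda >= lmax) {
        lams <- lambda
    } else {
        # short warm-start descent for stability at small penalties
        hi <- max(lmax, lambda + 1e-12)
        lams <- c(exp(seq(log(hi), log(max(lambda, hi * 1e-3)),
                          length.out = 8)), lambda)
        lams <- sort(unique(pmax(lams, lambda)), decreasing = TRUE)
    }
    fit <- cd_lasso_path_cpp(st$X, as.numeric(y), as.numeric(lams), tol,
                             as.integer(maxSweeps), as.integer(maxIRLS))
    last <- length(lams)
    out <- destandardize(fit$a0[last], fit$beta[, last, drop = FALSE],
                         st$center, st$scale)
    makeModel(out$a0, out$beta, colnames(X), "cd_lasso",
              list(lambda = lambda), st$center, st$scale)
}

#' Fit a logistic model by threshold gradient descent regularization
#'
#' Starting from zero coefficients, repeats \code{steps} times: compute the
#' gradient \code{g} of the (1/n-scaled) log-likelihood on the standardized
#' design; update only the coefficients with \code{|g_j| >= tau * max_l
#' |g_l|} (ties included) by \code{dnu * g_j}; the unpenalized intercept moves
#' by its full gradient every step. \code{tau = 1} keeps only the
#' largest-gradient feature(s) per step (LASSO-like sparsity); \code{tau = 0}
#' updates every feature (ridge-like density). The step count \code{steps}
#' plays the role of the regularization parameter and is what
#' cross-validation tunes.
#'
#' @param X,y as in [fitCDLasso()].
#' @param tau gradient threshold in \[0, 1\] (default 1).
#' @param dnu step size (default 0.01).
#' @param steps number of gradient steps (k >= 0).
#' @return a \linkS4class{SparseLogisticModel}.
#' @export
fitTGDR <- function(X, y, tau = 1, dnu = 0.01, steps = 100) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    checkBinaryResponse(y)
    if (length(y) != nrow(X)) stop("X and y dimensions disagree")
    if (is.na(tau) || tau < 0 || tau > 1) stop("tau must be in [0, 1]")
    if (dnu <= 0) stop("dnu must be > 0")
    if (steps < 0) stop("steps must be >= 0")
    st <- standardizeX(X)
    fit <- tgdr_path_cpp(st$X, as.numeric(y), tau, dnu,
                         as.integer(round(steps)))
    out <- destandardize(fit$a0, fit$beta, st$center, st$scale)
    makeModel(out$a0, out$beta, colnames(X), "tgdr",
              list(tau = tau, dnu = dnu, steps = as.integer(round(steps))),
              st$center, st$scale)
}

# TGDR path on original-scale X with snapshots at the step counts `ks`
# (ascending). Returns list(a0 = numeric(S), beta = p x S) original scale.
tgdrPath <- function(X, y, tau = 1, dnu = 0.01, ks = seq(0, 2000, 10)) {
    X <- as.matrix(X); checkBinaryResponse(y)
    stopifnot(!is.unsorted(ks), all(ks >= 0))
    st <- standardizeX(X)
    fit <- tgdr_path_cpp(st$X, as.numeric(y), tau, dnu, as.integer(ks))
    out <- destandardize(fit$a0, fit$beta, st$center, st$scale)
    rownames(out$beta) <- colnames(X)
    out
}

#' @describeIn fitCDLasso names of features with nonzero coefficients.
#' @param model a \linkS4class{SparseLogisticModel}.
#' @export
selectedGenes <- function(model) {
    names(model@coefficients)[model@coefficients != 0]
}

#' @describeIn fitCDLasso model intercept.
#' @export
modelIntercept <- function(model) model@intercept

#' @describeIn fitCDLasso full named coefficient vector (original feature
#'   scale).
#' @param object a \linkS4class{SparseLogisticModel}.
#' @export
setMethod("coef", "SparseLogisticModel", function(object) object@coefficients)

setMethod("show", "SparseLogisticModel", function(object) {
    cat(sprintf("SparseLogisticModel (%s): %d / %d features selected\n",
                object@solver, sum(object@coefficients != 0),
                length(object@coefficients)))
    cat("  tuning:", paste(names(object@tuning),
                           vapply(object@tuning, format, ""),
                           sep = "=", collapse = ", "), "\n")
})

#' Posterior class-1 probabilities from a sparse logistic model
#'
#' \code{expit(intercept + X beta)}; coefficients are on the original feature
#' scale so \code{newX} is used as-is. Features carrying nonzero coefficients
#' must be present; class calls threshold at 0.5.
#'
#' @param model a \linkS4class{SparseLogisticModel}.
#' @param newX numeric matrix, subjects x features, with column names.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, newX) {
    newX <- as.matrix(newX)
    if (is.null(colnames(newX)) && ncol(newX) == length(model@coefficients))
        colnames(newX) <- names(model@coefficients)
    sel <- names(model@coefficients)[model@coefficients != 0]
    miss <- setdiff(sel, colnames(newX))
    if (length(miss))
        stop("model features missing from new data: ",
             paste(miss, collapse = ", "))
    eta <- rep(model@intercept, nrow(newX)) +
        if (length(sel)) as.vector(newX[, sel, drop = FALSE] %*%
                                   model@coefficients[sel]) else 0
    plogis(eta)
}

#' Serialize / deserialize a SparseLogisticModel as JSON
#'
#' Records solver tag, tuning, intercept, the sparse coefficient map and the
#' internal standardization parameters.
#'
#' @param model a \linkS4class{SparseLogisticModel}.
#' @param path JSON file path.
#' @export
writeModel <- function(model, path) {
    nz <- model@coefficients[model@coefficients != 0]
    jsonlite::write_json(list(
        solver_tag = model@solver, tuning = model@tuning,
        intercept = model@intercept,
        coefficients = as.list(nz),
        features = names(model@coefficients),
        center = as.list(model@center), scale = as.list(model@scale)),
        path, auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    cf <- stats::setNames(numeric(length(j$features)), j$features)
    if (length(j$coefficients)) cf[names(j$coefficients)] <-
        unlist(j$coefficients)
    new("SparseLogisticModel", intercept = j$intercept, coefficients = cf,
        solver = j$solver_tag, tuning = as.list(j$tuning),
        center = unlist(j$center), scale = unlist(j$scale))
}
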