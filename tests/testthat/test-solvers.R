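test_that("soft-threshold operator follows its branch table", {
    expect_equal(softThreshold(3, 1), 2)
    expect_equal(softThreshold(-3, 1), -2)
    expect_equal(softThreshold(0.5, 1), 0)
    expect_equal(softThreshold(-0.5, 1), 0)
    expect_equal(softThreshold(c(-2, 0, 7), 0), c(-2, 0, 7))
    expect_error(softThreshold(1, -0.1), ">= 0")
})

test_that("penalties at or above lambda_max give the null model", {
    fx <- solverFixture()
    lmax <- lambdaMax(fx$X, fx$y)
    for (lam in c(lmax, 1.5 * lmax)) {
        m <- fitCDLasso(fx$X, fx$y, lam)
        expect_true(all(coef(m) == 0))
        expect_equal(modelIntercept(m), qlogis(mean(fx$y)), tolerance = 1e-8)
    }
    m2 <- fitCDLasso(fx$X, fx$y, lmax * 0.95)
    expect_gt(sum(coef(m2) != 0), 0)
})

test_that("unpenalized fit matches the logistic MLE", {
    fx <- solverFixture(seed = 7)
    m <- fitCDLasso(fx$X, fx$y, 0, tol = 1e-12)
    gl <- stats::glm(fx$y ~ fx$X, family = stats::binomial)
    expect_equal(unname(c(modelIntercept(m), coef(m))), unname(coef(gl)),
                 tolerance = 1e-4)
})

test_that("CD objective matches an independent proximal-gradient oracle", {
    fx <- solverFixture(seed = 3)
    Xs <- scale(fx$X)
    lmax <- lambdaMax(fx$X, fx$y)
    grid <- exp(seq(log(lmax * 0.9), log(lmax * 0.02), length.out = 10))
    for (lam in grid) {
        m <- fitCDLasso(fx$X, fx$y, lam, tol = 1e-10)
        sc <- standardizedCoefs(m)
        mine <- lassoObjective(Xs, fx$y, sc$b0, sc$b, lam)
        or <- fistaLasso(Xs, fx$y, lam)
        oracle <- lassoObjective(Xs, fx$y, or$b0, or$b, lam)
        expect_lt(abs(mine - oracle), 1e-6)
    }
})

test_that("KKT conditions hold at the CD solution", {
    fx <- solverFixture(n = 40, p = 6, seed = 5, strength = c(1, -1, 0.5))
    lam <- 0.05
    m <- fitCDLasso(fx$X, fx$y, lam, tol = 1e-10)
    Xs <- scale(fx$X)
    sc <- standardizedCoefs(m)
    pr <- plogis(sc$b0 + as.vector(Xs %*% sc$b))
    score <- as.vector(crossprod(Xs, fx$y - pr)) / length(fx$y)
    tol <- 1e-6
    zero <- sc$b == 0
    expect_true(all(abs(score[zero]) <= lam + tol))
    expect_true(all(abs(score[!zero] - lam * sign(sc$b[!zero])) <= tol))
})

test_that("CD agrees with glmnet as an independent implementation", {
    skip_if_not_installed("glmnet")
    fx <- solverFixture(n = 30, p = 5, seed = 17, strength = c(1, -0.7))
    Xs <- scale(fx$X)
    lam <- 0.08
    m <- fitCDLasso(fx$X, fx$y, lam, tol = 1e-12)
    sc <- standardizedCoefs(m)
    g <- glmnet::glmnet(Xs, fx$y, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(sc$b), as.numeric(g$beta), tolerance = 1e-5)
    expect_equal(unname(sc$b0), as.numeric(g$a0), tolerance = 1e-5)
})

test_that("model size is non-increasing in the penalty", {
    fx <- solverFixture(n = 50, p = 8, seed = 23, strength = c(1.5, -1, 0.8))
    grid <- lambdaGrid(fx$X, fx$y, nlambda = 15)
    nnz <- vapply(grid, function(l)
        sum(coef(fitCDLasso(fx$X, fx$y, l)) != 0), numeric(1))
    # grid is descending, so sizes should be non-decreasing down the path
    expect_true(all(diff(nnz) >= 0))
})

test_that("TGDR follows the threshold-update rules", {
    fx <- solverFixture(n = 30, p = 6, seed = 31, strength = c(1.2, -0.9))
    # k = 0: empty model
    m0 <- fitTGDR(fx$X, fx$y, tau = 1, steps = 0)
    expect_true(all(coef(m0) == 0))
    expect_equal(modelIntercept(m0), 0)
    # tau = 1, k = 1: exactly the argmax-gradient feature(s) move
    Xs <- scale(fx$X)
    g0 <- as.vector(crossprod(Xs, fx$y - 0.5)) / length(fx$y)
    expected <- which(abs(g0) >= max(abs(g0)))
    m1 <- fitTGDR(fx$X, fx$y, tau = 1, steps = 1)
    expect_equal(which(coef(m1) != 0), expected, ignore_attr = TRUE)
    # tau = 0: dense (ridge-like) model
    md <- fitTGDR(fx$X, fx$y, tau = 0, steps = 50)
    expect_equal(sum(coef(md) != 0), ncol(fx$X))
    # sparsity ordering at equal step counts
    ms <- fitTGDR(fx$X, fx$y, tau = 1, steps = 50)
    expect_lte(sum(coef(ms) != 0), sum(coef(md) != 0))
    expect_error(fitTGDR(fx$X, fx$y, tau = 1.2, steps = 5), "tau")
})

test_that("TGDR training log-likelihood is non-decreasing in k", {
    fx <- solverFixture(n = 40, p = 10, seed = 37, strength = c(1, -1))
    ks <- seq(0, 400, by = 40)
    ll <- vapply(ks, function(k)
        meanLogLik(fitTGDR(fx$X, fx$y, tau = 1, dnu = 0.01, steps = k),
                   fx$X, fx$y), numeric(1))
    expect_true(all(diff(ll) >= -1e-10))
})

test_that("both solvers are permutation-equivariant in the features", {
    fx <- solverFixture(n = 30, p = 6, seed = 41, strength = c(1, -0.8))
    perm <- c(4, 1, 6, 2, 5, 3)
    Xp <- fx$X[, perm]
    m1 <- fitCDLasso(fx$X, fx$y, 0.05, tol = 1e-10)
    m2 <- fitCDLasso(Xp, fx$y, 0.05, tol = 1e-10)
    expect_equal(coef(m2), coef(m1)[perm], tolerance = 1e-8)
    t1 <- fitTGDR(fx$X, fx$y, steps = 100)
    t2 <- fitTGDR(Xp, fx$y, steps = 100)
    expect_equal(coef(t2), coef(t1)[perm], tolerance = 1e-10)
})

test_that("predictProb behaves as the logistic link demands", {
    fx <- solverFixture(seed = 43)
    lmax <- lambdaMax(fx$X, fx$y)
    null <- fitCDLasso(fx$X, fx$y, lmax)
    expect_equal(unname(predictProb(null, fx$X)), rep(mean(fx$y), nrow(fx$X)),
                 tolerance = 1e-8)
    m <- fitTGDR(fx$X, fx$y, steps = 200)
    pr <- predictProb(m, fx$X)
    expect_true(all(pr > 0 & pr < 1))
    # monotone in a positive-coefficient feature
    j <- which(coef(m) > 0)[1]
    if (!is.na(j)) {
        X2 <- fx$X; X2[, j] <- X2[, j] + 1
        expect_true(all(predictProb(m, X2) > pr))
    }
    # manual expit on a 2-sample toy
    toy <- matrix(c(0, 1, 2, -1), 2, 2, dimnames = list(NULL, c("a", "b")))
    tm <- new("SparseLogisticModel", intercept = 0.5,
              coefficients = c(a = 1, b = -2), solver = "tgdr",
              tuning = list(), center = c(a = 0, b = 0), scale = c(a = 1, b = 1))
    expect_equal(unname(predictProb(tm, toy)),
                 plogis(c(0.5 + 0 - 4, 0.5 + 1 + 2)))
    expect_error(predictProb(tm, toy[, 1, drop = FALSE]), "missing")
})

test_that("model JSON round trip preserves fit and predictions", {
    fx <- solverFixture(seed = 47)
    m <- fitCDLasso(fx$X, fx$y, 0.05)
    f <- tempfile(fileext = ".json")
    writeModel(m, f)
    back <- readModel(f)
    expect_equal(coef(back), coef(m), tolerance = 1e-12)
    expect_equal(predictProb(back, fx$X), predictProb(m, fx$X),
                 tolerance = 1e-12)
})
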