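test_that("CV folds are stratified, deterministic, and errors are counts", {
    ds <- toyLES(n = 20, G = 10, seed = 3, effect = 1)
    pm <- meanSummary(ds)
    X <- scoreMatrix(pm)
    y <- as.numeric(phenoLabels(ds)[rownames(X)])
    cv1 <- cvSelect(X, y, "tgdr", folds = 5, seed = 11,
                    config = list(maxSteps = 200))
    cv2 <- cvSelect(X, y, "tgdr", folds = 5, seed = 11,
                    config = list(maxSteps = 200))
    expect_identical(cv1@folds, cv2@folds)
    expect_identical(chosenTuning(cv1), chosenTuning(cv2))
    # fold class ratios within 1 subject of each other
    tab <- table(cv1@folds, y)
    expect_lte(diff(range(tab[, 1])), 1)
    expect_lte(diff(range(tab[, 2])), 1)
    expect_true(all(cv1@cvErrors == round(cv1@cvErrors)))
    expect_true(all(cv1@cvErrors >= 0 & cv1@cvErrors <= length(y)))
    expect_error(cvSelect(X[1:6, ], y[1:6], "tgdr", folds = 5, seed = 1),
                 "folds")
})

test_that("a single-value grid is chosen trivially", {
    ds <- toyLES(n = 15, G = 6, seed = 5, effect = 0.5)
    X <- scoreMatrix(meanSummary(ds))
    y <- as.numeric(phenoLabels(ds)[rownames(X)])
    cv <- cvSelect(X, y, "cd_lasso", grid = 0.2, folds = 3, seed = 1)
    expect_equal(chosenTuning(cv), 0.2)
    expect_length(foldGeneLists(cv), 3)
})

test_that("on pure noise CV prefers sparse models and near-null error", {
    set.seed(29)
    nrep <- 20
    chosenK <- numeric(nrep); errRate <- numeric(nrep); minor <- numeric(nrep)
    for (r in seq_len(nrep)) {
        X <- matrix(rnorm(30 * 10), 30, 10,
                    dimnames = list(sprintf("s%02d", 1:30), paste0("g", 1:10)))
        y <- rep(c(0, 1), 15)
        cv <- cvSelect(X, y, "tgdr", folds = 5, seed = r,
                       config = list(maxSteps = 300))
        chosenK[r] <- chosenTuning(cv)
        errRate[r] <- min(cv@cvErrors) / 30
        minor[r] <- min(mean(y), 1 - mean(y))
    }
    # tie-break toward k = 0 makes the null model the usual choice
    expect_gte(mean(chosenK <= 60), 0.5)
    # chosen-model CV error close to the minority-class rate on average
    expect_lt(abs(mean(errRate) - mean(minor)), 0.15)
})

test_that("mean pipeline equals sign-average pipeline on sign-homogeneous data", {
    # strong positive effect at every time point -> all training signs +1
    ds <- toyLES(n = 16, G = 6, seed = 9, effect = 3)
    pr <- estimateSigns(ds)
    expect_true(all(signMatrix(pr) == 1))
    cfg <- list(seed = 4, maxSteps = 300)
    fp1 <- fitPipeline(ds, "sign_average", "tgdr", config = cfg)
    fp2 <- fitPipeline(ds, "mean", "tgdr", config = cfg)
    expect_equal(coef(pipelineModel(fp1)), coef(pipelineModel(fp2)),
                 tolerance = 1e-12)
    expect_equal(chosenTuning(fp1@cv), chosenTuning(fp2@cv))
})

test_that("pipelines are equivariant to gene reordering", {
    ds <- toyLES(n = 16, G = 5, seed = 15, effect = 1)
    perm <- c(3, 5, 1, 4, 2)
    dsp <- ds[perm, ]
    cfg <- list(seed = 2, maxSteps = 200)
    fp <- fitPipeline(ds, "sign_average", "tgdr", config = cfg)
    fpp <- fitPipeline(dsp, "sign_average", "tgdr", config = cfg)
    expect_equal(coef(pipelineModel(fpp)),
                 coef(pipelineModel(fp))[rownames(dsp)], tolerance = 1e-10)
})

test_that("applyPipeline reproduces training probabilities and ignores labels", {
    ds <- toyLES(n = 20, G = 8, seed = 19, effect = 1.5)
    sp <- splitTrainTest(ds, 0.4, seed = 6)
    fp <- fitPipeline(sp$train, "sign_average", "cd_lasso",
                      config = list(seed = 6))
    # training-set application reproduces the final model's fitted values
    trPred <- applyPipeline(fp, sp$train)
    pm <- pseudogenes(sp$train, "sign_average", pipelineProfile(fp))
    direct <- predictProb(pipelineModel(fp), scoreMatrix(pm))
    expect_equal(unname(trPred$prob), unname(direct), tolerance = 1e-12)
    # label-agnostic prediction
    pred <- applyPipeline(fp, sp$test)
    lab <- phenoLabels(sp$test)
    perm <- stats::setNames(rev(unname(lab)), names(lab))
    cd <- SummarizedExperiment::colData(sp$test)
    flipped <- LongitudinalExpressionSet(
        SummarizedExperiment::assay(sp$test), cd$subject, cd$time, perm)
    expect_identical(applyPipeline(fp, flipped)$prob, pred$prob)
    expect_true(all(pred$prob > 0 & pred$prob < 1))
})

test_that("separate-per-time-point strategy averages per-time probabilities", {
    ds <- toyLES(n = 20, G = 6, seed = 25, effect = 2)
    sp <- splitTrainTest(ds, 0.4, seed = 8)
    fit <- separateTimepoints(sp$train, sp$test, "tgdr",
                              config = list(seed = 8, maxSteps = 200))
    expect_length(fit$models, length(timeGrid(sp$train)))
    # recompute one subject's probability by hand
    s <- subjectIDs(sp$test)[1]
    probs <- vapply(names(fit$models), function(t) {
        mt <- exprAt(sp$test, as.numeric(t))
        if (!s %in% colnames(mt)) return(NA_real_)
        predictProb(fit$models[[t]], t(mt[, s, drop = FALSE]))
    }, numeric(1))
    expect_equal(unname(fit$prob[s]), mean(probs, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_setequal(fit$selected,
                    unique(unlist(lapply(fit$models, selectedGenes))))
})

test_that("separate strategy handles single-time subjects and identical data", {
    # identical expression at every time point: the union of selections
    # equals any single time point's selection
    set.seed(33)
    n <- 16; G <- 5
    block <- matrix(rnorm(G * n), G, n, dimnames = list(paste0("g", 1:G), NULL))
    lab <- stats::setNames(rep(c(0, 1), n / 2), sprintf("s%02d", 1:n))
    block <- block + 1.5 * rep(lab, each = G)
    m <- cbind(block, block, block)
    ds <- LongitudinalExpressionSet(m, rep(names(lab), 3),
                                    rep(c(1, 2, 3), each = n), lab)
    fit <- separateTimepoints(ds, ds, "cd_lasso", config = list(seed = 3))
    sel1 <- selectedGenes(fit$models[[1]])
    expect_setequal(fit$selected, sel1)
    # subject measured at one time point only: membership = that probability
    one <- subsetSubjects(ds, names(lab)[1])
    cd <- SummarizedExperiment::colData(one)
    single <- LongitudinalExpressionSet(
        SummarizedExperiment::assay(one)[, cd$time == 1, drop = FALSE],
        cd$subject[cd$time == 1], cd$time[cd$time == 1],
        phenoLabels(one))
    p1 <- separateTimepoints(ds, single, "cd_lasso",
                             config = list(seed = 3))$prob
    m1 <- exprAt(single, 1)
    expect_equal(unname(p1), unname(predictProb(fit$models[["1"]], t(m1))),
                 tolerance = 1e-12)
})
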