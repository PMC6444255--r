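# Fixture builders shared across test files; everything is generated in code.

# Complete (or ragged) toy set with an optional additive group effect at every
# time point, so estimated signs are all +1 when `effect` is large.
toyLES <- function(n = 12, G = 8, times = c(1, 4, 7), seed = 1, effect = 0,
                   ragged = FALSE) {
    set.seed(seed)
    subj <- sprintf("s%02d", seq_len(n))
    labels <- stats::setNames(rep(c(0, 1), length.out = n), subj)
    keep <- matrix(TRUE, n, length(times))
    if (ragged) for (i in seq_len(n))
        if (i %% 3 == 0) keep[i, length(times)] <- FALSE
    cols <- which(t(keep))
    tcol <- rep(seq_along(times), n)[cols]
    scol <- rep(seq_len(n), each = length(times))[cols]
    m <- matrix(rnorm(G * length(cols)), G, length(cols),
                dimnames = list(sprintf("g%03d", seq_len(G)), NULL))
    m <- m + effect * rep(labels[scol], each = G)
    LongitudinalExpressionSet(m, subj[scol], times[tcol], labels)
}

# Single-gene set with fully specified values: `values` is a subjects x times
# matrix (NA = not measured); labels named by rownames.
manualLES <- function(values, labels, times = seq_len(ncol(values)),
                      gene = "g1") {
    subj <- rownames(values)
    idx <- which(!is.na(t(values)))
    tcol <- rep(seq_along(times), length(subj))[idx]
    scol <- rep(seq_along(subj), each = length(times))[idx]
    m <- matrix(t(values)[idx], 1, dimnames = list(gene, NULL))
    LongitudinalExpressionSet(m, subj[scol], times[tcol], labels)
}

# Sign profile with explicitly chosen signs for a single gene.
manualProfile <- function(signs, times = seq_along(signs), gene = "g1") {
    new("SignProfile", geneIDs = gene, times = as.numeric(times),
        beta1 = matrix(as.numeric(signs), 1), tstat = matrix(NA_real_, 1,
        length(signs)), sign = matrix(sign(as.numeric(signs)), 1))
}

# All-(+1) sign profile covering a dataset's genes and times.
manualProfileAllPos <- function(ds) {
    g <- rownames(ds); tg <- timeGrid(ds)
    ones <- matrix(1, length(g), length(tg), dimnames = list(g, tg))
    new("SignProfile", geneIDs = g, times = tg, beta1 = ones,
        tstat = ones * NA_real_, sign = ones)
}

# Small separable-ish classification fixture for the solvers.
solverFixture <- function(n = 20, p = 3, seed = 3, strength = c(0.8, -1.2)) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
    eta <- X[, seq_along(strength), drop = FALSE] %*% strength
    y <- rbinom(n, 1, plogis(eta))
    while (length(unique(y)) < 2) y <- rbinom(n, 1, plogis(eta))
    list(X = X, y = y)
}

# Penalized logistic objective on an already-standardized design.
lassoObjective <- function(Xs, y, b0, b, lambda) {
    eta <- as.vector(Xs %*% b) + b0
    mean(log(1 + exp(eta)) - y * eta) + lambda * sum(abs(b))
}

# Map a fitted model's original-scale coefficients back to the standardized
# scale it was optimized on.
standardizedCoefs <- function(model) {
    b <- coef(model) * model@scale
    b[!is.finite(b)] <- 0
    list(b0 = model@intercept + sum(coef(model) * model@center), b = b)
}

# Independent FISTA oracle for the L1-penalized logistic objective
# (accelerated proximal gradient; shares no code with the CD solver).
fistaLasso <- function(Xs, y, lambda, iters = 20000) {
    n <- nrow(Xs); p <- ncol(Xs)
    L <- max(eigen(crossprod(cbind(1, Xs)) / n)$values) / 4
    prox <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
    b <- rep(0, p); b0 <- 0
    vb <- b; v0 <- b0; s <- 1
    for (i in seq_len(iters)) {
        eta <- v0 + as.vector(Xs %*% vb)
        gr <- plogis(eta) - y
        bn <- prox(vb - crossprod(Xs, gr) / (n * L), lambda / L)
        b0n <- v0 - mean(gr) / L
        sn <- (1 + sqrt(1 + 4 * s^2)) / 2
        vb <- bn + (s - 1) / sn * (bn - b)
        v0 <- b0n + (s - 1) / sn * (b0n - b0)
        b <- bn; b0 <- b0n; s <- sn
    }
    list(b0 = b0, b = b)
}

# TGDR training log-likelihood (1/n scale) of a fitted model on its data.
meanLogLik <- function(model, X, y) {
    eta <- model@intercept + as.vector(X %*% coef(model))
    mean(y * eta - log(1 + exp(eta)))
}
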