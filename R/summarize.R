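# Sign estimation and pseudogene summarizers.

#' Estimate per-(gene, time point) group effects and their signs
#'
#' At each time point, for each gene, the group effect is the mean expression
#' difference between class 1 (complicated) and the reference class 0. A
#' moderated t statistic (limma empirical-Bayes variance shrinkage across
#' genes within the time point) is attached for reporting; the sign used by
#' the sign average is the sign of the raw mean difference, which the
#' shrinkage cannot change. Time points where either class has no subject get
#' sign 0 (with a warning) and NA estimates.
#'
#' @param x a \linkS4class{LongitudinalExpressionSet} with both classes
#'   present.
#' @return a \linkS4class{SignProfile}.
#' @export
estimateSigns <- function(x) {
    lab <- phenoLabels(x)
    if (length(unique(lab)) != 2) stop("both classes required")
    tg <- timeGrid(x); g <- rownames(x)
    beta1 <- tstat <- matrix(NA_real_, length(g), length(tg),
                             dimnames = list(g, tg))
    sg <- matrix(0, length(g), length(tg), dimnames = list(g, tg))
    for (ti in seq_along(tg)) {
        m <- exprAt(x, tg[ti])
        grp <- lab[colnames(m)]
        if (!any(grp == 0) || !any(grp == 1)) {
            warning(sprintf("time point %s lacks one class; signs set to 0",
                            format(tg[ti])))
            next
        }
        d <- rowMeans(m[, grp == 1, drop = FALSE]) -
             rowMeans(m[, grp == 0, drop = FALSE])
        beta1[, ti] <- d
        sg[, ti] <- sign(d)
        if (ncol(m) >= 3 && nrow(m) >= 2) {
            tstat[, ti] <- tryCatch({
                fit <- limma::lmFit(m, cbind(1, grp))
                limma::eBayes(fit)$t[, 2]
            }, error = function(e) NA_real_)
        }
    }
    new("SignProfile", geneIDs = g, times = tg, beta1 = beta1,
        tstat = tstat, sign = sg)
}

#' @describeIn estimateSigns genes x times sign matrix accessor.
#' @param profile a \code{SignProfile}.
#' @export
signMatrix <- function(profile) profile@sign

#' @describeIn estimateSigns genes x times group-effect matrix accessor.
#' @export
effectSizes <- function(profile) profile@beta1

#' @describeIn estimateSigns genes x times moderated t matrix accessor.
#' @export
modTStats <- function(profile) profile@tstat

setMethod("show", "SignProfile", function(object) {
    cat(sprintf("SignProfile: %d genes x %d time points (+%d / 0:%d / -%d)\n",
                length(object@geneIDs), length(object@times),
                sum(object@sign > 0), sum(object@sign == 0),
                sum(object@sign < 0)))
})

#' Write / read a SignProfile as TSV
#'
#' Columns: \code{gene_id}, \code{time}, \code{beta1}, \code{tstat},
#' \code{sign}.
#'
#' @param profile a \linkS4class{SignProfile}.
#' @param path output (input) TSV path.
#' @export
writeSignProfile <- function(profile, path) {
    df <- data.frame(
        gene_id = rep(profile@geneIDs, length(profile@times)),
        time = rep(profile@times, each = length(profile@geneIDs)),
        beta1 = sprintf("%.15g", as.vector(profile@beta1)),
        tstat = sprintf("%.15g", as.vector(profile@tstat)),
        sign = as.vector(profile@sign))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname writeSignProfile
#' @export
readSignProfile <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    g <- unique(df$gene_id); tg <- sort(unique(df$time))
    shape <- function(v) matrix(as.numeric(v), length(g), length(tg),
                                dimnames = list(g, tg))
    idx <- order(match(df$time, tg), match(df$gene_id, g))
    new("SignProfile", geneIDs = g, times = tg,
        beta1 = shape(df$beta1[idx]), tstat = shape(df$tstat[idx]),
        sign = shape(df$sign[idx]))
}

checkCoverage <- function(x, profile) {
    if (!all(rownames(x) %in% profile@geneIDs) ||
        !all(timeGrid(x) %in% profile@times))
        stop("sign profile does not cover every (gene, time) in the data")
}

newPseudogeneMatrix <- function(values, method, profile = NULL)
    new("PseudogeneMatrix", values = values, method = method,
        profile = profile)

#' Sign-average pseudogene summary
#'
#' For subject i and gene k, the sign average is
#' \deqn{\frac{1}{|t_i|} \sum_{t \in t_i} \mathrm{sign}(\hat\beta_{1kt})\,
#' x_{ikt},}
#' the mean over the subject's measured time points of expression multiplied
#' by the estimated direction of the group effect at that time point, so
#' oppositely directed time effects reinforce rather than cancel. Time points
#' with sign 0 drop out of the numerator but still count in the divisor
#' \eqn{|t_i|} (the number of measured time points).
#'
#' The profile is typically estimated on training data only and then frozen
#' for test-set summarization, so test labels never enter the summary.
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @param profile a \linkS4class{SignProfile} covering every (gene, time) in
#'   \code{x}.
#' @return a \linkS4class{PseudogeneMatrix} (subjects x genes).
#' @export
signAverage <- function(x, profile) {
    checkCoverage(x, profile)
    arr <- exprArray(x)
    g <- rownames(x); tg <- timeGrid(x); subj <- subjectIDs(x)
    sg <- profile@sign[match(g, profile@geneIDs),
                       match(tg, profile@times), drop = FALSE]
    num <- matrix(0, length(subj), length(g), dimnames = list(subj, g))
    for (ti in seq_along(tg)) {
        m <- matrix(arr[, , ti], length(g), length(subj))
        m[is.na(m)] <- 0
        num <- num + t(m * sg[, ti])
    }
    den <- rowSums(availability(x))
    if (any(den == 0)) stop("subject with zero available time points")
    newPseudogeneMatrix(num / den, "sign_average", profile)
}

summarizeOverTime <- function(x, fun, tag) {
    arr <- exprArray(x)
    v <- apply(arr, c(2, 1), fun, na.rm = TRUE)
    newPseudogeneMatrix(v, tag)
}

#' Plain summary comparators: per-subject mean / median over time
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @return a \linkS4class{PseudogeneMatrix}.
#' @export
meanSummary <- function(x) {
    arr <- exprArray(x)
    num <- apply(arr, c(2, 1), function(v) sum(v, na.rm = TRUE))
    den <- rowSums(availability(x))
    if (any(den == 0)) stop("subject with zero available time points")
    newPseudogeneMatrix(num / den, "mean")
}

#' @rdname meanSummary
#' @export
medianSummary <- function(x) summarizeOverTime(x, median, "median")

#' First-principal-component pseudogene summary
#'
#' Per gene, the subjects x times matrix of its time course is built (missing
#' (subject, time) entries mean-imputed per time point), columns are centered,
#' and each subject's score on the first principal component is returned.
#' Orientation is fixed by requiring the loading vector to have positive sum
#' (ties broken by the first nonzero loading), so results are reproducible.
#' With a single time point the score is the centered value.
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @return a \linkS4class{PseudogeneMatrix}.
#' @export
pc1Summary <- function(x) {
    arr <- exprArray(x)
    subj <- subjectIDs(x); g <- rownames(x)
    v <- matrix(NA_real_, length(subj), length(g),
                dimnames = list(subj, g))
    tg <- timeGrid(x)
    for (k in seq_along(g)) {
        # subjects x times time-course matrix for gene k
        M <- matrix(arr[k, , ], length(subj), length(tg))
        for (j in seq_len(ncol(M))) {
            mu <- mean(M[, j], na.rm = TRUE)
            M[is.na(M[, j]), j] <- mu
        }
        M <- scale(M, center = TRUE, scale = FALSE)
        if (ncol(M) == 1L) { v[, k] <- M[, 1]; next }
        sv <- svd(M, nu = 1, nv = 1)
        load <- sv$v[, 1]
        s <- sum(load)
        if (s < 0 || (s == 0 && load[which(load != 0)[1]] < 0)) {
            load <- -load; sv$u[, 1] <- -sv$u[, 1]
        }
        v[, k] <- sv$u[, 1] * sv$d[1]
    }
    newPseudogeneMatrix(v, "pc1")
}

#' Build a pseudogene matrix by method tag
#'
#' Dispatcher used by the pipelines; \code{"sign_average"} requires a
#' \linkS4class{SignProfile}.
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @param method one of \code{"sign_average"}, \code{"mean"}, \code{"median"},
#'   \code{"pc1"}.
#' @param profile \linkS4class{SignProfile} (sign average only).
#' @return a \linkS4class{PseudogeneMatrix}.
#' @export
pseudogenes <- function(x, method = c("sign_average", "mean", "median", "pc1"),
                        profile = NULL) {
    method <- match.arg(method)
    switch(method,
        sign_average = {
            if (is.null(profile)) stop("sign_average requires a SignProfile")
            signAverage(x, profile)
        },
        mean = meanSummary(x),
        median = medianSummary(x),
        pc1 = pc1Summary(x))
}

#' @describeIn pseudogenes subjects x genes value matrix accessor.
#' @param pm a \code{PseudogeneMatrix}.
#' @export
scoreMatrix <- function(pm) pm@values

#' @describeIn pseudogenes method tag accessor.
#' @export
summaryMethod <- function(pm) pm@method

setMethod("show", "PseudogeneMatrix", function(object) {
    cat(sprintf("PseudogeneMatrix (%s): %d subjects x %d genes\n",
                object@method, nrow(object@values), ncol(object@values)))
})

#' Write a PseudogeneMatrix as TSV plus a JSON sidecar
#'
#' The TSV has subjects as rows and genes as columns; the sidecar records the
#' summary method tag.
#'
#' @param pm a \linkS4class{PseudogeneMatrix}.
#' @param path output TSV path; the sidecar is \code{<path>.json}.
#' @export
writePseudogeneMatrix <- function(pm, path) {
    df <- data.frame(subject_id = rownames(pm@values),
                     signif(pm@values, 15), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(method_tag = pm@method),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(NULL)
}
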