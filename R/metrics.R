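# Predictive and stability metrics.

#' Misclassified error rate
#'
#' (false positives + false negatives) / sample size.
#'
#' @param calls 0/1 class calls.
#' @param labels 0/1 true labels.
#' @return fraction misclassified in \[0, 1\].
#' @export
errorRate <- function(calls, labels) {
    if (length(calls) != length(labels)) stop("length mismatch")
    if (!all(calls %in% c(0, 1)) || !all(labels %in% c(0, 1)))
        stop("calls and labels must be 0/1")
    mean(calls != labels)
}

#' Belief confusion metric (BCM)
#'
#' The class-balanced mean posterior probability assigned to a sample's true
#' class: for each class, average the fitted posterior of that class over its
#' members, then average over classes. Captures the average confidence that a
#' sample belongs in its own class; 1 is perfect, 0.5 is uninformative (two
#' classes).
#'
#' @param prob class-1 posterior probabilities (class-0 posterior is
#'   \code{1 - prob}).
#' @param labels 0/1 true labels; both classes must be present.
#' @return BCM in \[0, 1\].
#' @export
bcm <- function(prob, labels) {
    if (length(prob) != length(labels)) stop("length mismatch")
    if (!all(labels %in% c(0, 1)) || !any(labels == 0) || !any(labels == 1))
        stop("labels must be 0/1 with both classes present")
    mean(c(mean(1 - prob[labels == 0]), mean(prob[labels == 1])))
}

# Step-wise average precision treating `positive` as the positive class and
# ranking by `scores` (higher = more positive); tied scores enter the curve
# together.
averagePrecision <- function(scores, positive) {
    P <- sum(positive)
    if (P == 0) stop("no positive samples")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; pos <- positive[o]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(pos); fp <- cumsum(!pos)
    last <- !duplicated(grp, fromLast = TRUE)
    tp <- tp[last]; fp <- fp[last]
    prec <- tp / (tp + fp)
    rec <- tp / P
    sum(diff(c(0, rec)) * prec)
}

#' Area under the precision-recall curve, averaged over classes
#'
#' For each class the area under its precision-recall curve is computed by
#' step-wise average precision (no interpolation; ties grouped) treating that
#' class as positive and ranking by its posterior; the unweighted mean over
#' the two classes is returned.
#'
#' @param prob class-1 posterior probabilities.
#' @param labels 0/1 labels with both classes present.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(prob, labels) {
    if (length(prob) != length(labels)) stop("length mismatch")
    if (!any(labels == 0) || !any(labels == 1))
        stop("both classes must be present")
    mean(c(averagePrecision(1 - prob, labels == 0),
           averagePrecision(prob, labels == 1)))
}

#' Gene-list stability (average pairwise Jaccard) index
#'
#' Over k gene lists, \code{2/(k(k-1)) * sum_{i<j} |gs_i & gs_j| /
#' |gs_i | gs_j|}: the mean Jaccard similarity over list pairs. A pair of
#' empty lists counts as identical (similarity 1). This stability index over
#' repeated gene lists is distinct from the classical partition Rand index.
#'
#' @param gene_lists list of k >= 2 character vectors.
#' @return stability in \[0, 1\].
#' @export
randIndex <- function(gene_lists) {
    k <- length(gene_lists)
    if (k < 2) stop("at least 2 gene lists required")
    gene_lists <- lapply(gene_lists, unique)
    tot <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        u <- length(union(gene_lists[[i]], gene_lists[[j]]))
        tot <- tot + if (u == 0) 1 else
            length(intersect(gene_lists[[i]], gene_lists[[j]])) / u
    }
    2 * tot / (k * (k - 1))
}

#' Overlap between two gene lists with Fisher's exact test
#'
#' Builds the 2x2 membership table of the two lists over a universe of
#' \code{universe_size} genes and returns the one-sided (enrichment) Fisher's
#' exact p-value together with the overlap fraction
#' \code{|intersection| / |union|}.
#'
#' @param list1,list2 character vectors of gene ids.
#' @param universe_size number of genes in the universe (>= union size).
#' @return list with \code{overlap} and \code{p_value}.
#' @export
overlapTest <- function(list1, list2, universe_size) {
    list1 <- unique(list1); list2 <- unique(list2)
    a <- length(intersect(list1, list2))
    b <- length(setdiff(list1, list2))
    c <- length(setdiff(list2, list1))
    d <- universe_size - a - b - c
    if (d < 0) stop("universe smaller than the union of the lists")
    p <- fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")$p.value
    u <- a + b + c
    list(overlap = if (u == 0) 1 else a / u, p_value = p)
}

#' All predictive metrics at once
#'
#' @param prob class-1 posterior probabilities.
#' @param labels 0/1 labels.
#' @return list: \code{error_rate}, \code{bcm}, \code{aupr}, \code{n},
#'   \code{class_counts}.
#' @export
metricsReport <- function(prob, labels) {
    list(error_rate = errorRate(as.integer(prob > 0.5), labels),
         bcm = bcm(prob, labels), aupr = aupr(prob, labels),
         n = length(labels),
         class_counts = c(`0` = sum(labels == 0), `1` = sum(labels == 1)))
}
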