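# Data layer: construction, I/O, split and standardization utilities.

# Evaluate expr under a private RNG stream; the caller's .Random.seed is
# untouched so package functions are deterministic given their seed argument.
withLocalSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(expr)
}

#' Construct a LongitudinalExpressionSet
#'
#' @param exprs numeric matrix, genes x measurements, with gene rownames; each
#'   column is one measured (subject, time) pair.
#' @param subject character vector, subject id per column.
#' @param time numeric vector, time point per column.
#' @param labels named numeric/integer vector of 0/1 phenotype labels, one per
#'   subject (names are subject ids); 0 is the reference class.
#' @return a validated \linkS4class{LongitudinalExpressionSet}.
#' @examples
#' m <- matrix(rnorm(12), 2, 6, dimnames = list(c("g1", "g2"), NULL))
#' les <- LongitudinalExpressionSet(m, rep(c("a", "b"), each = 3),
#'                                  rep(1:3, 2), c(a = 0, b = 1))
#' @export
LongitudinalExpressionSet <- function(exprs, subject, time, labels) {
    exprs <- as.matrix(exprs)
    subject <- as.character(subject)
    if (is.null(names(labels))) stop("labels must be named by subject id")
    miss <- setdiff(subject, names(labels))
    if (length(miss))
        stop("subjects without a label: ", paste(miss, collapse = ", "))
    lab <- as.numeric(labels[subject])
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    cd <- S4Vectors::DataFrame(subject = subject, time = as.numeric(time),
                               label = lab)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd)
    new("LongitudinalExpressionSet", se)
}

#' @describeIn LongitudinalExpressionSet subject identifiers, in order of first
#'   appearance.
#' @param x a \code{LongitudinalExpressionSet}.
#' @export
subjectIDs <- function(x) unique(SummarizedExperiment::colData(x)$subject)

#' @describeIn LongitudinalExpressionSet sorted unique time points.
#' @export
timeGrid <- function(x) sort(unique(SummarizedExperiment::colData(x)$time))

#' @describeIn LongitudinalExpressionSet named 0/1 label per subject.
#' @export
phenoLabels <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    i <- !duplicated(cd$subject)
    stats::setNames(cd$label[i], cd$subject[i])
}

#' @describeIn LongitudinalExpressionSet subjects x times logical availability
#'   mask.
#' @export
availability <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    subj <- subjectIDs(x); tg <- timeGrid(x)
    m <- matrix(FALSE, length(subj), length(tg), dimnames = list(subj, tg))
    m[cbind(match(cd$subject, subj), match(cd$time, tg))] <- TRUE
    m
}

#' @describeIn LongitudinalExpressionSet genes x subjects expression matrix at
#'   one time point (columns named by subject).
#' @param t a time point present in the grid.
#' @export
exprAt <- function(x, t) {
    cd <- SummarizedExperiment::colData(x)
    sel <- which(cd$time == t)
    m <- SummarizedExperiment::assay(x)[, sel, drop = FALSE]
    colnames(m) <- cd$subject[sel]
    m
}

#' @describeIn LongitudinalExpressionSet restrict to a set of subjects.
#' @param ids subject identifiers to keep.
#' @export
subsetSubjects <- function(x, ids) {
    cd <- SummarizedExperiment::colData(x)
    x[, cd$subject %in% ids]
}

# genes x subjects x times array; NA where (subject, time) is not measured.
exprArray <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    subj <- subjectIDs(x); tg <- timeGrid(x); g <- rownames(x)
    arr <- array(NA_real_, c(length(g), length(subj), length(tg)),
                 dimnames = list(g, subj, tg))
    idx <- cbind(match(cd$subject, subj), match(cd$time, tg))
    a <- SummarizedExperiment::assay(x)
    for (j in seq_len(ncol(a))) arr[, idx[j, 1L], idx[j, 2L]] <- a[, j]
    arr
}

setMethod("show", "LongitudinalExpressionSet", function(object) {
    lab <- phenoLabels(object)
    cat(sprintf(paste0("LongitudinalExpressionSet: %d genes, %d subjects ",
                       "(%d vs %d), %d time points\n"),
                nrow(object), length(lab), sum(lab == 0), sum(lab == 1),
                length(timeGrid(object))))
    cat("  time grid:", paste(timeGrid(object), collapse = ", "), "\n")
})

#' Read a long-format expression table and subject labels
#'
#' The expression file is tab-separated with header columns
#' \code{subject_id}, \code{time}, \code{gene_id}, \code{value}; the labels
#' file has \code{subject_id}, \code{label}. Labels are 0/1 or two string
#' levels with \code{reference} naming the level mapped to 0.
#'
#' @param expression_path,labels_path paths to the two TSV files.
#' @param reference optional reference label level (required for string
#'   labels).
#' @return a \linkS4class{LongitudinalExpressionSet}; the time grid is the
#'   sorted union of observed times and the availability mask reflects which
#'   (subject, time) rows exist.
#' @export
readLongTable <- function(expression_path, labels_path, reference = NULL) {
    ex <- read.delim(expression_path, stringsAsFactors = FALSE)
    need <- c("subject_id", "time", "gene_id", "value")
    if (!all(need %in% colnames(ex)))
        stop("expression file must have columns ", paste(need, collapse = ", "))
    key <- paste(ex$subject_id, ex$time, ex$gene_id, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate (subject, time, gene) rows")
    lb <- read.delim(labels_path, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "label") %in% colnames(lb)))
        stop("labels file must have columns subject_id, label")
    miss <- setdiff(unique(ex$subject_id), lb$subject_id)
    if (length(miss))
        stop("subjects in expression but absent from labels: ",
             paste(miss, collapse = ", "))
    lev <- unique(lb$label)
    if (all(lev %in% c(0, 1))) {
        lab <- as.numeric(lb$label)
    } else {
        if (length(lev) != 2)
            stop("labels must be binary (found levels: ",
                 paste(lev, collapse = ", "), ")")
        if (is.null(reference) || !reference %in% lev)
            stop("string labels need 'reference' naming the level coded 0")
        lab <- as.numeric(lb$label != reference)
    }
    labels <- stats::setNames(lab, lb$subject_id)

    genes <- unique(ex$gene_id)
    st <- paste(ex$subject_id, ex$time, sep = "\r")
    cols <- !duplicated(st)
    counts <- table(st)
    if (any(counts != length(genes)))
        stop("every available (subject, time) pair must carry all genes")
    m <- matrix(NA_real_, length(genes), sum(cols),
                dimnames = list(genes, NULL))
    m[cbind(match(ex$gene_id, genes), match(st, st[cols]))] <- ex$value
    LongitudinalExpressionSet(m, ex$subject_id[cols], ex$time[cols], labels)
}

#' Write a LongitudinalExpressionSet as long-format TSV files
#'
#' Inverse of [readLongTable()]; values are written with 15 significant
#' digits so a round trip preserves them.
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @param expression_path,labels_path output paths.
#' @export
writeLongTable <- function(x, expression_path, labels_path) {
    cd <- SummarizedExperiment::colData(x)
    a <- SummarizedExperiment::assay(x)
    df <- data.frame(
        subject_id = rep(cd$subject, each = nrow(a)),
        time = rep(cd$time, each = nrow(a)),
        gene_id = rep(rownames(a), ncol(a)),
        value = sprintf("%.15g", as.vector(a)))
    write.table(df, expression_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    lab <- phenoLabels(x)
    write.table(data.frame(subject_id = names(lab), label = unname(lab)),
                labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Stratified subject-level train/test split
#'
#' Splits subjects (never single measurements) into train and test sets,
#' stratified by phenotype so each half's class ratio approximates the
#' whole (the cohort protocol: a 3:2 split means \code{test_fraction = 0.4}).
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @param test_fraction fraction of subjects assigned to the test set.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @param stratify stratify by label (default TRUE).
#' @return list with elements \code{train} and \code{test}.
#' @export
splitTrainTest <- function(x, test_fraction = 0.4, seed = 1, stratify = TRUE) {
    stopifnot(test_fraction > 0, test_fraction < 1)
    lab <- phenoLabels(x)
    if (min(table(lab)) < 2)
        stop("each class needs at least 2 subjects to split")
    testIDs <- withLocalSeed(seed, {
        if (stratify) {
            unlist(lapply(split(names(lab), lab), function(ids) {
                k <- round(test_fraction * length(ids))
                k <- min(max(k, 1L), length(ids) - 1L)
                sample(ids, k)
            }), use.names = FALSE)
        } else {
            k <- round(test_fraction * length(lab))
            k <- min(max(k, 1L), length(lab) - 1L)
            sample(names(lab), k)
        }
    })
    list(train = subsetSubjects(x, setdiff(names(lab), testIDs)),
         test = subsetSubjects(x, testIDs))
}

#' Standardize each gene to mean 0, sd 1
#'
#' Centering and scaling are pooled over all subjects and time points; the
#' sample standard deviation (n - 1 denominator) is used.
#'
#' @param x a \linkS4class{LongitudinalExpressionSet}.
#' @return the standardized set.
#' @export
standardizeGenes <- function(x) {
    a <- SummarizedExperiment::assay(x)
    m <- rowMeans(a)
    s <- apply(a, 1, sd)
    bad <- which(!is.finite(s) | s == 0)
    if (length(bad))
        stop("zero-variance gene(s): ",
             paste(rownames(a)[bad], collapse = ", "))
    SummarizedExperiment::assay(x) <- (a - m) / s
    x
}
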