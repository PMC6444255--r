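#' @import methods
#' @importFrom stats median plogis qlogis rbinom rnorm runif sd fisher.test
#'   coef setNames
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp sourceCpp
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib longsign, .registration = TRUE
NULL

#' Container for longitudinal two-group expression data
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are genes, columns are the
#' measured (subject, time) pairs, so ragged designs (subjects with different
#' numbers of time points) are represented structurally, without imputation.
#' \code{colData} carries \code{subject}, \code{time} (real-valued, e.g. day
#' 0.5) and \code{label} (0 = reference/uncomplicated, 1 = complicated),
#' constant within subject.
#'
#' @slot .Data inherited \code{SummarizedExperiment} internals.
#' @seealso [LongitudinalExpressionSet()], [readLongTable()]
#' @export
setClass("LongitudinalExpressionSet", contains = "SummarizedExperiment")

setValidity("LongitudinalExpressionSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("subject", "time", "label")
    if (!all(need %in% colnames(cd)))
        return(sprintf("colData must contain columns %s",
                       paste(need, collapse = ", ")))
    if (ncol(object) == 0L) return("at least one (subject, time) column required")
    if (is.null(rownames(object))) return("gene identifiers (rownames) required")
    if (anyDuplicated(rownames(object))) return("duplicated gene identifiers")
    key <- paste(cd$subject, cd$time, sep = "\r")
    if (anyDuplicated(key)) return("duplicated (subject, time) pairs")
    if (!is.numeric(cd$time)) return("time must be numeric")
    if (!all(cd$label %in% c(0, 1))) return("labels must be 0/1")
    lab <- tapply(cd$label, cd$subject, function(v) length(unique(v)))
    if (any(lab != 1L)) return("label must be constant within subject")
    a <- SummarizedExperiment::assay(object)
    if (anyNA(a)) return("expression values must not be missing")
    TRUE
})

#' Per-(gene, time point) estimated group effects and their signs
#'
#' Holds, for every gene and time point, the estimated mean expression
#' difference between the two phenotype groups (class 1 minus class 0), a
#' moderated t statistic (empirical-Bayes variance shrinkage across genes
#' within a time point; reporting only), and the sign in \{-1, 0, +1\} used by
#' the sign average. Time points where a group is empty carry sign 0 and NA
#' estimates.
#'
#' @slot geneIDs character vector of gene identifiers.
#' @slot times numeric vector, the ordered time grid.
#' @slot beta1 genes x times matrix of group mean differences.
#' @slot tstat genes x times matrix of moderated t statistics (may be NA).
#' @slot sign genes x times matrix with entries in \{-1, 0, 1\}.
#' @export
setClass("SignProfile",
    representation(geneIDs = "character", times = "numeric",
                   beta1 = "matrix", tstat = "matrix", sign = "matrix"))

setValidity("SignProfile", function(object) {
    G <- length(object@geneIDs); T <- length(object@times)
    for (s in c("beta1", "tstat", "sign")) {
        m <- slot(object, s)
        if (!identical(dim(m), c(G, T)))
            return(sprintf("%s must be %d x %d", s, G, T))
    }
    if (is.unsorted(object@times, strictly = TRUE))
        return("times must be strictly increasing")
    if (!all(object@sign %in% c(-1, 0, 1))) return("signs must be in {-1,0,1}")
    ok <- is.na(object@beta1) | object@sign == sign(object@beta1)
    if (!all(ok)) return("sign must equal sign(beta1) where beta1 is defined")
    TRUE
})

#' Subject x gene pseudogene summary matrix
#'
#' One value per subject and gene summarizing the gene's time course
#' (sign average, mean, median, or first principal component score).
#'
#' @slot values numeric subjects x genes matrix, no missing entries.
#' @slot method one of \code{"sign_average"}, \code{"mean"}, \code{"median"},
#'   \code{"pc1"}.
#' @slot profile the \linkS4class{SignProfile} used (sign average only), else
#'   \code{NULL}.
#' @export
setClass("PseudogeneMatrix",
    representation(values = "matrix", method = "character", profile = "ANY"))

setValidity("PseudogeneMatrix", function(object) {
    if (anyNA(object@values)) return("pseudogene values must not be missing")
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
        return("values must carry subject rownames and gene colnames")
    if (!object@method %in% c("sign_average", "mean", "median", "pc1"))
        return("unknown method tag")
    TRUE
})

#' Sparse logistic regression model
#'
#' Fit of an L1-style sparse logistic classifier, either by cyclic coordinate
#' descent with soft-threshold updates (LASSO penalty) or by threshold
#' gradient descent regularization (TGDR). Coefficients are stored on the
#' original feature scale; the internal standardization used during fitting is
#' retained in \code{center}/\code{scale}.
#'
#' @slot intercept numeric(1).
#' @slot coefficients named numeric vector over all features (zeros included).
#' @slot solver \code{"cd_lasso"} or \code{"tgdr"}.
#' @slot tuning list: \code{lambda} (cd_lasso) or \code{tau}, \code{dnu},
#'   \code{steps} (tgdr).
#' @slot center,scale per-feature standardization parameters used internally.
#' @export
setClass("SparseLogisticModel",
    representation(intercept = "numeric", coefficients = "numeric",
                   solver = "character", tuning = "list",
                   center = "numeric", scale = "numeric"))

setValidity("SparseLogisticModel", function(object) {
    if (length(object@intercept) != 1L) return("intercept must be scalar")
    if (is.null(names(object@coefficients))) return("coefficients must be named")
    if (!object@solver %in% c("cd_lasso", "tgdr")) return("unknown solver tag")
    TRUE
})

#' Cross-validation result for a tuning grid
#'
#' @slot grid numeric vector of tuning values (lambda for cd_lasso, step count
#'   k for tgdr).
#' @slot cvErrors integer vector: misclassified subjects summed over folds, one
#'   per grid value.
#' @slot chosen the selected tuning value (ties broken toward sparsity: larger
#'   lambda / smaller k).
#' @slot foldGeneLists list of character vectors: genes selected per fold at
#'   the chosen tuning.
#' @slot folds integer vector of fold assignments per subject.
#' @slot solver solver tag.
#' @export
setClass("CVResult",
    representation(grid = "numeric", cvErrors = "numeric", chosen = "numeric",
                   foldGeneLists = "list", folds = "integer",
                   solver = "character"))

setValidity("CVResult", function(object) {
    if (length(object@cvErrors) != length(object@grid))
        return("one CV error per grid value required")
    if (!object@chosen %in% object@grid) return("chosen value not in grid")
    if (abs(min(object@cvErrors) -
            object@cvErrors[match(object@chosen, object@grid)]) > 1e-9)
        return("chosen value must attain the minimum CV error")
    TRUE
})

#' End-to-end fitted pipeline (summarizer + tuned sparse model)
#'
#' @slot summarizer summary tag (\code{"sign_average"}, \code{"mean"},
#'   \code{"median"}, \code{"pc1"}).
#' @slot profile training-derived \linkS4class{SignProfile} (sign average
#'   only), else \code{NULL}.
#' @slot model final \linkS4class{SparseLogisticModel} refit on the full
#'   training set at the chosen tuning.
#' @slot cv the \linkS4class{CVResult} behind the tuning choice.
#' @slot config list of configuration used (folds, seed, grids, solver
#'   settings).
#' @export
setClass("FittedPipeline",
    representation(summarizer = "character", profile = "ANY",
                   model = "SparseLogisticModel", cv = "CVResult",
                   config = "list"))

#' Simulation design: causal logit coefficients over a time grid
#'
#' @slot nSubjects number of subjects per replicate.
#' @slot geneIDs all gene identifiers (causal + noise).
#' @slot times time grid (length T).
#' @slot causal data.frame with columns \code{gene}, \code{timeIndex},
#'   \code{coef}: the nonzero logit coefficients.
#' @slot intercept logit intercept (0 gives ~50\% prevalence).
#' @slot rho AR(1) correlation of a gene's values across time (0 = iid).
#' @slot covModel \code{"ar1"} or \code{"iid"}.
#' @slot dropout per-subject probability of truncating the time course
#'   (0 = all subjects complete).
#' @export
setClass("SimulationDesign",
    representation(nSubjects = "numeric", geneIDs = "character",
                   times = "numeric", causal = "data.frame",
                   intercept = "numeric", rho = "numeric",
                   covModel = "character", dropout = "numeric"))

setValidity("SimulationDesign", function(object) {
    if (!all(object@causal$gene %in% object@geneIDs))
        return("causal genes must be among geneIDs")
    if (!all(object@causal$timeIndex %in% seq_along(object@times)))
        return("causal time indices out of range")
    if (!all(is.finite(object@causal$coef))) return("coefficients must be finite")
    if (object@rho < 0 || object@rho >= 1) return("rho must be in [0, 1)")
    if (!object@covModel %in% c("ar1", "iid")) return("unknown covariate model")
    if (object@dropout < 0 || object@dropout >= 1)
        return("dropout must be in [0, 1)")
    TRUE
})

#' Replicate-study summary (simulation benchmark)
#'
#' Per-replicate results of simulate / split / fit / evaluate runs plus the
#' aggregate columns reported by the simulation benchmark: mean model size,
#' pairwise-Jaccard Rand index across replicate gene lists, per-causal-gene
#' selection frequency (\%), and mean test error rate / BCM / AUPR.
#'
#' @slot perReplicate data.frame, one row per replicate.
#' @slot geneLists list of selected-gene character vectors, one per replicate.
#' @slot causalGenes character vector of the design's causal genes.
#' @slot aggregate named list of the summary columns.
#' @export
setClass("ReplicateSummary",
    representation(perReplicate = "data.frame", geneLists = "list",
                   causalGenes = "character", aggregate = "list"))
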