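#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ComorbidityCohort: binary patient-by-comorbidity data
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"indicators"}
#' assay of 0/1 values with comorbidities as rows and patients as columns
#' (the orientation of a p x n comorbidity-patient matrix). \code{rowData}
#' carries the comorbidity catalog (\code{code}, \code{label},
#' \code{category}, \code{include_flag}); \code{colData} carries per-patient
#' covariates such as \code{discharge_year}.
#'
#' @export
setClass("ComorbidityCohort", contains = "SummarizedExperiment")

.validComorbidityCohort <- function(object) {
    msg <- character()
    if (!"indicators" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'indicators' is missing")
    else {
        x <- SummarizedExperiment::assay(object, "indicators")
        if (!all(x %in% c(0L, 1L)))
            msg <- c(msg, "indicator entries must all be 0 or 1")
    }
    if (nrow(object) < 2L || ncol(object) < 2L)
        msg <- c(msg, "need at least 2 comorbidities and 2 patients")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "patient ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "comorbidity codes must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("ComorbidityCohort", .validComorbidityCohort)

#' PrevalenceEstimates: ML marginal and joint co-occurrence probabilities
#'
#' Per-comorbidity counts \eqn{n_i}, pairwise AND counts \eqn{n_{ij}}, and
#' their (optionally additively smoothed) probability estimates from a
#' cohort of \code{nPatients} patients.
#'
#' @slot codes comorbidity codes, in matrix order
#' @slot nPatients number of patients the counts were taken over
#' @slot marginalCounts integer vector of column sums
#' @slot jointCounts symmetric matrix of pairwise AND counts; diagonal
#'   equals \code{marginalCounts}
#' @slot marginalProbs,jointProbs probability estimates; with pseudocount
#'   \eqn{c > 0}, marginals use \eqn{(n_i + c)/(n + 2c)} and joints
#'   \eqn{(n_{ij} + c)/(n + 4c)}
#' @slot pseudocount the additive smoothing constant used (0 = raw MLE)
#' @export
setClass("PrevalenceEstimates",
    representation(codes = "character", nPatients = "integer",
        marginalCounts = "numeric", jointCounts = "matrix",
        marginalProbs = "numeric", jointProbs = "matrix",
        pseudocount = "numeric"))

setValidity("PrevalenceEstimates", function(object) {
    msg <- character()
    p <- length(object@codes)
    if (length(object@marginalCounts) != p ||
        !all(dim(object@jointCounts) == p))
        msg <- c(msg, "count dimensions do not match the code vector")
    if (!isTRUE(all.equal(object@jointCounts, t(object@jointCounts))))
        msg <- c(msg, "joint count matrix must be symmetric")
    if (any(object@marginalProbs < 0 | object@marginalProbs > 1))
        msg <- c(msg, "marginal probabilities outside [0, 1]")
    nij <- object@jointCounts
    ni <- object@marginalCounts
    if (any(nij > pmin(rep(ni, each = p), rep(ni, times = p)) + 1e-9))
        msg <- c(msg, "joint counts exceed min of marginal counts")
    if (length(msg)) msg else TRUE
})

#' CouplingMatrix: pairwise comorbidity coupling strengths
#'
#' Symmetric matrix of coupling strengths \eqn{J_{ij}} (pointwise mutual
#' information by default) with zero diagonal. Pairs whose joint count is
#' zero under the \code{"mask"} policy are flagged in \code{mask} and carry
#' no weight downstream.
#'
#' @slot codes node order
#' @slot J symmetric coupling matrix, diagonal 0
#' @slot mask logical matrix; TRUE marks pairs with undefined coupling
#' @slot logBase "natural" or "10"
#' @slot formula "pmi" (ratio) or "literal" (product) form
#' @export
setClass("CouplingMatrix",
    representation(codes = "character", J = "matrix", mask = "matrix",
        logBase = "character", formula = "character"))

setValidity("CouplingMatrix", function(object) {
    msg <- character()
    p <- length(object@codes)
    if (!all(dim(object@J) == p) || !all(dim(object@mask) == p))
        msg <- c(msg, "matrix dimensions do not match the code vector")
    if (!isTRUE(all.equal(object@J, t(object@J), tolerance = 1e-10)))
        msg <- c(msg, "J must be symmetric")
    if (any(abs(diag(object@J)) > 1e-12))
        msg <- c(msg, "diagonal of J must be 0")
    if (any(!is.finite(object@J[!object@mask])))
        msg <- c(msg, "non-finite J outside the masked set")
    if (length(msg)) msg else TRUE
})

#' ModulePartition: disease modules from coupling-threshold components
#'
#' Connected components (size >= 2) of the network restricted to edges with
#' coupling strictly above \code{threshold}; remaining nodes are singletons.
#'
#' @slot threshold the coupling cutoff applied (signed, strict)
#' @slot clusters list of character vectors, the disease modules
#' @slot singletons nodes in no module
#' @export
setClass("ModulePartition",
    representation(threshold = "numeric", clusters = "list",
        singletons = "character"))

setValidity("ModulePartition", function(object) {
    all_nodes <- c(unlist(object@clusters), object@singletons)
    if (anyDuplicated(all_nodes))
        "clusters and singletons must be disjoint" else TRUE
})

#' OplsdaModel: fitted two-class OPLS-DA model
#'
#' One predictive component (the two-class response spans rank one) plus
#' \code{nOrtho} orthogonal components removed by NIPALS-style deflation.
#' Scores/loadings follow the usual O-PLS notation: predictive
#' \eqn{t, p, w} and orthogonal \eqn{t_o, p_o, w_o}.
#'
#' @slot features feature names retained in the fit
#' @slot dropped zero-variance features removed before scaling
#' @slot classes the two group labels, in (-1, +1) encoding order
#' @slot center,scale centering/scaling vectors applied to X
#' @slot yMean mean of the +/-1 response
#' @slot weights,loadings,scores predictive component vectors
#' @slot q regression of centered y on the predictive score
#' @slot orthoWeights,orthoLoadings,orthoScores matrices, one column per
#'   orthogonal component (possibly 0 columns)
#' @slot r2x,r2y fractions of X / Y sum of squares explained
#' @slot vip per-feature variable importance in projection
#' @export
setClass("OplsdaModel",
    representation(features = "character", dropped = "character",
        classes = "character", center = "numeric", scale = "numeric",
        yMean = "numeric", weights = "numeric", loadings = "numeric",
        scores = "numeric", q = "numeric", orthoWeights = "matrix",
        orthoLoadings = "matrix", orthoScores = "matrix",
        r2x = "numeric", r2y = "numeric", vip = "numeric"))

#' @describeIn ComorbidityCohort compact display
#' @param object a \code{ComorbidityCohort}
#' @export
setMethod("show", "ComorbidityCohort", function(object) {
    x <- SummarizedExperiment::assay(object, "indicators")
    cat(sprintf("ComorbidityCohort: %d comorbidities x %d patients\n",
        nrow(x), ncol(x)))
    cat(sprintf("  mean comorbidities per patient: %.2f\n", mean(colSums(x))))
    cv <- names(SummarizedExperiment::colData(object))
    if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "CouplingMatrix", function(object) {
    p <- length(object@codes)
    nm <- sum(object@mask[upper.tri(object@mask)])
    cat(sprintf("CouplingMatrix: %d nodes, %d pairs (%d masked), log base %s, %s form\n",
        p, p * (p - 1L) / 2L, nm, object@logBase, object@formula))
    jj <- object@J[upper.tri(object@J)][!object@mask[upper.tri(object@mask)]]
    if (length(jj))
        cat(sprintf("  J range: [%.3f, %.3f]\n", min(jj), max(jj)))
    invisible(NULL)
})

setMethod("show", "ModulePartition", function(object) {
    cat(sprintf("ModulePartition at J > %g: %d modules, %d singletons\n",
        object@threshold, length(object@clusters),
        length(object@singletons)))
    for (cl in object@clusters)
        cat("  {", paste(cl, collapse = ", "), "}\n")
    invisible(NULL)
})

setMethod("show", "OplsdaModel", function(object) {
    cat(sprintf("OplsdaModel: %d features, classes %s vs %s, %d orthogonal component(s)\n",
        length(object@features), object@classes[1], object@classes[2],
        ncol(object@orthoScores)))
    cat(sprintf("  R2X = %.3f, R2Y = %.3f\n", object@r2x, object@r2y))
    invisible(NULL)
})

setMethod("show", "PrevalenceEstimates", function(object) {
    cat(sprintf("PrevalenceEstimates: %d comorbidities over %d patients (pseudocount %g)\n",
        length(object@codes), object@nPatients, object@pseudocount))
    invisible(NULL)
})
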