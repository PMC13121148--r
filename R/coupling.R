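#' Maximum-likelihood prevalence and co-occurrence estimates
#'
#' Counts are exact: marginal counts are row sums of the indicator matrix,
#' joint counts pairwise AND sums. With pseudocount \eqn{c > 0},
#' probabilities are additively smoothed: marginals
#' \eqn{(n_i + c)/(n + 2c)}, joints \eqn{(n_{ij} + c)/(n + 4c)}; with
#' \eqn{c = 0} they are the raw MLE \eqn{n_i/n} and \eqn{n_{ij}/n}.
#'
#' @param cohort a \linkS4class{ComorbidityCohort} with no degenerate
#'   columns (prevalence 0 or 1 is an error; filter first)
#' @param pseudocount nonnegative additive smoothing constant
#' @return a \linkS4class{PrevalenceEstimates}
#' @examples
#' coh <- ComorbidityCohort(rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0)))
#' est <- estimateProbabilities(coh)
#' marginalProbs(est)  # 0.5 0.5
#' @export
estimateProbabilities <- function(cohort, pseudocount = 0) {
    stopifnot(pseudocount >= 0)
    x <- indicators(cohort)
    n <- ncol(x)
    cs <- rowSums(x)
    if (any(cs == 0L | cs == n))
        stop("degenerate column(s) present (prevalence 0 or 1): ",
            paste(rownames(x)[cs == 0L | cs == n], collapse = ", "),
            "; run filterComorbidities() first")
    joint <- tcrossprod(x)           # n_ij, diagonal n_i
    storage.mode(joint) <- "double"
    c0 <- pseudocount
    methods::new("PrevalenceEstimates", codes = rownames(x),
        nPatients = as.integer(n), marginalCounts = as.numeric(cs),
        jointCounts = joint,
        marginalProbs = as.numeric((cs + c0) / (n + 2 * c0)),
        jointProbs = (joint + c0) / (n + 4 * c0),
        pseudocount = c0)
}

#' Accessors for PrevalenceEstimates
#' @param est a \linkS4class{PrevalenceEstimates}
#' @return numeric vector / matrix
#' @export
marginalProbs <- function(est) stats::setNames(est@marginalProbs, est@codes)

#' @rdname marginalProbs
#' @export
jointProbs <- function(est) est@jointProbs

#' Pairwise coupling-strength matrix
#'
#' The coupling strength between comorbidities i and j is the pointwise
#' mutual information of their co-occurrence,
#' \deqn{J_{ij} = \log \frac{P(i \cap j)}{P(i)\,P(j)},}
#' the log-likelihood ratio of observed versus independence co-occurrence:
#' zero under exact independence, positive for synergistic co-occurrence,
#' negative for avoidance. An audit-only \code{formula = "literal"} variant
#' computes \eqn{\log(P(i) P(j) P(i \cap j))} instead.
#'
#' Pairs never observed together (\eqn{n_{ij} = 0}) have
#' \eqn{J = -\infty} under the raw MLE; \code{zeroPolicy = "mask"}
#' (default) flags them as undefined and they carry no network edge, while
#' \code{"smooth"} requires the estimates to have been computed with a
#' positive pseudocount.
#'
#' @param est a \linkS4class{PrevalenceEstimates}
#' @param logBase \code{"natural"} (default) or \code{"10"}
#' @param zeroPolicy \code{"mask"} or \code{"smooth"}
#' @param formula \code{"pmi"} (default) or \code{"literal"}
#' @return a \linkS4class{CouplingMatrix}
#' @examples
#' coh <- ComorbidityCohort(rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0)))
#' couplingStrengths(couplingMatrix(estimateProbabilities(coh)))  # J_AB = 0
#' @export
couplingMatrix <- function(est, logBase = c("natural", "10"),
                           zeroPolicy = c("mask", "smooth"),
                           formula = c("pmi", "literal")) {
    logBase <- match.arg(logBase)
    zeroPolicy <- match.arg(zeroPolicy)
    formula <- match.arg(formula)
    pi <- est@marginalProbs
    if (any(pi <= 0 | pi >= 1))
        stop("marginal probabilities must lie strictly in (0, 1)")
    pij <- est@jointProbs
    zero <- est@jointCounts == 0
    diag(zero) <- FALSE
    if (zeroPolicy == "smooth") {
        if (est@pseudocount <= 0 && any(zero))
            stop("zeroPolicy = 'smooth' requires a positive pseudocount ",
                 "when zero joint counts are present")
        mask <- matrix(FALSE, nrow(pij), ncol(pij))
    } else {
        mask <- zero
    }
    J <- if (formula == "pmi") log(pij / outer(pi, pi))
         else log(pij * outer(pi, pi))
    if (logBase == "10") J <- J / log(10)
    diag(J) <- 0
    J[mask] <- 0
    dimnames(J) <- dimnames(mask) <- list(est@codes, est@codes)
    methods::new("CouplingMatrix", codes = est@codes, J = J, mask = mask,
        logBase = logBase, formula = formula)
}

#' Accessors for CouplingMatrix
#' @param cm a \linkS4class{CouplingMatrix}
#' @return matrix / character vector
#' @export
couplingStrengths <- function(cm) cm@J

#' @rdname couplingStrengths
#' @export
couplingMask <- function(cm) cm@mask

#' @rdname couplingStrengths
#' @export
nodeCodes <- function(cm) cm@codes

#' Extract an edge list from a coupling matrix
#'
#' Upper-triangle pairs with \eqn{|J| \ge} \code{minAbsJ}, masked pairs
#' excluded, sorted by \eqn{|J|} descending.
#'
#' @param cm a \linkS4class{CouplingMatrix}
#' @param minAbsJ minimum absolute coupling to report
#' @return data.frame with columns \code{code_i}, \code{code_j}, \code{J}
#' @export
edgeList <- function(cm, minAbsJ = 0) {
    ut <- upper.tri(cm@J)
    keep <- ut & !cm@mask & abs(cm@J) >= minAbsJ
    idx <- which(keep, arr.ind = TRUE)
    out <- data.frame(code_i = cm@codes[idx[, 1]],
        code_j = cm@codes[idx[, 2]], J = cm@J[keep])
    out[order(-abs(out$J)), , drop = FALSE]
}
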