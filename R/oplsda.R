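#' @keywords internal
#' Extract samples-x-features matrix and +/-1 response for two groups.
.oplsXy <- function(se, groups) {
    stopifnot(length(groups) == 2L)
    grp <- SummarizedExperiment::colData(se)$group
    sel <- grp %in% groups
    if (sum(grp == groups[1]) == 0L || sum(grp == groups[2]) == 0L)
        stop("both groups must be present: ",
            paste(groups, collapse = ", "))
    X <- t(SummarizedExperiment::assay(se, "intensity")[, sel,
        drop = FALSE])
    y <- ifelse(grp[sel] == groups[1], -1, 1)
    list(X = X, y = y)
}

# Core NIPALS O-PLS fit on a plain samples-x-features matrix.
# Returns centering/scaling, predictive w/p/t/q, orthogonal W/P/T.
.oplsCore <- function(X, y, nOrtho, scaling) {
    ctr <- colMeans(X)
    scl <- switch(scaling,
        uv = apply(X, 2, stats::sd),
        pareto = sqrt(apply(X, 2, stats::sd)),
        none = rep(1, ncol(X)))
    keep <- scl > 0
    Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2,
        scl[keep], "/")
    ym <- mean(y)
    yc <- y - ym
    ssxTot <- sum(Xs^2)
    w <- drop(crossprod(Xs, yc))
    w <- w / sqrt(sum(w^2))
    p <- ncol(Xs)
    Wo <- matrix(0, p, 0)
    Po <- matrix(0, p, 0)
    To <- matrix(0, nrow(Xs), 0)
    Xd <- Xs
    for (a in seq_len(nOrtho)) {
        t1 <- drop(Xd %*% w)
        pv <- drop(crossprod(Xd, t1)) / sum(t1^2)
        wo <- pv - sum(w * pv) * w
        nw <- sqrt(sum(wo^2))
        if (nw < 1e-12) break      # no orthogonal variation left
        wo <- wo / nw
        to <- drop(Xd %*% wo)
        po <- drop(crossprod(Xd, to)) / sum(to^2)
        Xd <- Xd - tcrossprod(to, po)
        Wo <- cbind(Wo, wo)
        Po <- cbind(Po, po)
        To <- cbind(To, to)
    }
    t1 <- drop(Xd %*% w)
    p1 <- drop(crossprod(Xd, t1)) / sum(t1^2)
    q1 <- sum(yc * t1) / sum(t1^2)
    r2y <- if (sum(yc^2) > 0)
        1 - sum((yc - t1 * q1)^2) / sum(yc^2) else NA_real_
    ssMod <- sum(t1^2) * sum(p1^2) +
        if (ncol(To)) sum(colSums(To^2) * colSums(Po^2)) else 0
    list(center = ctr[keep], scale = scl[keep], keep = keep, yMean = ym,
        w = w, p = p1, t = t1, q = q1, Wo = Wo, Po = Po, To = To,
        r2x = ssMod / ssxTot, r2y = r2y)
}

# Predict on new raw data with a .oplsCore fit.
.oplsPredict <- function(fit, Xnew) {
    Xc <- sweep(sweep(Xnew[, fit$keep, drop = FALSE], 2, fit$center), 2,
        fit$scale, "/")
    for (a in seq_len(ncol(fit$Wo))) {
        to <- drop(Xc %*% fit$Wo[, a])
        Xc <- Xc - tcrossprod(to, fit$Po[, a])
    }
    t1 <- drop(Xc %*% fit$w)
    list(scores = t1, yhat = t1 * fit$q + fit$yMean)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for
#' a binary class response encoded -1/+1 (first label -1). The model has
#' one predictive component — a two-class response spans rank one — and
#' \code{nOrtho} orthogonal components removed by NIPALS-style deflation:
#' for each orthogonal component the Y-orthogonal part of the X loading is
#' split off and its variation deflated from X before the predictive
#' component is extracted. With \code{nOrtho = 0} the fit reduces to
#' single-component PLS1.
#'
#' Features are mean-centered and unit-variance scaled by default
#' (\code{scaling = "uv"}); zero-variance features are dropped with a
#' message. \code{nOrtho = "auto"} picks the count in 0..3 maximizing
#' cross-validated Q-squared.
#'
#' @param se omics \code{SummarizedExperiment} (see \code{\link{OmicsTable}})
#' @param groups the two class labels, reference first
#' @param nOrtho number of orthogonal components, or \code{"auto"}
#' @param scaling \code{"uv"}, \code{"pareto"} or \code{"none"}
#' @param nFolds,seed cross-validation settings used when
#'   \code{nOrtho = "auto"}
#' @return an \linkS4class{OplsdaModel}
#' @export
fitOplsda <- function(se, groups, nOrtho = 1L,
                      scaling = c("uv", "pareto", "none"),
                      nFolds = 7L, seed = 1L) {
    scaling <- match.arg(scaling)
    xy <- .oplsXy(se, groups)
    if (nrow(xy$X) < 4L) stop("need at least 4 samples")
    if (identical(nOrtho, "auto")) {
        cand <- 0:min(3L, nrow(xy$X) - 2L)
        q2 <- vapply(cand, function(k)
            .oplsCV(xy$X, xy$y, k, scaling, nFolds, seed)$q2, numeric(1))
        nOrtho <- cand[which.max(q2)]
    }
    fit <- .oplsCore(xy$X, xy$y, nOrtho, scaling)
    feats <- colnames(xy$X)[fit$keep]
    dropped <- colnames(xy$X)[!fit$keep]
    if (length(dropped))
        message("dropping ", length(dropped),
            " zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    vip <- sqrt(length(fit$w)) * abs(fit$w)   # single predictive comp
    methods::new("OplsdaModel", features = feats, dropped = dropped,
        classes = as.character(groups), center = fit$center,
        scale = fit$scale, yMean = fit$yMean,
        weights = stats::setNames(fit$w, feats),
        loadings = stats::setNames(fit$p, feats),
        scores = fit$t, q = fit$q,
        orthoWeights = fit$Wo, orthoLoadings = fit$Po,
        orthoScores = fit$To, r2x = fit$r2x, r2y = fit$r2y,
        vip = stats::setNames(vip, feats))
}

#' Variable importance in projection
#'
#' Predictive-component VIP (default): with one predictive component and
#' normalized weights, \eqn{VIP_k = \sqrt{p}\,|w_k|}, so the mean of
#' squared VIPs is exactly 1. \code{type = "total"} additionally spreads
#' importance over the orthogonal components, weighting each component's
#' normalized squared loadings by the X sum of squares it explains.
#'
#' @param model a fitted \linkS4class{OplsdaModel}
#' @param type \code{"predictive"} or \code{"total"}
#' @return named numeric vector, one VIP per retained feature
#' @export
vipScores <- function(model, type = c("predictive", "total")) {
    type <- match.arg(type)
    if (!length(model@weights)) stop("model is not fitted")
    if (type == "predictive") return(model@vip)
    p <- length(model@weights)
    ssx <- c(sum(model@scores^2) * sum(model@loadings^2),
        if (ncol(model@orthoScores))
            colSums(model@orthoScores^2) * colSums(model@orthoLoadings^2))
    L <- cbind(model@weights,
        if (ncol(model@orthoWeights)) model@orthoWeights)
    L2 <- sweep(L^2, 2, colSums(L^2), "/")
    stats::setNames(sqrt(p * drop(L2 %*% ssx) / sum(ssx)),
        names(model@weights))
}

# Stratified fold assignment; redraws until every training set holds both
# classes.
.foldAssign <- function(y, nFolds, seed) {
    n <- length(y)
    nFolds <- min(nFolds, n)
    for (try in 1:100) {
        folds <- integer(n)
        withr::with_seed(seed + try - 1L, {
            offset <- 0L
            for (cls in unique(y)) {
                idx <- sample(which(y == cls))
                folds[idx] <- (offset + seq_along(idx) - 1L) %%
                    nFolds + 1L
                offset <- offset + length(idx)
            }
        })
        ok <- all(vapply(seq_len(nFolds), function(k)
            length(unique(y[folds != k])) == 2L, logical(1)))
        if (ok) return(folds)
    }
    stop("could not assign folds leaving both classes in every ",
        "training set")
}

.oplsCV <- function(X, y, nOrtho, scaling, nFolds, seed) {
    folds <- .foldAssign(y, nFolds, seed)
    nFolds <- max(folds)
    press <- 0
    for (k in seq_len(nFolds)) {
        tr <- folds != k
        fit <- .oplsCore(X[tr, , drop = FALSE], y[tr], nOrtho, scaling)
        pred <- .oplsPredict(fit, X[!tr, , drop = FALSE])
        press <- press + sum((y[!tr] - pred$yhat)^2)
    }
    ssy <- sum((y - mean(y))^2)
    list(q2 = 1 - press / ssy, nFolds = nFolds)
}

#' Cross-validated predictive ability (Q-squared)
#'
#' Stratified k-fold cross-validation with centering/scaling recomputed on
#' every training fold; \eqn{Q^2 = 1 - PRESS / SSY}. \code{nFolds} equal
#' to the sample count gives leave-one-out.
#'
#' @inheritParams fitOplsda
#' @param nOrtho number of orthogonal components
#' @return list with \code{q2}, \code{r2y}, \code{n_folds}, \code{seed}
#' @export
crossValidate <- function(se, groups, nOrtho = 1L, nFolds = 7L,
                          seed = 1L, scaling = c("uv", "pareto", "none")) {
    scaling <- match.arg(scaling)
    xy <- .oplsXy(se, groups)
    cv <- .oplsCV(xy$X, xy$y, nOrtho, scaling, nFolds, seed)
    fit <- .oplsCore(xy$X, xy$y, nOrtho, scaling)
    list(q2 = cv$q2, r2y = fit$r2y, n_folds = cv$nFolds, seed = seed)
}

#' Permutation test of the OPLS-DA model
#'
#' Class labels are permuted across samples \code{nPerm} times; each
#' permuted model's cross-validated Q-squared is compared with the
#' observed one and
#' \deqn{p = \frac{1 + \#\{Q^2_{perm} \ge Q^2_{obs}\}}{nPerm + 1}.}
#'
#' @inheritParams crossValidate
#' @param nPerm number of label permutations
#' @return list with \code{p}, \code{q2_observed}, \code{q2_permuted},
#'   \code{n_permutations}, \code{seed}
#' @export
permutationTest <- function(se, groups, nOrtho = 1L, nPerm = 1000L,
                            nFolds = 7L, seed = 1L,
                            scaling = c("uv", "pareto", "none")) {
    stopifnot(nPerm >= 1)
    scaling <- match.arg(scaling)
    xy <- .oplsXy(se, groups)
    obs <- .oplsCV(xy$X, xy$y, nOrtho, scaling, nFolds, seed)$q2
    perms <- withr::with_seed(seed,
        replicate(nPerm, sample(xy$y), simplify = FALSE))
    q2p <- vapply(seq_len(nPerm), function(b)
        .oplsCV(xy$X, perms[[b]], nOrtho, scaling, nFolds,
            seed + b)$q2, numeric(1))
    list(p = (1 + sum(q2p >= obs)) / (nPerm + 1), q2_observed = obs,
        q2_permuted = q2p, n_permutations = nPerm, seed = seed)
}
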