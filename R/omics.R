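#' Construct an omics intensity table
#'
#' A \linkS4class{SummarizedExperiment} with one \code{"intensity"} assay
#' (features x samples, positive reals: relative intensity or ng/ml) and
#' sample annotation \code{group} (e.g. HC / PV_pre / PV_post) plus an
#' optional \code{subject} id linking paired samples.
#'
#' @param intensities numeric matrix, features x samples
#' @param group character/factor, one label per sample
#' @param subject optional subject id per sample for paired contrasts
#' @return a \code{SummarizedExperiment}
#' @export
OmicsTable <- function(intensities, group, subject = NULL) {
    intensities <- as.matrix(intensities)
    if (is.null(rownames(intensities)))
        rownames(intensities) <- paste0("f", seq_len(nrow(intensities)))
    if (is.null(colnames(intensities)))
        colnames(intensities) <- paste0("s", seq_len(ncol(intensities)))
    if (length(group) != ncol(intensities))
        stop("one group label per sample required")
    cd <- S4Vectors::DataFrame(group = as.character(group),
        row.names = colnames(intensities))
    if (!is.null(subject)) cd$subject <- as.character(subject)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensities), colData = cd)
}

#' Read an omics table and its sample sheet
#'
#' \code{tablePath}: TSV/CSV, first column feature ids, remaining columns
#' samples. \code{designPath}: sample sheet with columns \code{sample},
#' \code{group} and optional \code{subject}.
#' @param tablePath intensity matrix file
#' @param designPath sample sheet file
#' @return a \code{SummarizedExperiment}
#' @export
readOmicsTable <- function(tablePath, designPath) {
    tab <- .readDelim(tablePath)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    design <- .readDelim(designPath)
    if (!all(c("sample", "group") %in% names(design)))
        stop("sample sheet needs 'sample' and 'group' columns")
    miss <- setdiff(colnames(m), design$sample)
    if (length(miss))
        stop("samples missing from sheet: ", paste(miss, collapse = ", "))
    design <- design[match(colnames(m), design$sample), , drop = FALSE]
    OmicsTable(m, design$group,
        if ("subject" %in% names(design)) design$subject else NULL)
}

.groupMatrix <- function(se, label) {
    grp <- SummarizedExperiment::colData(se)$group
    sel <- grp == label
    if (!any(sel)) stop("no samples in group: ", label)
    SummarizedExperiment::assay(se, "intensity")[, sel, drop = FALSE]
}

#' Per-feature fold change between two groups
#'
#' Fold change is the ratio of raw-scale group means,
#' comparison / reference (e.g. PV_post / PV_pre). A zero reference mean
#' yields \code{NA} with a \code{flagged} marker.
#'
#' @param se omics \code{SummarizedExperiment}
#' @param reference,comparison group labels
#' @return \code{DataFrame}: \code{feature}, \code{refMean},
#'   \code{cmpMean}, \code{fc}, \code{flagged}
#' @export
foldChange <- function(se, reference, comparison) {
    refMean <- rowMeans(.groupMatrix(se, reference))
    cmpMean <- rowMeans(.groupMatrix(se, comparison))
    fc <- ifelse(refMean == 0, NA_real_, cmpMean / refMean)
    S4Vectors::DataFrame(feature = rownames(se),
        refMean = unname(refMean), cmpMean = unname(cmpMean),
        fc = unname(fc), flagged = unname(refMean == 0),
        row.names = rownames(se))
}

#' Per-feature two-group test
#'
#' Unpaired contrasts use Welch's two-sample t test; paired contrasts a
#' paired t on subject-matched differences (requires a subject bijection
#' between the groups). \code{method = "ranksum"} substitutes the
#' Mann-Whitney / Wilcoxon signed-rank test. \code{logTransform} applies a
#' natural log before testing.
#'
#' @param se omics \code{SummarizedExperiment}
#' @param reference,comparison group labels
#' @param paired match samples by subject id
#' @param logTransform test on the natural-log scale
#' @param method \code{"t"} or \code{"ranksum"}
#' @return named numeric vector of two-sided p-values
#' @export
groupTest <- function(se, reference, comparison, paired = FALSE,
                      logTransform = FALSE,
                      method = c("t", "ranksum")) {
    method <- match.arg(method)
    xr <- .groupMatrix(se, reference)
    xc <- .groupMatrix(se, comparison)
    if (ncol(xr) < 2L || ncol(xc) < 2L)
        stop("need at least 2 samples per group")
    if (paired) {
        cd <- SummarizedExperiment::colData(se)
        if (is.null(cd$subject))
            stop("paired test requires a 'subject' column")
        sr <- cd$subject[cd$group == reference]
        sc <- cd$subject[cd$group == comparison]
        unmatched <- c(setdiff(sr, sc), setdiff(sc, sr))
        if (length(unmatched) || anyDuplicated(sr) || anyDuplicated(sc))
            stop("paired groups must map subjects one-to-one; offending ",
                "subject(s): ",
                paste(unique(c(unmatched, sr[duplicated(sr)],
                    sc[duplicated(sc)])), collapse = ", "))
        xc <- xc[, match(sr, sc), drop = FALSE]
    }
    if (logTransform) {
        xr <- log(xr)
        xc <- log(xc)
    }
    p <- vapply(seq_len(nrow(xr)), function(i) {
        a <- xr[i, ]; b <- xc[i, ]
        if (method == "t") {
            if (paired) {
                d <- b - a
                if (stats::sd(d) == 0)
                    return(if (mean(d) == 0) 1 else 0)
                stats::t.test(d)$p.value
            } else {
                if (stats::sd(a) == 0 && stats::sd(b) == 0)
                    return(if (mean(a) == mean(b)) 1 else 0)
                stats::t.test(a, b)$p.value
            }
        } else {
            suppressWarnings(if (paired)
                stats::wilcox.test(b, a, paired = TRUE)$p.value
            else stats::wilcox.test(a, b)$p.value)
        }
    }, numeric(1))
    stats::setNames(p, rownames(se))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' clipped to 1. NA p-values propagate as NA.
#' @param p numeric p-values in [0, 1]
#' @return q-values of the same length
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Combined differential-screening verdicts
#'
#' A feature is \code{"up"} iff fc >= \code{fcUp}, its (q if
#' \code{useFdr} else raw) p < \code{alpha}, and, when VIP scores are
#' supplied, VIP > \code{vipMin}; \code{"down"} symmetrically with fc <=
#' \code{fcDown}; otherwise \code{"ns"}.
#'
#' @param dr \code{DataFrame}/data.frame with columns \code{fc}, \code{p}
#'   and optionally \code{q}, \code{vip}
#' @param fcUp,fcDown fold-change gates (defaults 1.20 / 0.86)
#' @param alpha significance level
#' @param vipMin VIP gate (applied only when a \code{vip} column exists)
#' @param useFdr gate on BH q instead of raw p
#' @return input with a \code{verdict} column plus a \code{"summary"}
#'   attribute of up/down/ns counts
#' @export
screenFeatures <- function(dr, fcUp = 1.20, fcDown = 0.86, alpha = 0.05,
                           vipMin = 1.0, useFdr = FALSE) {
    stopifnot(fcUp > 1, fcDown < 1, fcDown > 0, alpha > 0)
    pGate <- if (useFdr) {
        if (is.null(dr$q)) stop("useFdr = TRUE but no 'q' column")
        dr$q
    } else dr$p
    sig <- !is.na(pGate) & pGate < alpha
    if (!is.null(dr$vip)) sig <- sig & !is.na(dr$vip) & dr$vip > vipMin
    verdict <- rep("ns", nrow(dr))
    verdict[sig & !is.na(dr$fc) & dr$fc >= fcUp] <- "up"
    verdict[sig & !is.na(dr$fc) & dr$fc <= fcDown] <- "down"
    dr$verdict <- verdict
    attr(dr, "summary") <- c(up = sum(verdict == "up"),
        down = sum(verdict == "down"), ns = sum(verdict == "ns"))
    dr
}

#' One-stop differential screening for a contrast
#'
#' Fold change, test p, BH q, optional OPLS-DA VIP, and verdicts.
#'
#' @inheritParams groupTest
#' @param withVip fit an OPLS-DA on the contrast and gate on its VIP
#' @param nOrtho orthogonal components for the OPLS-DA (see
#'   \code{\link{fitOplsda}})
#' @param ... passed to \code{\link{screenFeatures}}
#' @return \code{DataFrame} with means, fc, p, q, (vip), verdict
#' @export
differentialScreen <- function(se, reference, comparison, paired = FALSE,
                               logTransform = FALSE,
                               method = c("t", "ranksum"),
                               withVip = FALSE, nOrtho = 1L, ...) {
    dr <- foldChange(se, reference, comparison)
    dr$p <- groupTest(se, reference, comparison, paired = paired,
        logTransform = logTransform, method = match.arg(method))
    dr$q <- bhAdjust(dr$p)
    if (withVip) {
        fit <- fitOplsda(se, c(reference, comparison), nOrtho = nOrtho)
        dr$vip <- vipScores(fit)[rownames(dr)]
    }
    screenFeatures(dr, ...)
}
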