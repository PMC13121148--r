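#' Split a cohort on a covariate cutpoint
#'
#' Patients with covariate value <= \code{cutpoint} go to subset A, the
#' rest to subset B (e.g. \code{discharge_year} at 2014 for 1993-2014 vs
#' 2015-2024 eras). Comorbidity columns are harmonized to the intersection
#' of columns non-degenerate in both subsets; dropped codes are reported.
#'
#' @param cohort a \linkS4class{ComorbidityCohort}
#' @param covariate covariate column name (numeric)
#' @param cutpoint split value
#' @return list with elements \code{A}, \code{B}
#'   (\linkS4class{ComorbidityCohort}) and \code{dropped} codes
#' @export
splitCohort <- function(cohort, covariate, cutpoint) {
    cov <- patientData(cohort)
    if (!covariate %in% names(cov))
        stop("covariate not found: ", covariate)
    v <- cov[[covariate]]
    if (anyNA(v)) stop("covariate has missing values: ", covariate)
    inA <- v <= cutpoint
    if (!any(inA) || all(inA))
        stop("split on ", covariate, " at ", cutpoint,
            " leaves an empty subset")
    a <- cohort[, inA]
    b <- cohort[, !inA]
    ok <- function(m) {
        cs <- rowSums(indicators(m))
        cs > 0L & cs < ncol(m)
    }
    keep <- ok(a) & ok(b)
    dropped <- rownames(cohort)[!keep]
    if (length(dropped))
        message("dropping ", length(dropped),
            " column(s) degenerate in a subset: ",
            paste(dropped, collapse = ", "))
    if (sum(keep) < 2L)
        stop("fewer than 2 comorbidities shared between subsets")
    list(A = a[keep, ], B = b[keep, ], dropped = dropped)
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' \eqn{z = \mathrm{atanh}(r)}, CI \eqn{\tanh(z \pm z_{1-\alpha/2} /
#' \sqrt{n - 3})}.
#'
#' @param r correlation
#' @param n number of paired values (must exceed 3)
#' @param level confidence level
#' @return numeric c(lower, upper)
#' @examples
#' round(fisherZCI(0.7179, 78), 4)  # 0.5896 0.8109
#' @export
fisherZCI <- function(r, n, level = 0.95) {
    if (n < 4) stop("Fisher-z CI undefined for n < 4")
    z <- atanh(r)
    h <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
    c(lower = tanh(z - h), upper = tanh(z + h))
}

#' Node strengths of a coupling matrix
#'
#' \eqn{\sum_j |J_{ij}|} over unmasked pairs (masked pairs weigh 0),
#' identical to the network strength centrality of the complete weighted
#' graph.
#' @param cm a \linkS4class{CouplingMatrix}
#' @return named numeric vector
#' @export
nodeStrengths <- function(cm) {
    J <- abs(cm@J)
    J[cm@mask] <- 0
    stats::setNames(rowSums(J), cm@codes)
}

#' Compare two subset networks
#'
#' Pearson correlation of upper-triangle edge weights over pairs unmasked
#' in both subsets and of node strengths, each with a 95\% Fisher-z CI;
#' rank consistency is the top-\code{topK} overlap of strength rankings,
#' with Kendall's tau over all nodes as a secondary measure.
#'
#' @param cmA,cmB \linkS4class{CouplingMatrix} objects over identical node
#'   sets in identical order
#' @param topK size of the top set for rank consistency
#' @param level confidence level for the CIs
#' @return list with \code{edge_r}, \code{edge_ci}, \code{strength_r},
#'   \code{strength_ci}, \code{n_edges}, \code{n_nodes},
#'   \code{rank_consistency}, \code{kendall_tau}
#' @export
compareNetworks <- function(cmA, cmB, topK = 10L, level = 0.95) {
    if (!identical(cmA@codes, cmB@codes))
        stop("coupling matrices must share the same node set and order")
    ut <- upper.tri(cmA@J)
    both <- ut & !cmA@mask & !cmB@mask
    wa <- cmA@J[both]
    wb <- cmB@J[both]
    if (length(wa) < 4L)
        stop("fewer than 4 shared unmasked edges; CI undefined")
    edge_r <- stats::cor(wa, wb)
    sa <- nodeStrengths(cmA)
    sb <- nodeStrengths(cmB)
    if (length(sa) < 4L)
        stop("fewer than 4 nodes; CI undefined")
    strength_r <- stats::cor(sa, sb)
    k <- min(topK, length(sa))
    topA <- names(sort(sa, decreasing = TRUE))[seq_len(k)]
    topB <- names(sort(sb, decreasing = TRUE))[seq_len(k)]
    list(edge_r = edge_r,
        edge_ci = fisherZCI(edge_r, length(wa), level),
        strength_r = strength_r,
        strength_ci = fisherZCI(strength_r, length(sa), level),
        n_edges = length(wa), n_nodes = length(sa),
        rank_consistency = length(intersect(topA, topB)) / k,
        kendall_tau = stats::cor(sa, sb, method = "kendall"))
}

#' Baseline comparability of two cohort subsets
#'
#' Binary variables (comorbidity codes or 0/1 covariates) are compared by
#' a 2x2 chi-square test (no continuity correction) with Cramer's V;
#' continuous covariates by Welch's t test with Cohen's d (pooled SD).
#' Effect-size bands: V < 0.1 negligible, < 0.3 small, < 0.5 moderate,
#' else large; |d| < 0.2 negligible, < 0.5 small, < 0.8 moderate, else
#' large. No multiplicity correction by default (descriptive table);
#' \code{adjust = "BH"} adds a \code{q} column.
#'
#' @param cohortA,cohortB the two subsets
#' @param variables comorbidity codes and/or covariate names
#' @param adjust \code{"none"} or \code{"BH"}
#' @return data.frame with columns \code{variable}, \code{type},
#'   \code{statistic}, \code{p}, \code{effect}, \code{band}
#' @export
baselineComparison <- function(cohortA, cohortB, variables,
                               adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    pull <- function(cohort, v) {
        if (v %in% rownames(cohort)) indicators(cohort)[v, ]
        else if (v %in% names(patientData(cohort)))
            patientData(cohort)[[v]]
        else stop("variable not found in cohort: ", v)
    }
    rows <- lapply(variables, function(v) {
        a <- pull(cohortA, v)
        b <- pull(cohortB, v)
        binary <- all(c(a, b) %in% c(0, 1))
        if (binary) {
            tab <- rbind(c(sum(a == 1), sum(a == 0)),
                         c(sum(b == 1), sum(b == 0)))
            ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
            V <- sqrt(as.numeric(ht$statistic) / sum(tab))
            band <- cut(V, c(-Inf, 0.1, 0.3, 0.5, Inf),
                c("negligible", "small", "moderate", "large"))
            data.frame(variable = v, type = "chi2",
                statistic = as.numeric(ht$statistic), p = ht$p.value,
                effect = V, band = as.character(band))
        } else {
            if (stats::sd(a) == 0 && stats::sd(b) == 0)
                return(data.frame(variable = v, type = "t",
                    statistic = NA_real_, p = NA_real_,
                    effect = NA_real_, band = "zero-variance"))
            ht <- stats::t.test(a, b)
            sp <- sqrt(((length(a) - 1) * stats::var(a) +
                        (length(b) - 1) * stats::var(b)) /
                       (length(a) + length(b) - 2))
            d <- abs(mean(a) - mean(b)) / sp
            band <- cut(d, c(-Inf, 0.2, 0.5, 0.8, Inf),
                c("negligible", "small", "moderate", "large"))
            data.frame(variable = v, type = "t",
                statistic = as.numeric(ht$statistic), p = ht$p.value,
                effect = d, band = as.character(band))
        }
    })
    out <- do.call(rbind, rows)
    if (adjust == "BH") out$q <- bhAdjust(out$p)
    out
}
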