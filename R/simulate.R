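#' Exact distribution of a small binary Markov random field
#'
#' Enumerates all \eqn{2^p} states of the \{0,1\}-spin pairwise model
#' \deqn{P(s) \propto \exp\!\big(\textstyle\sum_i h_i s_i +
#'   \sum_{i<j} J_{ij} s_i s_j\big),}
#' the Boltzmann distribution whose conditional log-odds for node i is
#' \eqn{h_i + \sum_j J_{ij} s_j}. Intended as the brute-force oracle for
#' sampler checks (p <= ~15).
#'
#' @param J symmetric coupling matrix, zero diagonal (model scale)
#' @param h per-node field (recycled)
#' @return list with \code{states} (\eqn{2^p \times p} 0/1 matrix) and
#'   \code{prob}
#' @export
exactIsingDistribution <- function(J, h = 0) {
    J <- as.matrix(J)
    p <- nrow(J)
    stopifnot(isTRUE(all.equal(J, t(J))), all(diag(J) == 0), p <= 20)
    h <- rep_len(h, p)
    states <- as.matrix(expand.grid(rep(list(0:1), p)))
    colnames(states) <- rownames(J) %||% paste0("V", seq_len(p))
    loglik <- drop(states %*% h) +
        0.5 * rowSums((states %*% J) * states)
    w <- exp(loglik - max(loglik))
    list(states = states, prob = w / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic pairwise PMI of a small binary MRF
#'
#' Marginal and pairwise joint probabilities are computed by exact
#' enumeration (\code{\link{exactIsingDistribution}}) and turned into the
#' population pointwise-mutual-information matrix
#' \eqn{\log(P_{ij}/(P_i P_j))} — the quantity the coupling estimator
#' converges to (which is not the generative \code{J} itself).
#'
#' @inheritParams exactIsingDistribution
#' @return symmetric PMI matrix with zero diagonal
#' @export
exactPairwisePMI <- function(J, h = 0) {
    d <- exactIsingDistribution(J, h)
    pi <- drop(crossprod(d$states, d$prob))
    pij <- crossprod(d$states * d$prob, d$states)
    pij <- (pij + t(pij)) / 2
    pmi <- log(pij / outer(pi, pi))
    diag(pmi) <- 0
    dimnames(pmi) <- list(colnames(d$states), colnames(d$states))
    pmi
}

#' Gibbs-sample a binary cohort from an Ising-type model
#'
#' Spins use the \{0,1\} (presence/absence) convention so the conditional
#' log-odds of comorbidity i given the rest is \eqn{h_i + \sum_j J_{ij}
#' s_j}. By default each patient is an independent Gibbs chain, burned in
#' for \code{burnIn} full sweeps from a random start and read out once
#' (sweeps vectorize across patients, so cohorts of thousands are cheap);
#' \code{chains = "single"} instead thins one long chain every
#' \code{thin} sweeps.
#'
#' @param nPatients number of patients to draw
#' @param J symmetric coupling matrix (model scale), zero diagonal
#' @param h per-node external field (recycled; 0 gives prevalence 0.5 at
#'   J = 0)
#' @param burnIn full Gibbs sweeps before readout
#' @param thin sweeps between readouts in \code{"single"} mode
#' @param chains \code{"independent"} or \code{"single"}
#' @param seed RNG seed (bit-reproducible output)
#' @param codes node names (default V1..Vp)
#' @return a \linkS4class{ComorbidityCohort}
#' @examples
#' J <- matrix(c(0, 1, 1, 0), 2)
#' coh <- sampleIsingCohort(500, J, h = -0.5, seed = 1)
#' mean(indicators(coh)[1, ])
#' @export
sampleIsingCohort <- function(nPatients, J, h = 0, burnIn = 500L,
                              thin = 1L, chains = c("independent",
                              "single"), seed = 1L, codes = NULL) {
    chains <- match.arg(chains)
    J <- as.matrix(J)
    p <- nrow(J)
    stopifnot(isTRUE(all.equal(J, t(J))), all(diag(J) == 0),
        burnIn >= 1L, thin >= 1L)
    h <- rep_len(h, p)
    codes <- codes %||% (rownames(J) %||% paste0("V", seq_len(p)))
    sweep1 <- function(S) {
        for (i in seq_len(p)) {
            eta <- h[i] + S %*% J[, i]
            S[, i] <- (stats::runif(nrow(S)) <
                stats::plogis(eta)) + 0L
        }
        S
    }
    S <- withr::with_seed(seed, {
        if (chains == "independent") {
            S <- matrix(stats::rbinom(nPatients * p, 1L, 0.5),
                nPatients, p)
            for (b in seq_len(burnIn)) S <- sweep1(S)
            S
        } else {
            s <- matrix(stats::rbinom(p, 1L, 0.5), 1L, p)
            for (b in seq_len(burnIn)) s <- sweep1(s)
            out <- matrix(0L, nPatients, p)
            for (k in seq_len(nPatients)) {
                for (b in seq_len(thin)) s <- sweep1(s)
                out[k, ] <- s
            }
            out
        }
    })
    dimnames(S) <- list(paste0("p", seq_len(nPatients)), codes)
    ComorbidityCohort(t(S))
}

#' Sample a cohort with planted comorbidity modules
#'
#' Latent-activation generative model: per patient, each module is
#' independently active with probability \code{activationProb}; nodes of
#' an active module are present with probability \code{boostProb}, all
#' other nodes with \code{baselineProb}. Modules are mutually independent,
#' so cross-module couplings vanish while within-module PMI is strongly
#' positive (about 0.94 nats at the defaults), well above the 0.5
#' strong-association threshold.
#'
#' @param nPatients number of patients
#' @param moduleSizes integer vector of module sizes
#' @param activationProb per-patient module activation probability
#' @param baselineProb background presence probability
#' @param boostProb presence probability within an active module
#' @param nNoise additional independent background nodes
#' @param seed RNG seed
#' @return a \linkS4class{ComorbidityCohort}; the catalog's
#'   \code{category} column records the planted module of each node
#'   (\code{"module<k>"} or \code{"noise"})
#' @export
samplePlantedModules <- function(nPatients, moduleSizes = c(3L, 3L),
                                 activationProb = 0.3,
                                 baselineProb = 0.05, boostProb = 0.8,
                                 nNoise = 0L, seed = 1L) {
    stopifnot(all(moduleSizes >= 1L),
        activationProb > 0, activationProb < 1,
        baselineProb > 0, baselineProb < 1,
        boostProb > 0, boostProb < 1)
    nm <- length(moduleSizes)
    codes <- c(unlist(lapply(seq_len(nm), function(k)
        paste0("M", k, "_", seq_len(moduleSizes[k])))),
        if (nNoise) paste0("N", seq_len(nNoise)))
    member <- c(rep(paste0("module", seq_len(nm)), moduleSizes),
        rep("noise", nNoise))
    p <- length(codes)
    S <- withr::with_seed(seed, {
        act <- matrix(stats::rbinom(nPatients * nm, 1L, activationProb),
            nPatients, nm)
        probs <- matrix(baselineProb, nPatients, p)
        probs[, seq_len(sum(moduleSizes))] <-
            ifelse(act[, rep(seq_len(nm), moduleSizes),
                drop = FALSE] == 1L, boostProb, baselineProb)
        matrix((stats::runif(nPatients * p) < probs) + 0L, nPatients, p)
    })
    dimnames(S) <- list(paste0("p", seq_len(nPatients)), codes)
    ComorbidityCohort(t(S),
        catalog = data.frame(code = codes, label = codes,
            category = member, include_flag = TRUE))
}

#' Sample an omics table with planted fold changes
#'
#' Log-normal intensities: \eqn{x = \exp(N(\mu_k + \delta, \sigma^2))}
#' where \eqn{\mu_k} is a per-feature baseline level and \eqn{\delta =
#' \ln(\mathrm{FC})} for planted features in the comparison group (0
#' otherwise). Paired mode adds a per-subject random effect (SD
#' \code{sigmaSubject}) shared between the two samples of each subject.
#'
#' @param nFeatures number of features (default emulates a ~1181-protein
#'   serum panel)
#' @param nPerGroup samples per group (default 10, the study's group
#'   size)
#' @param groupLabels the two group labels, reference first
#' @param planted indices (or names) of features carrying an effect
#' @param trueFC fold change(s) for planted features (recycled)
#' @param sigma log-scale noise SD (0.3 matches coefficients of variation
#'   around 30\%)
#' @param muRange range of per-feature baseline log-intensities
#' @param paired generate subject-paired samples
#' @param sigmaSubject log-scale SD of the shared subject effect
#' @param seed RNG seed
#' @return omics \code{SummarizedExperiment} with a
#'   \code{"planted_fc"} column in \code{rowData}
#' @export
sampleOmicsTable <- function(nFeatures = 1181L, nPerGroup = 10L,
                             groupLabels = c("A", "B"),
                             planted = integer(), trueFC = 2,
                             sigma = 0.3, muRange = c(log(1e4), log(1e7)),
                             paired = FALSE, sigmaSubject = 0,
                             seed = 1L) {
    stopifnot(all(trueFC > 0), sigma > 0, length(groupLabels) == 2L)
    nPerGroup <- rep_len(nPerGroup, 2L)
    if (paired && nPerGroup[1] != nPerGroup[2])
        stop("paired mode requires equal group sizes")
    n <- sum(nPerGroup)
    fid <- paste0("f", seq_len(nFeatures))
    if (is.character(planted)) planted <- match(planted, fid)
    delta <- numeric(nFeatures)
    delta[planted] <- log(rep_len(trueFC, length(planted)))
    group <- rep(groupLabels, nPerGroup)
    m <- withr::with_seed(seed, {
        mu <- stats::runif(nFeatures, muRange[1], muRange[2])
        lm <- matrix(stats::rnorm(nFeatures * n, mu, sigma),
            nFeatures, n)
        lm <- lm + outer(delta, as.numeric(group == groupLabels[2]))
        if (paired && sigmaSubject > 0) {
            stopifnot(nPerGroup[1] == nPerGroup[2])
            subj <- stats::rnorm(nPerGroup[1], 0, sigmaSubject)
            lm <- lm + matrix(rep(rep(subj, 2), each = nFeatures),
                nFeatures, n)
        }
        exp(lm)
    })
    rownames(m) <- fid
    colnames(m) <- paste0("s", seq_len(n))
    subject <- if (paired) paste0("subj", c(seq_len(nPerGroup[1]),
        seq_len(nPerGroup[2]))) else NULL
    se <- OmicsTable(m, group, subject)
    fcCol <- rep(1, nFeatures)
    fcCol[planted] <- exp(delta[planted])
    SummarizedExperiment::rowData(se)$planted_fc <- fcCol
    se
}
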