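# Independent brute-force oracles and small fixture builders.

# Build a CouplingMatrix directly from a symmetric J (and optional mask).
makeCouplingMatrix <- function(J, mask = NULL, codes = NULL) {
    J <- as.matrix(J)
    codes <- codes %||% (rownames(J) %||% LETTERS[seq_len(nrow(J))])
    if (is.null(mask)) mask <- matrix(FALSE, nrow(J), ncol(J))
    dimnames(J) <- dimnames(mask) <- list(codes, codes)
    methods::new("CouplingMatrix", codes = codes, J = J, mask = mask,
        logBase = "natural", formula = "pmi")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random signed coupling matrix with optional masked pairs.
randomCouplingMatrix <- function(p, seed, negProb = 0.25,
                                 maskProb = 0.1) {
    withr::with_seed(seed, {
        w <- matrix(0, p, p)
        ut <- upper.tri(w)
        vals <- runif(sum(ut), 0.2, 2) *
            ifelse(runif(sum(ut)) < negProb, -1, 1)
        w[ut] <- vals
        w <- w + t(w)
        m <- matrix(FALSE, p, p)
        m[ut] <- runif(sum(ut)) < maskProb
        m <- m | t(m)
        makeCouplingMatrix(w, m)
    })
}

# Exhaustive shortest-path centralities: enumerate every simple path
# between each unordered node pair on the positive-weight edge set with
# distance 1/w; shortest paths get fractional betweenness credit.
oracleCentralities <- function(cm) {
    J <- couplingStrengths(cm)
    J[couplingMask(cm)] <- 0
    codes <- nodeCodes(cm)
    p <- length(codes)
    strength <- rowSums(abs(J))
    ei <- rowSums(J)
    D <- ifelse(J > 0, 1 / J, Inf)
    diag(D) <- Inf
    allPaths <- function(s, t) {
        out <- list()
        walk <- function(node, visited, cost) {
            if (node == t) {
                out[[length(out) + 1L]] <<- list(path = visited,
                    cost = cost)
                return(invisible(NULL))
            }
            for (nb in seq_len(p)) {
                if (is.finite(D[node, nb]) && !(nb %in% visited))
                    walk(nb, c(visited, nb), cost + D[node, nb])
            }
        }
        walk(s, s, 0)
        out
    }
    btw <- numeric(p)
    dist <- matrix(Inf, p, p)
    diag(dist) <- 0
    for (s in seq_len(p - 1L)) for (t in (s + 1L):p) {
        paths <- allPaths(s, t)
        if (!length(paths)) next
        costs <- vapply(paths, `[[`, numeric(1), "cost")
        dmin <- min(costs)
        dist[s, t] <- dist[t, s] <- dmin
        sp <- paths[abs(costs - dmin) < 1e-9 * max(1, dmin)]
        for (pp in sp) {
            inner <- setdiff(pp$path, c(s, t))
            btw[inner] <- btw[inner] + 1 / length(sp)
        }
    }
    clo <- vapply(seq_len(p), function(i) {
        d <- dist[i, -i]
        d <- d[is.finite(d)]
        if (!length(d)) 0 else length(d) / sum(d)
    }, numeric(1))
    data.frame(code = codes, strength = strength,
        expectedInfluence = ei, betweenness = btw, closeness = clo)
}

# Brute-force Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, clipped to 1, mapped back to input
# order.
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        cand <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
        q[ord[i]] <- min(1, min(cand))
    }
    q
}

# Tiny deterministic cohort used across cohort/coupling tests:
# 4 patients, columns A = (1,1,0,0), B = (1,0,1,0).
toyCohort <- function() {
    ComorbidityCohort(rbind(A = c(1L, 1L, 0L, 0L),
        B = c(1L, 0L, 1L, 0L)))
}

# Cohort with prescribed marginal/joint counts for a 2-comorbidity pair.
countsCohort <- function(n, ni, nj, nij) {
    a <- c(rep(1L, ni), rep(0L, n - ni))
    b <- c(rep(1L, nij), rep(0L, ni - nij),
        rep(1L, nj - nij), rep(0L, n - ni - (nj - nij)))
    ComorbidityCohort(rbind(A = a, B = b))
}
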