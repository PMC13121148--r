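#' Build the weighted comorbidity network
#'
#' Undirected igraph over all catalog nodes, one edge per unmasked pair
#' with \eqn{|J| \ge} \code{minAbsJ} (default 0: complete weighted graph
#' over finite couplings). Edge attribute \code{weight} holds the signed
#' coupling strength.
#'
#' @param cm a \linkS4class{CouplingMatrix}
#' @param minAbsJ minimum absolute coupling for an edge
#' @return an \code{igraph} graph
#' @export
buildNetwork <- function(cm, minAbsJ = 0) {
    el <- edgeList(cm, minAbsJ)
    g <- igraph::graph_from_data_frame(
        el[, c("code_i", "code_j")], directed = FALSE,
        vertices = data.frame(name = cm@codes))
    igraph::E(g)$weight <- el$J
    g
}

#' Weighted centralities of the comorbidity network
#'
#' Per node: \emph{strength} (degree centrality) \eqn{\sum_j |w_{ij}|};
#' \emph{expected influence} \eqn{\sum_j w_{ij}} (one-step signed;
#' \code{twoStep = TRUE} adds each neighbour's own one-step expected
#' influence weighted by the connecting edge); \emph{betweenness} and
#' \emph{closeness} from exact all-pairs shortest paths on positive-weight
#' edges with distance \eqn{d_{ij} = 1/|w_{ij}|}, equal-cost paths earning
#' fractional (Brandes) credit. Closeness is the number of reachable other
#' nodes divided by the summed distance to them; isolated nodes score 0.
#'
#' Negative edges contribute to strength (absolute) and expected influence
#' (signed) but are excluded from path-based centralities.
#'
#' @param net igraph network from \code{\link{buildNetwork}}
#' @param twoStep also report two-step expected influence
#' @return \code{DataFrame} with columns \code{code}, \code{strength},
#'   \code{expectedInfluence}, \code{betweenness}, \code{closeness}
#' @examples
#' cmJ <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' dimnames(cmJ) <- list(c("A", "B", "C"), c("A", "B", "C"))
#' cm <- methods::new("CouplingMatrix", codes = c("A", "B", "C"), J = cmJ,
#'   mask = cmJ == 0, logBase = "natural", formula = "pmi")
#' centralities(buildNetwork(cm))  # betweenness: 0 1 0
#' @export
centralities <- function(net, twoStep = FALSE) {
    w <- igraph::E(net)$weight
    strength <- igraph::strength(net, weights = abs(w))
    ei <- igraph::strength(net, weights = w)
    gp <- igraph::subgraph_from_edges(net, igraph::E(net)[w > 0],
        delete.vertices = FALSE)
    dw <- 1 / abs(igraph::E(gp)$weight)
    btw <- igraph::betweenness(gp, weights = dw, directed = FALSE)
    D <- igraph::distances(gp, weights = dw)
    clo <- vapply(seq_len(nrow(D)), function(i) {
        d <- D[i, -i]
        d <- d[is.finite(d)]
        if (!length(d)) 0 else length(d) / sum(d)
    }, numeric(1))
    out <- S4Vectors::DataFrame(code = igraph::V(net)$name,
        strength = as.numeric(strength),
        expectedInfluence = as.numeric(ei),
        betweenness = as.numeric(btw), closeness = clo)
    if (twoStep) {
        A <- igraph::as_adjacency_matrix(net, attr = "weight",
            sparse = FALSE)
        out$expectedInfluence2 <- as.numeric(ei + A %*% ei)
    }
    rownames(out) <- out$code
    out
}

#' Detect disease modules by coupling-threshold components
#'
#' Keeps edges with signed weight strictly above \code{threshold} and
#' reports connected components of size >= 2 as disease modules; all other
#' nodes are singletons. Modules are ordered by decreasing size, nodes
#' within a module alphabetically, so cluster ids are stable.
#'
#' @param net igraph network
#' @param threshold signed coupling cutoff (default 0.5, strong
#'   association)
#' @return a \linkS4class{ModulePartition}
#' @export
detectModules <- function(net, threshold = 0.5) {
    stopifnot(is.finite(threshold))
    keep <- igraph::E(net)[igraph::E(net)$weight > threshold]
    g <- igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
    comp <- igraph::components(g)
    groups <- split(igraph::V(g)$name, comp$membership)
    sizes <- lengths(groups)
    clusters <- lapply(groups[sizes >= 2L], function(v) sort(v))
    clusters <- clusters[order(-lengths(clusters),
        vapply(clusters, `[`, character(1), 1L))]
    singles <- sort(unlist(groups[sizes < 2L], use.names = FALSE))
    methods::new("ModulePartition", threshold = threshold,
        clusters = unname(clusters),
        singletons = as.character(singles))
}

#' Accessors for ModulePartition
#' @param partition a \linkS4class{ModulePartition}
#' @return list of character vectors / character vector
#' @export
moduleClusters <- function(partition) partition@clusters

#' @rdname moduleClusters
#' @export
moduleSingletons <- function(partition) partition@singletons

#' Classify comorbidities into core / hub / peripheral tiers
#'
#' Tier rules use strict inequalities ("exceeding"): \code{"core"} if
#' strength > \code{coreStrength}; otherwise \code{"hub"} if betweenness >
#' \code{hubBetweenness} and the code is not excluded (e.g. composite
#' entities such as benign tumours); otherwise \code{"peripheral"}. The
#' \code{highEfficiency} flag marks closeness > \code{closenessCut}.
#'
#' @param ct centrality table from \code{\link{centralities}}
#' @param coreStrength strength cutoff (default 10)
#' @param hubBetweenness betweenness cutoff (default 60)
#' @param closenessCut closeness cutoff (default 0.0125)
#' @param exclude codes never labelled hub
#' @return the table with \code{tier} and \code{highEfficiency} columns
#' @export
classifyTiers <- function(ct, coreStrength = 10, hubBetweenness = 60,
                          closenessCut = 0.0125, exclude = character()) {
    stopifnot(is.finite(coreStrength), is.finite(hubBetweenness),
        is.finite(closenessCut))
    tier <- ifelse(ct$strength > coreStrength, "core",
        ifelse(ct$betweenness > hubBetweenness &
            !(ct$code %in% exclude), "hub", "peripheral"))
    ct$tier <- tier
    ct$highEfficiency <- ct$closeness > closenessCut
    ct
}

#' Export network, centralities and modules
#'
#' Writes \code{network.graphml} (nodes annotated with centralities, tier
#' and cluster id; edges with weight), \code{centralities.tsv},
#' \code{edges.tsv} and \code{modules.tsv} into \code{dir}.
#'
#' @param net igraph network
#' @param ct centrality table (ideally tier-annotated)
#' @param partition a \linkS4class{ModulePartition}
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
exportNetwork <- function(net, ct, partition, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    stopifnot(setequal(igraph::V(net)$name, ct$code))
    clusterId <- rep(NA_integer_, length(igraph::V(net)))
    names(clusterId) <- igraph::V(net)$name
    for (k in seq_along(partition@clusters))
        clusterId[partition@clusters[[k]]] <- k
    ord <- match(igraph::V(net)$name, ct$code)
    for (col in setdiff(names(ct), "code"))
        net <- igraph::set_vertex_attr(net, col, value = ct[[col]][ord])
    net <- igraph::set_vertex_attr(net, "cluster",
        value = ifelse(is.na(clusterId), 0L, clusterId))
    paths <- file.path(dir, c("network.graphml", "centralities.tsv",
        "edges.tsv", "modules.tsv"))
    igraph::write_graph(net, paths[1], format = "graphml")
    utils::write.table(as.data.frame(ct), paths[2], sep = "\t",
        quote = FALSE, row.names = FALSE)
    el <- igraph::as_data_frame(net, what = "edges")
    utils::write.table(el, paths[3], sep = "\t", quote = FALSE,
        row.names = FALSE)
    mods <- data.frame(code = names(clusterId),
        cluster = ifelse(is.na(clusterId), 0L, clusterId))
    utils::write.table(mods[order(mods$cluster, mods$code), ], paths[4],
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
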