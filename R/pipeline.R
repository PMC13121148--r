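#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: ingest filter
#' (\code{min_count}), coupling settings (\code{pseudocount},
#' \code{log_base}, \code{zero_policy}), module threshold (0.5), tier
#' cutoffs (strength 10, betweenness 60, closeness 0.0125), the stability
#' split (\code{split_on}, \code{cutpoint}, \code{top_k}) and the omics
#' gates (FC 1.20/0.86, alpha 0.05, VIP 1). Values can be overridden via
#' \code{...} or merged from a YAML file with
#' \code{\link{readPipelineConfig}}.
#'
#' @param ... named overrides
#' @return named list
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        min_count = 0L, exclude = character(),
        pseudocount = 0, log_base = "natural", zero_policy = "mask",
        min_abs_j = 0,
        module_threshold = 0.5,
        core_strength = 10, hub_betweenness = 60, closeness_cut = 0.0125,
        hub_exclude = character(),
        split_on = "discharge_year", cutpoint = 2014, top_k = 10L,
        fc_up = 1.20, fc_down = 0.86, alpha = 0.05, vip_min = 1,
        use_fdr = FALSE, n_ortho = 1L, n_perm = 200L, n_folds = 7L,
        seed = 1L)
    over <- list(...)
    cfg[names(over)] <- over
    cfg
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' \code{\link{pipelineConfig}}.
#' @param path YAML file
#' @return named list
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    bad <- setdiff(names(y), names(pipelineConfig()))
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(pipelineConfig, y)
}

.writeTsv <- function(x, path) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    path
}

#' Run the full comorbidity-network pipeline
#'
#' Ingest (or accept) a cohort, filter, estimate couplings, build the
#' weighted network, compute centralities and tiers, detect disease
#' modules, optionally validate stability across a covariate split, and
#' write a report bundle: \code{coupling.tsv}, \code{edges.tsv},
#' \code{network.graphml}, \code{centralities.tsv}, \code{modules.tsv},
#' \code{stability.tsv}, \code{config.yaml} and \code{summary.json}.
#'
#' @param cohort a \linkS4class{ComorbidityCohort}, or a records file path
#'   (then \code{catalogPath} is required)
#' @param outDir output directory
#' @param config list from \code{\link{pipelineConfig}}
#' @param catalogPath catalog CSV when \code{cohort} is a path
#' @param stability also split on \code{config$split_on} and compare the
#'   two subset networks
#' @return invisibly, the summary list (also written as JSON)
#' @export
comorbidityPipeline <- function(cohort, outDir,
                                config = pipelineConfig(),
                                catalogPath = NULL, stability = FALSE) {
    if (is.character(cohort)) {
        if (is.null(catalogPath))
            stop("catalogPath required when reading records from file")
        cohort <- readCohortRecords(cohort, catalogPath)
    }
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    cohort <- filterComorbidities(cohort, config$min_count,
        config$exclude)
    est <- estimateProbabilities(cohort, config$pseudocount)
    cm <- couplingMatrix(est, logBase = config$log_base,
        zeroPolicy = config$zero_policy)
    net <- buildNetwork(cm, config$min_abs_j)
    ct <- classifyTiers(centralities(net),
        coreStrength = config$core_strength,
        hubBetweenness = config$hub_betweenness,
        closenessCut = config$closeness_cut,
        exclude = config$hub_exclude)
    part <- detectModules(net, config$module_threshold)
    Jout <- couplingStrengths(cm)
    .writeTsv(data.frame(code = rownames(Jout), Jout,
        check.names = FALSE), file.path(outDir, "coupling.tsv"))
    exportNetwork(net, ct, part, outDir)
    stab <- NULL
    if (stability) {
        halves <- splitCohort(cohort, config$split_on, config$cutpoint)
        cmp <- compareNetworks(
            couplingMatrix(estimateProbabilities(halves$A,
                config$pseudocount), logBase = config$log_base,
                zeroPolicy = config$zero_policy),
            couplingMatrix(estimateProbabilities(halves$B,
                config$pseudocount), logBase = config$log_base,
                zeroPolicy = config$zero_policy),
            topK = config$top_k)
        stab <- data.frame(metric = c("edge_r", "edge_ci_lower",
            "edge_ci_upper", "strength_r", "strength_ci_lower",
            "strength_ci_upper", "n_edges", "n_nodes",
            "rank_consistency", "kendall_tau"),
            value = c(cmp$edge_r, cmp$edge_ci, cmp$strength_r,
                cmp$strength_ci, cmp$n_edges, cmp$n_nodes,
                cmp$rank_consistency, cmp$kendall_tau))
        .writeTsv(stab, file.path(outDir, "stability.tsv"))
    }
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))
    summary <- list(
        n_patients = ncol(cohort), n_comorbidities = nrow(cohort),
        n_edges = length(igraph::E(net)),
        n_clusters = length(moduleClusters(part)),
        n_singletons = length(moduleSingletons(part)),
        core = ct$code[ct$tier == "core"],
        hub = ct$code[ct$tier == "hub"],
        stability = if (!is.null(stab))
            stats::setNames(as.list(stab$value), stab$metric))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    invisible(summary)
}

#' Run the omics differential-screening pipeline
#'
#' For each requested contrast: fold change, (paired) test, BH q, OPLS-DA
#' VIP, verdicts, plus a model validation report (cross-validated Q2 and
#' label-permutation p). Writes one \code{differential_<name>.tsv} per
#' contrast, \code{validation.tsv}, \code{config.yaml} and
#' \code{summary.json}.
#'
#' @param se omics \code{SummarizedExperiment}, or intensity-table path
#'   (then \code{designPath} is required)
#' @param contrasts list of contrasts, each a list with \code{name},
#'   \code{reference}, \code{comparison} and optional \code{paired}
#' @param outDir output directory
#' @param config list from \code{\link{pipelineConfig}}
#' @param designPath sample sheet path when \code{se} is a file path
#' @return invisibly, the summary list
#' @export
omicsPipeline <- function(se, contrasts, outDir,
                          config = pipelineConfig(),
                          designPath = NULL) {
    if (is.character(se)) {
        if (is.null(designPath))
            stop("designPath required when reading a table from file")
        se <- readOmicsTable(se, designPath)
    }
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    summaries <- list()
    valRows <- list()
    for (ctr in contrasts) {
        paired <- isTRUE(ctr$paired)
        if (paired &&
            is.null(SummarizedExperiment::colData(se)$subject))
            stop("contrast '", ctr$name,
                "' is paired but the table has no subject column")
        dr <- differentialScreen(se, ctr$reference, ctr$comparison,
            paired = paired, withVip = TRUE, nOrtho = config$n_ortho,
            fcUp = config$fc_up, fcDown = config$fc_down,
            alpha = config$alpha, vipMin = config$vip_min,
            useFdr = config$use_fdr)
        .writeTsv(dr, file.path(outDir,
            paste0("differential_", ctr$name, ".tsv")))
        cv <- crossValidate(se, c(ctr$reference, ctr$comparison),
            nOrtho = config$n_ortho, nFolds = config$n_folds,
            seed = config$seed)
        pt <- permutationTest(se, c(ctr$reference, ctr$comparison),
            nOrtho = config$n_ortho, nPerm = config$n_perm,
            nFolds = config$n_folds, seed = config$seed)
        valRows[[ctr$name]] <- data.frame(contrast = ctr$name,
            q2 = cv$q2, r2y = cv$r2y, permutation_p = pt$p,
            n_permutations = config$n_perm, n_folds = cv$n_folds,
            seed = config$seed)
        summaries[[ctr$name]] <- as.list(attr(dr, "summary"))
    }
    .writeTsv(do.call(rbind, valRows), file.path(outDir,
        "validation.tsv"))
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))
    out <- list(contrasts = summaries,
        validation = lapply(valRows, function(v)
            list(q2 = v$q2, permutation_p = v$permutation_p)))
    jsonlite::write_json(out, file.path(outDir, "summary.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(out)
}

#' Published worked-example group means
#'
#' Ships the printed group-mean summary tables (serum proteins, relative
#' intensity; lipid-mediator metabolites, ng/ml) from a published
#' psoriasis IL-17A-inhibitor study, with the printed fold changes,
#' p-values and (for proteins) VIPs, as plain TSVs under
#' \code{inst/extdata}. Each row carries a \code{fc_consistent} flag:
#' FALSE marks rows whose printed FC disagrees with the ratio of printed
#' means at 3 decimal places (rounding artifacts in the source table).
#'
#' @param which \code{"protein"} or \code{"metabolite"}
#' @return data.frame with columns \code{feature}, \code{contrast},
#'   \code{ref_group}, \code{cmp_group}, \code{ref_mean}, \code{cmp_mean},
#'   \code{fc_printed}, \code{p_printed}, \code{vip_printed},
#'   \code{fc_consistent}
#' @export
workedExampleMeans <- function(which = c("protein", "metabolite")) {
    which <- match.arg(which)
    path <- system.file("extdata",
        paste0(which, "_group_means.tsv"), package = "comorbnet",
        mustWork = TRUE)
    utils::read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE)
}

#' Build a two-sample-per-group toy table from printed group means
#'
#' Both samples of each group sit exactly at the printed mean, so group
#' means — and therefore \code{\link{foldChange}} ratios — reproduce the
#' printed values. Used by the worked examples.
#'
#' @param means data.frame as from \code{\link{workedExampleMeans}},
#'   restricted to one contrast
#' @return omics \code{SummarizedExperiment} with groups \code{"ref"} and
#'   \code{"cmp"}
#' @export
meansToToyTable <- function(means) {
    stopifnot(length(unique(means$contrast)) == 1L)
    m <- cbind(means$ref_mean, means$ref_mean, means$cmp_mean,
        means$cmp_mean)
    rownames(m) <- means$feature
    OmicsTable(m, c("ref", "ref", "cmp", "cmp"))
}
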