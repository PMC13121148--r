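#' Construct a ComorbidityCohort
#'
#' @param indicators 0/1 matrix, comorbidities as rows, patients as columns
#'   (a p x n comorbidity-patient matrix). Dimnames supply codes and
#'   patient ids unless given explicitly.
#' @param catalog optional comorbidity catalog data frame with columns
#'   \code{code}, \code{label}, \code{category}, \code{include_flag};
#'   every row code must appear in it.
#' @param covariates optional per-patient data frame (e.g.
#'   \code{discharge_year}, \code{sex}, \code{age}), one row per patient.
#' @return a \linkS4class{ComorbidityCohort}
#' @examples
#' m <- rbind(S23 = c(1, 1, 0), S16 = c(1, 0, 1))
#' colnames(m) <- paste0("p", 1:3)
#' ComorbidityCohort(m)
#' @export
ComorbidityCohort <- function(indicators, catalog = NULL, covariates = NULL) {
    indicators <- as.matrix(indicators)
    if (is.null(rownames(indicators)))
        stop("indicator matrix needs comorbidity codes as rownames")
    if (is.null(colnames(indicators)))
        colnames(indicators) <- paste0("p", seq_len(ncol(indicators)))
    storage.mode(indicators) <- "integer"
    if (is.null(catalog)) {
        catalog <- data.frame(code = rownames(indicators),
            label = rownames(indicators), category = NA_character_,
            include_flag = TRUE)
    }
    catalog <- .checkCatalog(catalog)
    missing <- setdiff(rownames(indicators), catalog$code)
    if (length(missing))
        stop("comorbidity code(s) not in catalog: ",
            paste(missing, collapse = ", "))
    rd <- catalog[match(rownames(indicators), catalog$code), , drop = FALSE]
    rownames(rd) <- rd$code
    if (is.null(covariates))
        covariates <- data.frame(row.names = colnames(indicators))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(indicators = indicators),
        rowData = S4Vectors::DataFrame(rd),
        colData = S4Vectors::DataFrame(covariates,
            row.names = colnames(indicators)))
    methods::new("ComorbidityCohort", se)
}

.checkCatalog <- function(catalog) {
    catalog <- as.data.frame(catalog)
    need <- c("code", "label", "category", "include_flag")
    for (col in setdiff(need, names(catalog)))
        catalog[[col]] <- if (col == "include_flag") TRUE else NA_character_
    if (anyDuplicated(catalog$code))
        stop("catalog codes must be unique")
    catalog[, need]
}

#' Read a comorbidity catalog CSV/TSV
#'
#' Expects columns \code{code,label,category,include_flag}; separator is
#' sniffed from the header line.
#' @param path file path
#' @return data.frame catalog
#' @export
readCatalog <- function(path) {
    .checkCatalog(.readDelim(path))
}

.readDelim <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    hdr <- readLines(path, n = 1L)
    if (!length(hdr) || !nzchar(hdr)) stop("empty file: ", path)
    sep <- if (grepl("\t", hdr)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
        stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read cohort records (long or wide) into a ComorbidityCohort
#'
#' Long format has one row per patient-diagnosis pair with columns
#' \code{patient_id}, \code{comorbidity_code} and optional covariates
#' (covariates must be constant within a patient). Wide format has one row
#' per patient, a \code{patient_id} column and one 0/1 column per catalog
#' code. The layout is auto-detected from the header.
#'
#' A patient-code pair appearing one or more times yields indicator 1;
#' unknown codes are an error naming the code.
#'
#' @param path CSV/TSV path
#' @param catalog comorbidity catalog (data frame or path)
#' @return a \linkS4class{ComorbidityCohort}
#' @export
readCohortRecords <- function(path, catalog) {
    if (is.character(catalog)) catalog <- readCatalog(catalog)
    catalog <- .checkCatalog(catalog)
    df <- .readDelim(path)
    if (!nrow(df)) stop("no records in ", path)
    long <- all(c("patient_id", "comorbidity_code") %in% names(df))
    if (long) .pivotLong(df, catalog) else .readWide(df, catalog)
}

.pivotLong <- function(df, catalog) {
    unknown <- setdiff(unique(df$comorbidity_code), catalog$code)
    if (length(unknown))
        stop("unknown comorbidity code(s) not in catalog: ",
            paste(unknown, collapse = ", "))
    pid <- unique(as.character(df$patient_id))
    codes <- catalog$code
    m <- matrix(0L, nrow = length(codes), ncol = length(pid),
        dimnames = list(codes, pid))
    m[cbind(match(df$comorbidity_code, codes),
            match(as.character(df$patient_id), pid))] <- 1L
    covCols <- setdiff(names(df), c("patient_id", "comorbidity_code"))
    covariates <- NULL
    if (length(covCols)) {
        first <- df[!duplicated(df$patient_id), , drop = FALSE]
        covariates <- first[match(pid, as.character(first$patient_id)),
            covCols, drop = FALSE]
        rownames(covariates) <- pid
    }
    ComorbidityCohort(m, catalog, covariates)
}

.readWide <- function(df, catalog) {
    idCol <- intersect(c("patient_id", names(df)[1]), names(df))[1]
    codes <- intersect(names(df), catalog$code)
    if (length(codes) < 2L)
        stop("wide table shares fewer than 2 columns with the catalog")
    unknown <- setdiff(names(df), c(idCol, catalog$code))
    m <- t(as.matrix(df[, codes, drop = FALSE]))
    colnames(m) <- as.character(df[[idCol]])
    covariates <- if (length(unknown))
        data.frame(df[, unknown, drop = FALSE],
            row.names = colnames(m)) else NULL
    ComorbidityCohort(m, catalog, covariates)
}

#' Write a cohort as long-format records
#'
#' One row per (patient, comorbidity) presence; covariates carried along.
#' Round-trips through \code{\link{readCohortRecords}}.
#' @param cohort a \linkS4class{ComorbidityCohort}
#' @param path output path (TSV)
#' @export
writeCohortRecords <- function(cohort, path) {
    x <- indicators(cohort)
    idx <- which(x == 1L, arr.ind = TRUE)
    out <- data.frame(patient_id = colnames(x)[idx[, "col"]],
        comorbidity_code = rownames(x)[idx[, "row"]])
    cov <- as.data.frame(SummarizedExperiment::colData(cohort))
    if (ncol(cov))
        out <- cbind(out, cov[match(out$patient_id, colnames(x)), ,
            drop = FALSE])
    out <- out[order(out$patient_id, out$comorbidity_code), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Accessors for ComorbidityCohort
#'
#' \code{indicators} returns the 0/1 comorbidity-by-patient matrix;
#' \code{catalog} the comorbidity catalog; \code{patientData} the
#' per-patient covariates.
#' @param cohort a \linkS4class{ComorbidityCohort}
#' @return matrix / data.frame
#' @export
indicators <- function(cohort) {
    SummarizedExperiment::assay(cohort, "indicators")
}

#' @rdname indicators
#' @export
catalog <- function(cohort) {
    as.data.frame(SummarizedExperiment::rowData(cohort))
}

#' @rdname indicators
#' @export
patientData <- function(cohort) {
    as.data.frame(SummarizedExperiment::colData(cohort))
}

#' Filter comorbidity columns
#'
#' Drops comorbidities observed fewer than \code{minCount} times, those in
#' \code{exclude}, and degenerate ones with prevalence 0 or 1 (coupling
#' estimation requires 0 < P < 1). Dropped codes are reported via
#' \code{message}.
#'
#' @param cohort a \linkS4class{ComorbidityCohort}
#' @param minCount minimum number of patients carrying the comorbidity
#' @param exclude codes to drop regardless of count
#' @return filtered \linkS4class{ComorbidityCohort}
#' @export
filterComorbidities <- function(cohort, minCount = 0L,
                                exclude = character()) {
    stopifnot(minCount >= 0)
    x <- indicators(cohort)
    n <- ncol(x)
    cs <- rowSums(x)
    drop <- cs < minCount | cs == 0L | cs == n | rownames(x) %in% exclude
    if (any(drop))
        message("dropping ", sum(drop), " comorbidity column(s): ",
            paste(rownames(x)[drop], collapse = ", "))
    if (all(drop))
        stop("all comorbidity columns dropped by filtering")
    cohort[!drop, ]
}

#' Validate a cohort matrix
#'
#' Report-only check of the cohort invariants: binary entries, unique
#' patient ids and codes, non-degenerate columns.
#'
#' @param cohort a \linkS4class{ComorbidityCohort} (validity is not
#'   enforced here; pass a raw object to inspect problems)
#' @return list with \code{valid} flag and data.frames of findings:
#'   \code{non_binary} (row, col, value), \code{duplicate_patients},
#'   \code{duplicate_codes}, \code{degenerate_codes}
#' @export
validateCohort <- function(cohort) {
    x <- SummarizedExperiment::assay(cohort, "indicators")
    bad <- which(!(x %in% c(0L, 1L)))
    nb <- if (length(bad)) {
        ai <- arrayInd(bad, dim(x))
        data.frame(code = rownames(x)[ai[, 1]],
            patient = colnames(x)[ai[, 2]], value = x[bad])
    } else data.frame(code = character(), patient = character(),
        value = numeric())
    dp <- unique(colnames(x)[duplicated(colnames(x))])
    dc <- unique(rownames(x)[duplicated(rownames(x))])
    cs <- rowSums(x == 1L)
    degen <- rownames(x)[cs == 0L | cs == ncol(x)]
    list(valid = !nrow(nb) && !length(dp) && !length(dc) && !length(degen),
        non_binary = nb, duplicate_patients = dp, duplicate_codes = dc,
        degenerate_codes = degen)
}
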