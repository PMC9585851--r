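risize_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "risize_error")))
}

#' Read one analyte column from a delimited table
#'
#' Loads a CSV or TSV file with a header row and extracts one named
#' numeric column as a reference population. Non-numeric and missing
#' cells are dropped with a warning giving the count; values are kept
#' in file order.
#'
#' @param path path to the file. The delimiter is taken from the
#'   extension (`.tsv`/`.txt` tab, otherwise comma) unless `sep` is
#'   given.
#' @param column name of the column holding the analyte values.
#' @param sep optional field separator override.
#' @param unit unit label attached to the population.
#' @return an `analyte_population`.
#' @export
read_analyte_table <- function(path, column, sep = NULL, unit = "") {
  if (!file.exists(path))
    risize_error(paste0("file not found: ", path), "risize_unreadable")
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
           else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      risize_error(paste0("cannot parse ", path, ": ",
                          conditionMessage(e)), "risize_unreadable")
  )
  if (!column %in% names(df))
    risize_error(paste0("column '", column, "' not found; available: ",
                        paste(names(df), collapse = ", ")),
                 "risize_missing_column")
  raw <- df[[column]]
  vals <- suppressWarnings(as.numeric(as.character(raw)))
  n_bad <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    risize_error(paste0("column '", column, "' has no numeric values"),
                 "risize_empty_column")
  if (n_bad > 0L)
    warning(sprintf("dropped %d non-numeric/missing cell(s) from '%s'",
                    n_bad, column), call. = FALSE)
  ri_population(vals, analyte = column, unit = unit)
}

#' Write a population to the delimited layout the readers accept
#'
#' One header line (the analyte name) and one value per row; the
#' round-trip through [read_analyte_table()] reproduces the values
#' exactly.
#'
#' @param pop an `analyte_population`.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  pop <- as_ri_population(pop)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t"
         else ","
  df <- stats::setNames(data.frame(format(pop$values, digits = 17,
                                          trim = TRUE,
                                          scientific = FALSE)),
                        pop$analyte)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read one gene's expression values from a GCT matrix
#'
#' Parses a GCT v1.2/v1.3 file (version line, dimension line, then a
#' table with `Name` and `Description` columns followed by one column
#' per sample) and returns the named gene's values across all samples
#' as a reference population. Gene identifiers are matched
#' case-sensitively; a miss reports near matches.
#'
#' @param path path to the GCT file.
#' @param gene_id gene identifier looked up in the `Name` column.
#' @return an `analyte_population` labelled with the gene id.
#' @export
read_gct <- function(path, gene_id) {
  if (!file.exists(path))
    risize_error(paste0("file not found: ", path), "risize_unreadable")
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^#1\\.[23]", lines[1]))
    risize_error("not a GCT v1.2/v1.3 file (missing #1.2/#1.3 version line)",
                 "risize_gct_format")
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    risize_error("malformed GCT dimension line", "risize_gct_format")
  n_genes <- dims[1]
  n_samples <- dims[2]
  body <- utils::read.delim(path, skip = 2L, header = TRUE,
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("Name", "Description") %in% names(body)[1:2]))
    risize_error("GCT body must start with Name and Description columns",
                 "risize_gct_format")
  if (nrow(body) != n_genes || ncol(body) - 2L != n_samples)
    risize_error(sprintf(
      "GCT dimension line (%d genes x %d samples) inconsistent with body (%d x %d)",
      n_genes, n_samples, nrow(body), ncol(body) - 2L),
      "risize_gct_format")
  hit <- which(body$Name == gene_id)
  if (length(hit) == 0L) {
    near <- body$Name[tolower(body$Name) == tolower(gene_id)]
    if (length(near) == 0L)
      near <- utils::head(
        body$Name[agrepl(gene_id, body$Name, ignore.case = TRUE)], 5L)
    risize_error(paste0("gene '", gene_id, "' not found",
                        if (length(near))
                          paste0("; near matches: ",
                                 paste(near, collapse = ", "))
                        else ""),
                 "risize_gene_missing")
  }
  vals <- as.numeric(body[hit[1L], -(1:2)])
  if (anyNA(vals))
    risize_error(paste0("non-numeric expression values for gene '",
                        gene_id, "'"), "risize_gct_format")
  ri_population(vals, analyte = gene_id, unit = "TPM")
}

#' Serialize a sample-size fit as a report
#'
#' Writes a machine-readable report of an [ri_samplesize()] fit.
#' JSON holds the full nested document (schema-versioned: estimate,
#' validation ratios, complete trace, control echo, provenance) at full
#' precision; TSV is the compact result table with one row per method
#' and columns `Analyte`, `Method`, `SampleSize`, `LLW_CI/W_RI`,
#' `ULW_CI/W_RI` (3 decimals). A non-converged search renders as `null`
#' in JSON and `NC` in TSV.
#'
#' @param fit an `ri_samplesize` object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @param provenance optional named list recording the input source
#'   (file, column/gene, filter counts); stored verbatim in JSON.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(fit, path, format = c("json", "tsv"),
                         provenance = NULL) {
  stopifnot(inherits(fit, "ri_samplesize"))
  format <- match.arg(format)
  method_label <- function(m)
    if (m == "parametric") "Transformed parametric" else "Non-parametric"
  if (format == "tsv") {
    rows <- do.call(rbind, lapply(fit$fits, function(f) {
      data.frame(
        Analyte = fit$population$analyte,
        Method = method_label(f$method),
        SampleSize = if (f$converged) as.character(f$estimated_n)
                     else "NC",
        `LLW_CI/W_RI` = sprintf("%.3f", f$validation["R1"]),
        `ULW_CI/W_RI` = sprintf("%.3f", f$validation["R2"]),
        check.names = FALSE, row.names = NULL
      )
    }))
    utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  doc <- list(
    schema = "risize-report/1",
    package_version = as.character(utils::packageVersion("risize")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    analyte = fit$population$analyte,
    unit = fit$population$unit,
    n_population = fit$population$n,
    n_outliers_removed = if (is.null(fit$outliers)) 0L
                         else length(fit$outliers$removed),
    provenance = provenance,
    control = unclass(fit$control),
    results = lapply(fit$fits, function(f) {
      list(method = f$method,
           estimated_n = if (f$converged) f$estimated_n else NULL,
           converged = f$converged,
           validation = list(llw_ci_w_ri = unname(f$validation["R1"]),
                             ulw_ci_w_ri = unname(f$validation["R2"])),
           trace = f$trace,
           moving_sums = f$moving_sums,
           moving_medians = f$moving_medians)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Reload a JSON report
#'
#' @param path path written by [write_report()] with `format = "json"`.
#' @return the report as a nested list (estimates, validation ratios
#'   and traces are recovered losslessly).
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "risize-report/1"))
    risize_error("not a risize report (unknown schema)",
                 "risize_report_format")
  doc
}
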