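# Expression-table preprocessing: FPKM-UQ-style tables keyed by Ensembl
# gene IDs, the median-zero gene filter, the log10(1+a) transform, and
# patient-wise train/validation/test splitting.

#' Construct an expression table
#'
#' @param values numeric genes x cases matrix, non-negative on the raw
#'   scale.
#' @param gene_ids unique gene identifiers (Ensembl IDs; a trailing
#'   version suffix like `.12` is tolerated and can be stripped).
#' @param case_ids case identifiers, one per column.
#' @param log_space whether `values` are already log10(1+a) transformed.
#' @param strip_versions drop `.N` version suffixes from `gene_ids`.
#' @return object of class `expression_table`.
#' @export
expression_table <- function(values, gene_ids, case_ids, log_space = FALSE,
                             strip_versions = FALSE) {
  values <- as.matrix(values)
  if (strip_versions) gene_ids <- sub("\\.\\d+$", "", gene_ids)
  if (anyDuplicated(gene_ids))
    stop_mf("gene_ids must be unique (%d duplicates)",
            sum(duplicated(gene_ids)), class = "mf_argument_error")
  stopifnot(nrow(values) == length(gene_ids),
            ncol(values) == length(case_ids))
  if (!log_space && any(values < 0))
    stop_mf("raw expression values must be non-negative",
            class = "mf_domain_error")
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 case_ids = as.character(case_ids),
                 log_space = isTRUE(log_space)),
            class = "expression_table")
}

#' Read / write an expression table as TSV (genes x cases)
#'
#' The first column holds gene IDs; remaining columns are cases.
#'
#' @param path TSV file.
#' @param log_space,strip_versions passed to [expression_table()].
#' @export
read_expression_table <- function(path, log_space = FALSE,
                                  strip_versions = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  expression_table(as.matrix(df[, -1, drop = FALSE]), df[[1]],
                   colnames(df)[-1], log_space = log_space,
                   strip_versions = strip_versions)
}

#' @rdname read_expression_table
#' @param table an `expression_table`.
#' @export
write_expression_table <- function(table, path) {
  df <- data.frame(gene_id = table$gene_ids, table$values,
                   check.names = FALSE)
  colnames(df) <- c("gene_id", table$case_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes whose across-case median is zero
#'
#' Applied on the raw FPKM-UQ scale (filtering a log-space table is
#' refused): keeps genes with median > 0 across all cases, preserving
#' order. On the full TCGA kidney cohort this retains 31,793 of 60,483
#' genes.
#'
#' @param table a raw-scale `expression_table`.
#' @return filtered `expression_table`.
#' @export
filter_median_zero <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  if (table$log_space)
    stop_mf("median-zero filtering is defined on the raw scale only",
            class = "mf_domain_error")
  med <- apply(table$values, 1L, stats::median)
  keep <- med > 0
  if (!any(keep))
    stop_mf("median-zero filter removed every gene",
            class = "mf_empty_result_error")
  expression_table(table$values[keep, , drop = FALSE],
                   table$gene_ids[keep], table$case_ids,
                   log_space = FALSE)
}

#' Log-transform expression values
#'
#' Elementwise `a -> log10(1 + a)`, compressing the dynamic range so that
#' highly expressed genes do not dominate squared-error losses.
#'
#' @param table a raw-scale `expression_table`.
#' @return log-space `expression_table`.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  if (table$log_space)
    stop_mf("table is already in log space", class = "mf_domain_error")
  if (any(table$values < 0))
    stop_mf("log transform needs non-negative values",
            class = "mf_domain_error")
  expression_table(log10(1 + table$values), table$gene_ids, table$case_ids,
                   log_space = TRUE)
}

#' Invert the log transform
#' @param table a log-space `expression_table`.
#' @return raw-scale `expression_table` (`10^v - 1`).
#' @export
inverse_log_transform <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  if (!table$log_space)
    stop_mf("table is not in log space", class = "mf_domain_error")
  expression_table(pmax(10^table$values - 1, 0), table$gene_ids,
                   table$case_ids, log_space = FALSE)
}

#' Split cases into train/validation/test at patient granularity
#'
#' Patients (not cases) are shuffled and partitioned so that every case of
#' a patient lands in the same split; split sizes follow `ratios` up to
#' rounding on the patient count.
#'
#' @param case_ids case identifiers.
#' @param patient_of_case patient identifier per case.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return list with case-id vectors `train`, `val`, `test` and the
#'   corresponding `patients` list.
#' @export
split_cases <- function(case_ids, patient_of_case,
                        ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(case_ids) == length(patient_of_case))
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_mf("ratios must sum to 1, got %s", format(sum(ratios)),
            class = "mf_argument_error")
  patients <- unique(as.character(patient_of_case))
  n_splits <- sum(ratios > 0)
  if (length(patients) < n_splits)
    stop_mf("%d patients cannot fill %d splits", length(patients), n_splits,
            class = "mf_argument_error")
  perm <- with_seed(seed, sample(patients))
  bounds <- round(cumsum(ratios) * length(patients))
  bounds[length(bounds)] <- length(patients)
  counts <- diff(c(0L, bounds))
  groups <- rep(c("train", "val", "test"), counts)
  assign <- split(perm, factor(groups, levels = c("train", "val", "test")))
  pick <- function(ps) case_ids[as.character(patient_of_case) %in% ps]
  list(train = pick(assign$train), val = pick(assign$val),
       test = pick(assign$test), patients = assign)
}
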