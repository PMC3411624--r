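# Fixed text dialect: tab-delimited UTF-8, '.' decimal, no thousands
# separators, floats at 10 significant digits.
.fmt_num <- function(x) formatC(x, format = "g", digits = 10)

#' Read a probe-level matrix from tab-delimited text
#'
#' Expected layout: a header row `probeset_id`, `probe_id`, then one column
#' per array; one row per probe.  Duplicate probe identifiers and
#' non-numeric cells are rejected with errors that name the offending probe
#' or cell.
#'
#' @param path Path to a tab-delimited text file.
#' @return A [probe_data] object.
#' @export
read_probe_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty probe matrix file: ", path)
  if (ncol(df) < 4L || !identical(names(df)[1:2], c("probeset_id", "probe_id")))
    stop("malformed header: expected columns probeset_id, probe_id, ",
         "then at least two array columns")
  probe_ids <- df$probe_id
  if (anyDuplicated(probe_ids))
    stop("duplicated probe_id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  arr_names <- names(df)[-(1:2)]
  chr <- as.matrix(df[, -(1:2), drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(chr), dim(chr)))
  bad <- which(is.na(vals) & !(chr %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row %d (probe %s), column %s",
                 chr[bad[1, 1], bad[1, 2]], bad[1, 1], probe_ids[bad[1, 1]],
                 arr_names[bad[1, 2]]))
  dimnames(vals) <- list(probe_ids, arr_names)
  probe_data(vals, probeset = df$probeset_id, array_ids = arr_names)
}

#' Write a probe-level matrix as tab-delimited text
#'
#' @param data A [probe_data] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probe_matrix <- function(data, path) {
  stopifnot(inherits(data, "probe_data"))
  out <- data.frame(probeset_id = data$probeset,
                    probe_id = rownames(data$intensities),
                    .fmt_num(data$intensities),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- data$array_ids
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene x array summary matrix
#'
#' The file starts with a `# method: <tag>` comment line, then a header row
#' `gene_id` plus one column per array.
#'
#' @param x An [expression_matrix] (its post-reset summaries are written) or
#'   a plain gene x array matrix.
#' @param path Output path.
#' @param method_tag Tag for the comment line; defaults to the object's tag.
#' @param raw For an [expression_matrix], write the raw (pre-reset) values
#'   instead of the post-reset summaries.
#' @return Invisibly, `path`.
#' @export
write_summary_matrix <- function(x, path, method_tag = NULL, raw = FALSE) {
  if (inherits(x, "expression_matrix")) {
    if (is.null(method_tag)) method_tag <- x$method_tag
    m <- if (raw) x$raw_summaries else x$summaries
  } else {
    m <- as.matrix(x)
    if (is.null(method_tag)) method_tag <- "external"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", method_tag), con)
  out <- data.frame(gene_id = rownames(m), .fmt_num(m),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- colnames(m)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x array summary matrix
#'
#' @param path Path to a file written by [write_summary_matrix()] (the
#'   `# method:` comment line is optional).
#' @return List with `summaries` (numeric matrix, genes x arrays) and
#'   `method_tag`.
#' @export
read_summary_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  tag <- "external"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    tag <- sub("^#\\s*method:\\s*", "", first)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, quote = "")
  if (!identical(names(df)[1], "gene_id"))
    stop("malformed header: expected first column gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in summary matrix ", path)
  rownames(m) <- df$gene_id
  list(summaries = m, method_tag = tag)
}

#' Write a JED table as tab-delimited text
#'
#' Rows keep the deterministic [compute_jed()] order: gene-major, with the
#' i < j pairs of each gene before its diagonal entries; diagonal rows are
#' omitted when `suppress_diagonal = TRUE`.
#'
#' @param table A `jed_table` from [compute_jed()].
#' @param path Output path.
#' @param suppress_diagonal Omit the (always-1) diagonal rows.
#' @return Invisibly, `path`.
#' @export
write_jed_table <- function(table, path, suppress_diagonal = FALSE) {
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) == 0L) stop("empty JED table")
  if (suppress_diagonal)
    table <- table[table$array_i != table$array_j, , drop = FALSE]
  out <- data.frame(gene = table$gene,
                    array_i = table$array_i, array_j = table$array_j,
                    jed = .fmt_num(table$jed),
                    sign_changes = table$sign_changes,
                    distance = .fmt_num(table$distance),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JED table written by [write_jed_table()]
#'
#' @param path Path to the file.
#' @return A data frame of class `jed_table`.
#' @export
read_jed_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          colClasses = c(gene = "character",
                                         array_i = "character",
                                         array_j = "character"))
  needed <- c("gene", "array_i", "array_j", "jed", "sign_changes", "distance")
  if (!all(needed %in% names(df)))
    stop("malformed JED table: missing column(s) ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  structure(df, class = c("jed_table", "data.frame"))
}

#' Assemble a jackknife set from external summary files
#'
#' Reads a full-data summary matrix and its A leave-one-out counterparts
#' (same TSV dialect) so JED can be computed for summaries produced by any
#' outside preprocessing tool.  Each leave-one-out file must omit exactly
#' one of the full run's array columns, which identifies the excluded array.
#'
#' @param full_path Path of the full-data raw summary matrix.
#' @param loo_paths Character vector of A leave-one-out file paths.
#' @return A [jackknife_set].
#' @export
read_external_jackknife <- function(full_path, loo_paths) {
  full <- read_summary_matrix(full_path)
  loo <- lapply(loo_paths, function(p) read_summary_matrix(p)$summaries)
  gen_jackknife_fixture(full$summaries, loo, method_tag = full$method_tag)
}
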