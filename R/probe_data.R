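#' Probe-level intensity matrix
#'
#' Container for log2-scale perfect-match (PM) probe intensities, the raw
#' material of preprocessing.  Rows are probes, columns are arrays, and every
#' probe belongs to exactly one probeset (gene).
#'
#' @param intensities Numeric matrix, probes x arrays, of finite log2-scale
#'   PM intensities.  Row names, if present, are used as probe identifiers;
#'   otherwise identifiers `p1, p2, ...` are generated.
#' @param probeset Character vector, one gene identifier per probe (row).
#' @param array_ids Character vector of unique array labels; defaults to the
#'   column names of `intensities`, or `A1, A2, ...` when absent.
#' @param log2_transform If `TRUE`, the input is taken to be on the raw
#'   intensity scale and is converted to `log2(x + 1)`.  By default inputs
#'   are assumed to be log2 already.
#'
#' @return An object of class `probe_data`: a list with elements
#'   `intensities` (probes x arrays matrix), `probeset` (gene per probe) and
#'   `array_ids`.
#' @examples
#' x <- matrix(c(1, 3, 2, 4), nrow = 2)
#' pd <- probe_data(x, probeset = c("g1", "g1"))
#' pd$array_ids
#' @export
probe_data <- function(intensities, probeset, array_ids = colnames(intensities),
                       log2_transform = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix (probes x arrays)")
  if (isTRUE(log2_transform)) {
    if (any(intensities < 0))
      stop("raw-scale intensities must be non-negative for log2 transformation")
    intensities <- log2(intensities + 1)
  }
  if (any(!is.finite(intensities)))
    stop("all intensities must be finite")
  if (nrow(intensities) < 1L)
    stop("at least one probe is required")
  if (ncol(intensities) < 2L)
    stop("at least 2 arrays are required")
  probeset <- as.character(probeset)
  if (length(probeset) != nrow(intensities))
    stop("`probeset` must have one entry per probe (row of `intensities`)")
  if (anyNA(probeset) || any(!nzchar(probeset)))
    stop("probeset identifiers must be non-missing and non-empty")
  if (is.null(array_ids))
    array_ids <- paste0("A", seq_len(ncol(intensities)))
  array_ids <- as.character(array_ids)
  if (length(array_ids) != ncol(intensities))
    stop("`array_ids` must have one entry per array")
  if (anyDuplicated(array_ids))
    stop("array labels must be unique; duplicated: ",
         paste(unique(array_ids[duplicated(array_ids)]), collapse = ", "))
  probe_ids <- rownames(intensities)
  if (is.null(probe_ids))
    probe_ids <- paste0("p", seq_len(nrow(intensities)))
  if (anyDuplicated(probe_ids))
    stop("probe identifiers must be unique; duplicated probe_id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  dimnames(intensities) <- list(probe_ids, array_ids)
  structure(list(intensities = intensities,
                 probeset = probeset,
                 array_ids = array_ids),
            class = "probe_data")
}

#' @export
print.probe_data <- function(x, ...) {
  cat(sprintf("probe_data: %d probes, %d genes, %d arrays\n",
              nrow(x$intensities), length(unique(x$probeset)),
              length(x$array_ids)))
  cat("arrays:", paste(x$array_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Gene identifiers of a probe-level matrix
#'
#' @param data A [probe_data] object.
#' @return Character vector of gene (probeset) identifiers, in order of first
#'   appearance.
#' @export
gene_ids <- function(data) {
  stopifnot(inherits(data, "probe_data"))
  unique(data$probeset)
}

# validate and normalize an array subset request against a probe_data object
.check_array_subset <- function(data, arrays, min_size = 1L) {
  if (length(arrays) < min_size)
    stop("array subset must contain at least ", min_size, " array(s)")
  bad <- setdiff(arrays, data$array_ids)
  if (length(bad))
    stop("unknown array label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(arrays))
    stop("array subset contains duplicates")
  as.character(arrays)
}
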