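#' Strictly per-array expression summarization
#'
#' Summarizes each gene on each array as the (optionally trimmed) mean of its
#' probes' log2 intensities on that array alone.  No information crosses
#' array boundaries at any step, so the summary for `(gene, array)` is
#' unchanged no matter which other arrays are included in the run.  This is
#' the package's reference point for a numerically independent method (the
#' independence property that MAS5 has in practice), and under the jackknife
#' it yields JED identically zero off the diagonal.
#'
#' @param data A [probe_data] object.
#' @param arrays Character vector of array labels to include (default: all).
#' @param trim Trim fraction passed to [mean()] for a robust-mean variant;
#'   0 (default) gives the plain mean.
#' @return An [expression_matrix] with `method_tag = "perarray"`.
#' @examples
#' pd <- probe_data(matrix(c(2, 4, 1, 5), 2), probeset = c("g1", "g1"))
#' summarize_per_array(pd)$summaries
#' @export
summarize_per_array <- function(data, arrays = data$array_ids, trim = 0) {
  stopifnot(inherits(data, "probe_data"))
  arrays <- .check_array_subset(data, arrays, min_size = 1L)
  x <- data$intensities[, arrays, drop = FALSE]
  genes <- gene_ids(data)
  if (trim == 0) {
    raw <- rowsum(x, group = data$probeset, reorder = FALSE) /
      as.vector(table(factor(data$probeset, levels = genes)))
  } else {
    raw <- t(vapply(genes, function(g) {
      apply(x[data$probeset == g, , drop = FALSE], 2, mean, trim = trim)
    }, numeric(length(arrays))))
  }
  dimnames(raw) <- list(genes, arrays)
  expression_matrix(raw, method_tag = "perarray", included_arrays = arrays)
}

#' Quantile normalization across arrays
#'
#' Forces every array (column) to share the same empirical distribution by
#' mapping each column's order statistics to their across-array means.  Ties
#' are resolved by the average-of-tied-ranks convention.  The heavy lifting
#' is done by [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix (rows x arrays) of finite values.
#' @return A matrix of the same shape whose column-sorted value vectors are
#'   all identical.  With a single column the input is returned unchanged,
#'   with a warning.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(6, 4, 5)))
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be a finite numeric matrix")
  if (ncol(x) == 1L) {
    warning("quantile normalization needs >= 2 arrays; returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Median polish decomposition of a gene's probe matrix
#'
#' Iterative row-then-column median sweeps decomposing a probe x array matrix
#' into `overall + probe_effect + array_effect + residual`.  This is Tukey's
#' median polish as implemented in [stats::medpolish()], run row-first with a
#' cap of `maxiter` iterations and relative tolerance `eps` on the change in
#' the summed absolute residuals.  The decomposition reproduces the input
#' exactly at every iteration, so reconstruction is exact regardless of
#' convergence.
#'
#' @param x Numeric matrix, probes x arrays, all finite.
#' @param eps Relative convergence tolerance (default 0.01).
#' @param maxiter Maximum number of sweep iterations (default 10).
#' @return A list with components `overall` (scalar), `probe_effects` (row
#'   effects), `array_effects` (column effects) and `residuals` (matrix).
#' @examples
#' mp <- median_polish(outer(c(0, 1, 2), c(5, 6), "+"))
#' max(abs(mp$residuals))  # exactly additive input -> zero residuals
#' @export
median_polish <- function(x, eps = 0.01, maxiter = 10L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be a finite numeric matrix")
  if (nrow(x) == 1L && ncol(x) == 1L) {
    return(list(overall = x[1L, 1L],
                probe_effects = stats::setNames(0, rownames(x)),
                array_effects = stats::setNames(0, colnames(x)),
                residuals = array(0, dim(x), dimnames(x))))
  }
  mp <- stats::medpolish(x, eps = eps, maxiter = maxiter, trace.iter = FALSE)
  list(overall = mp$overall,
       probe_effects = mp$row,
       array_effects = mp$col,
       residuals = mp$residuals)
}

#' Quantile-normalization + median-polish summarization
#'
#' The package's cross-array method: quantile-normalize the probe intensities
#' over the chosen array subset, then summarize each gene by median polish,
#' reporting `overall + array_effect` per array.  Because both steps pool
#' information across arrays, a summary on one array generally changes when
#' the subset changes — the behaviour that RMA-style pipelines exhibit and
#' that JED is designed to expose.
#'
#' @param data A [probe_data] object.
#' @param arrays Character vector of array labels to include (>= 2).
#' @param eps,maxiter Median-polish controls, see [median_polish()].
#' @return An [expression_matrix] with `method_tag = "rmalike"`.
#' @export
summarize_rma_like <- function(data, arrays = data$array_ids,
                               eps = 0.01, maxiter = 10L) {
  stopifnot(inherits(data, "probe_data"))
  arrays <- .check_array_subset(data, arrays, min_size = 2L)
  xq <- quantile_normalize(data$intensities[, arrays, drop = FALSE])
  genes <- gene_ids(data)
  raw <- matrix(NA_real_, length(genes), length(arrays),
                dimnames = list(genes, arrays))
  for (g in genes) {
    mp <- median_polish(xq[data$probeset == g, , drop = FALSE],
                        eps = eps, maxiter = maxiter)
    raw[g, ] <- mp$overall + mp$array_effects
  }
  expression_matrix(raw, method_tag = "rmalike", included_arrays = arrays)
}

#' Run a built-in preprocessing method on a subset of arrays
#'
#' Common entry point used by the jackknife driver and the command line.  All
#' built-in methods satisfy the same contract: given a probe-level matrix and
#' an array subset, return an [expression_matrix] over exactly that subset
#' (with the negative-summary reset already applied using the run's own
#' per-array floors).
#'
#' @param data A [probe_data] object.
#' @param method `"perarray"`, `"rmalike"` or `"mindep"`, or a function
#'   `f(data, arrays)` returning an [expression_matrix] over `arrays`.
#' @param arrays Array labels to include (default: all).
#' @param lambda MINDEP weight in `[0, 1]`; required when
#'   `method = "mindep"`, ignored otherwise.
#' @return An [expression_matrix].
#' @export
preprocess_arrays <- function(data, method, arrays = data$array_ids,
                              lambda = NULL) {
  runner <- .method_runner(method, lambda)
  runner(data, arrays)
}

# turn a method spec (name or function) into a function(data, arrays)
.method_runner <- function(method, lambda = NULL) {
  if (is.function(method)) return(method)
  method <- match.arg(method, c("perarray", "rmalike", "mindep"))
  switch(method,
    perarray = function(data, arrays) summarize_per_array(data, arrays),
    rmalike  = function(data, arrays) summarize_rma_like(data, arrays),
    mindep   = {
      if (is.null(lambda))
        stop("`lambda` is required for the mindep method")
      function(data, arrays) summarize_mindep(data, arrays, lambda = lambda)
    })
}
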