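#' Expression summary matrix with negative-summary reset
#'
#' Wraps a gene x array matrix of raw (as-produced) expression summaries and
#' applies the reset rule: summaries are interpreted on a non-negative log
#' scale, and a non-positive raw summary is taken as showing very little
#' evidence of expression and is reset to the smallest positive raw summary
#' observed for all genes on that array (the array's "floor").  Both the raw
#' and the post-reset values are kept: JED is computed on post-reset values,
#' while sign-change counting needs the raw ones.
#'
#' @param raw Numeric gene x array matrix of raw summaries (may contain
#'   non-positive values).  Row and column names identify genes and arrays.
#' @param method_tag Short label of the preprocessing method that produced
#'   the summaries.
#' @param included_arrays Array labels this run used; defaults to the column
#'   names of `raw`.
#' @return An object of class `expression_matrix`: a list with `summaries`
#'   (post-reset, all positive), `raw_summaries`, `array_floors` (named
#'   per-array positive floors), `method_tag` and `included_arrays`.
#' @examples
#' em <- expression_matrix(cbind(A1 = c(-2, 0.5, 3), A2 = c(1, 2, 3)), "toy")
#' em$summaries[, "A1"]
#' em$array_floors
#' @export
expression_matrix <- function(raw, method_tag = "external",
                              included_arrays = colnames(raw)) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("raw summaries must be finite numeric values")
  if (is.null(colnames(raw))) {
    if (is.null(included_arrays))
      included_arrays <- paste0("A", seq_len(ncol(raw)))
    colnames(raw) <- included_arrays
  }
  if (is.null(rownames(raw)))
    rownames(raw) <- paste0("g", seq_len(nrow(raw)))
  included_arrays <- as.character(included_arrays)
  if (!identical(included_arrays, colnames(raw)))
    stop("`included_arrays` must match the columns of `raw`")
  no_pos <- colSums(raw > 0) == 0L
  if (any(no_pos))
    stop("array(s) with no positive raw summary, cannot determine floor: ",
         paste(colnames(raw)[no_pos], collapse = ", "))
  floors <- apply(raw, 2, function(v) min(v[v > 0]))
  summaries <- raw
  for (j in seq_len(ncol(raw))) {
    low <- raw[, j] <= 0
    summaries[low, j] <- floors[j]
  }
  structure(list(summaries = summaries,
                 raw_summaries = raw,
                 array_floors = floors,
                 method_tag = method_tag,
                 included_arrays = included_arrays),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d arrays; %d value(s) reset\n",
              x$method_tag, nrow(x$summaries), ncol(x$summaries),
              sum(x$raw_summaries <= 0)))
  invisible(x)
}

#' Apply the negative-summary reset rule
#'
#' Convenience constructor equivalent to [expression_matrix()]: every raw
#' summary that is zero or negative is replaced by its array's smallest
#' positive raw summary.
#'
#' @inheritParams expression_matrix
#' @return An [expression_matrix].
#' @export
reset_negative_summaries <- function(raw, method_tag = "external") {
  expression_matrix(raw, method_tag = method_tag)
}

#' Bundle full-data and leave-one-out preprocessing runs
#'
#' @param full [expression_matrix] from the run over all A arrays.
#' @param loo Named list of A [expression_matrix] objects; `loo[[j]]` is the
#'   run that excluded array `j` (and only array `j`), over the remaining
#'   A - 1 arrays in the original order.
#' @param method_tag Label; defaults to the full run's tag.
#' @return An object of class `jackknife_set`.
#' @export
jackknife_set <- function(full, loo, method_tag = full$method_tag) {
  stopifnot(inherits(full, "expression_matrix"))
  arrays <- full$included_arrays
  if (length(loo) != length(arrays))
    stop("`loo` must contain exactly one run per array (", length(arrays), ")")
  if (is.null(names(loo)))
    names(loo) <- arrays
  if (!setequal(names(loo), arrays))
    stop("names of `loo` must be the array labels")
  loo <- loo[arrays]
  genes <- rownames(full$summaries)
  for (j in arrays) {
    ej <- loo[[j]]
    if (!inherits(ej, "expression_matrix"))
      stop("loo[['", j, "']] is not an expression_matrix")
    if (!identical(ej$included_arrays, setdiff(arrays, j)))
      stop("loo[['", j, "']] must cover exactly the arrays other than ", j,
           ", in the original order")
    if (!identical(rownames(ej$summaries), genes))
      stop("loo[['", j, "']] does not share the gene index of the full run")
  }
  structure(list(full = full, loo = loo, method_tag = method_tag,
                 arrays = arrays),
            class = "jackknife_set")
}

#' @export
print.jackknife_set <- function(x, ...) {
  cat(sprintf("jackknife_set [%s]: %d genes, %d arrays, %d preprocessing runs\n",
              x$method_tag, nrow(x$full$summaries), length(x$arrays),
              length(x$arrays) + 1L))
  invisible(x)
}

#' Run the leave-one-out jackknife over a preprocessing method
#'
#' Preprocesses the data A + 1 times: once with all A arrays, then once with
#' each array excluded from every step of the preprocessing.  Each run
#' applies the negative-summary reset with its own per-array floors.  The
#' cached runs are shared across array pairs: the pair (i, j) reuses the
#' runs that excluded j and i.
#'
#' @param data A [probe_data] object with at least 2 arrays.
#' @param method Method name (`"perarray"`, `"rmalike"`, `"mindep"`) or a
#'   function `f(data, arrays)` returning an [expression_matrix]; see
#'   [preprocess_arrays()].
#' @param lambda MINDEP weight, required when `method = "mindep"`.
#' @return A [jackknife_set].
#' @examples
#' pd <- gen_probe_data(genes = 5, probes_per_gene = 3, arrays = 3, seed = 1)
#' jk <- run_jackknife(pd, "perarray")
#' max(abs(compute_jed(jk)$jed[compute_jed(jk)$array_i != compute_jed(jk)$array_j]))
#' @export
run_jackknife <- function(data, method, lambda = NULL) {
  stopifnot(inherits(data, "probe_data"))
  arrays <- data$array_ids
  if (length(arrays) < 2L)
    stop("the jackknife needs at least 2 arrays")
  runner <- .method_runner(method, lambda)
  full <- runner(data, arrays)
  loo <- lapply(arrays, function(j) {
    tryCatch(runner(data, setdiff(arrays, j)),
             error = function(e)
               stop("preprocessing failed on the subset excluding array ",
                    j, ": ", conditionMessage(e), call. = FALSE))
  })
  names(loo) <- arrays
  jackknife_set(full, loo)
}

# internal: long table of per-gene, per-pair jackknife quantities.
# Rows are ordered gene-major, within gene the i < j pairs first (i, then j
# ascending in array order), then the diagonal entries.
.pair_table <- function(jk) {
  stopifnot(inherits(jk, "jackknife_set"))
  arrays <- jk$arrays
  A <- length(arrays)
  genes <- rownames(jk$full$summaries)
  y <- jk$full$summaries
  yraw <- jk$full$raw_summaries

  blocks <- list()
  for (a in seq_len(A)) {
    for (b in a:A) {
      i <- arrays[a]; j <- arrays[b]
      if (a == b) {
        # convention y_{i(-i)} = 0: both half-terms are |y - 0| / y = 1, and
        # a positive raw summary "flips" against the all-excluded zero
        jed <- rep(1, length(genes))
        sc <- 2L * as.integer(yraw[, i] > 0)
        dist <- rep(0, length(genes))
      } else {
        yi_mj <- jk$loo[[j]]$summaries[, i]
        yj_mi <- jk$loo[[i]]$summaries[, j]
        term_i <- abs(y[, i] - yi_mj) / y[, i]
        term_j <- abs(y[, j] - yj_mi) / y[, j]
        jed <- (term_i + term_j) / 2
        sc <- as.integer((yraw[, i] > 0) != (jk$loo[[j]]$raw_summaries[, i] > 0)) +
          as.integer((yraw[, j] > 0) != (jk$loo[[i]]$raw_summaries[, j] > 0))
        dist <- jed
      }
      blocks[[length(blocks) + 1L]] <-
        data.frame(gene = genes, array_i = i, array_j = j,
                   jed = jed, sign_changes = sc, distance = dist,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  gidx <- match(out$gene, genes)
  diag_flag <- out$array_i == out$array_j
  out <- out[order(gidx, diag_flag,
                   match(out$array_i, arrays), match(out$array_j, arrays)), ]
  rownames(out) <- NULL
  out
}

#' Compute the Jackknife Expression Difference table
#'
#' For each gene and each pair of arrays (i, j), JED is the average relative
#' change in the two arrays' post-reset summaries under mutual leave-one-out:
#' \deqn{JED_{ij} = \frac{1}{2}\left(\frac{|y_i - y_{i(-j)}|}{y_i} +
#'   \frac{|y_j - y_{j(-i)}|}{y_j}\right),}
#' where \eqn{y_{i(-j)}} is array i's summary when array j is excluded from
#' every step of the preprocessing, and \eqn{y_{i(-i)} = 0} by convention (no
#' information for an excluded array), which forces the diagonal to equal 1.
#' JED is 0 exactly when both leave-one-out summaries equal the full-data
#' summaries (strict numerical independence), is symmetric and non-negative,
#' and reads as the average percent change in the gene's expression value due
#' to inclusion/exclusion of the pair.  Values above 1 are possible (relative
#' changes can exceed 100%) and are reported, not truncated.
#'
#' The accompanying distance is `d_ij = JED_ij` off the diagonal and 0 on it;
#' `sign_changes` counts how many of the pair's two raw leave-one-out
#' summaries changed strict sign (positive vs non-positive) relative to the
#' full run — 0, 1 or 2.
#'
#' @param jk A [jackknife_set].
#' @return A data frame of class `jed_table` with columns `gene`, `array_i`,
#'   `array_j`, `jed`, `sign_changes`, `distance`, ordered gene-major with
#'   the i < j pairs before the diagonal entries.  The method tag is attached
#'   as attribute `method_tag`.
#' @examples
#' jk <- gen_jackknife_fixture(full = cbind(A1 = 8, A2 = 10),
#'                             loo = list(A1 = cbind(A2 = 7.5),
#'                                        A2 = cbind(A1 = 6)))
#' compute_jed(jk)  # off-diagonal JED 0.25: an average 25% change
#' @export
compute_jed <- function(jk) {
  out <- .pair_table(jk)
  bad <- out$jed < 0 | !is.finite(out$jed)
  if (any(bad))
    stop("internal error: invalid JED value (non-positive denominator?)")
  structure(out, class = c("jed_table", "data.frame"),
            method_tag = jk$method_tag)
}

#' Count jackknife-induced sign changes per gene and array pair
#'
#' A preprocessing method that can produce non-positive raw summaries may
#' see a summary flip sign when an array is excluded; each pair of arrays
#' contributes two comparisons (i under exclusion of j, and j under exclusion
#' of i), so the count is 0, 1 or 2.  After the reset rule maps the flipped
#' summary to a small array floor, one flip drives the affected half of the
#' JED toward 1/2 and two flips drive JED toward 1 — the banding the JED
#' display shows for methods with negative summaries.
#'
#' @param jk A [jackknife_set] (raw, pre-reset values are used).
#' @return Data frame with columns `gene`, `array_i`, `array_j`,
#'   `sign_changes`, same row order as [compute_jed()].
#' @export
count_sign_changes <- function(jk) {
  .pair_table(jk)[, c("gene", "array_i", "array_j", "sign_changes")]
}

#' Summary statistics of a JED table
#'
#' @param table A `jed_table` from [compute_jed()].
#' @param suppress_diagonal Drop the diagonal (always-1) entries before
#'   summarizing (default `TRUE`, matching how JED distributions are usually
#'   displayed).
#' @param thresholds JED thresholds for which exceedance fractions are
#'   reported.
#' @param by_sign_changes Also report one stratum per observed sign-change
#'   count.
#' @return Data frame with one row per stratum (`"all"` plus, optionally,
#'   `"sign_changes=k"`) and columns `n`, `mean`, `min`, `q25`, `median`,
#'   `q75`, `max` and `frac_gt_<t>` per threshold.
#' @export
summarize_jed <- function(table, suppress_diagonal = TRUE,
                          thresholds = c(0.25, 0.5, 1),
                          by_sign_changes = FALSE) {
  stopifnot(inherits(table, "data.frame"))
  if (suppress_diagonal)
    table <- table[table$array_i != table$array_j, , drop = FALSE]
  if (nrow(table) == 0L)
    stop("no JED entries left to summarize",
         if (suppress_diagonal) " after diagonal suppression")
  one <- function(v) {
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    row <- data.frame(n = length(v), mean = mean(v), min = min(v),
                      q25 = qs[1], median = qs[2], q75 = qs[3], max = max(v))
    for (t in thresholds)
      row[[sprintf("frac_gt_%g", t)]] <- mean(v > t)
    row
  }
  out <- cbind(stratum = "all", one(table$jed))
  if (by_sign_changes) {
    for (k in sort(unique(table$sign_changes))) {
      v <- table$jed[table$sign_changes == k]
      out <- rbind(out, cbind(stratum = sprintf("sign_changes=%d", k), one(v)))
    }
  }
  rownames(out) <- NULL
  out
}
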