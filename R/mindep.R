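#' Fit the MINDEP two-way ANOVA model for one gene
#'
#' MINDEP ("minimum dependency") is a deliberately simple preprocessing
#' method whose summaries have a covariance matrix obtainable from standard
#' least-squares theory, which makes it useful as a reference point when
#' relating JED to statistical correlation.  No background correction or
#' normalization is done; for each gene the log2 PM intensities are modeled
#' additively as
#' \deqn{x_{pi} = \mu_i + \beta_p + \varepsilon_{pi},}
#' with an array effect \eqn{\mu_i}, a probe effect \eqn{\beta_p} and iid
#' errors.  The model is fit by ordinary least squares on the balanced
#' probes x arrays layout.  The LSMEAN (marginal mean) for array \eqn{i} is
#' the array effect plus the average probe effect; in the balanced layout it
#' equals the column mean of the gene's probe matrix and is invariant to the
#' identifiability constraint used for the probe effects.
#'
#' @param data A [probe_data] object.
#' @param gene Gene (probeset) identifier to fit.
#' @param arrays Array labels to include (default: all; >= 2 for a
#'   non-degenerate fit).
#' @param constraint Identifiability constraint for the probe effects:
#'   `"sum"` (sum-to-zero, the default) or `"reference"` (first probe as
#'   baseline).  LSMEANs and everything derived from them are invariant to
#'   this choice.
#' @return An object of class `mindep_fit`: a list with the parameter
#'   estimates `theta`, their covariance `cov_theta` (residual-MSE scaled),
#'   the unscaled `(X'X)^{-1}` in `xtx_inv`, the LSMEAN coefficient matrix
#'   `L` (arrays x parameters), `lsmeans`, the residual variance estimate
#'   `sigma2`, residual degrees of freedom `df_residual`, the index `argmin`
#'   of the array attaining the minimum LSMEAN, and the layout sizes `P`
#'   (probes) and `A` (arrays).
#' @examples
#' pd <- probe_data(matrix(c(1, 3, 2, 4), 2), probeset = c("g1", "g1"))
#' mindep_fit(pd, "g1")$lsmeans
#' @export
mindep_fit <- function(data, gene, arrays = data$array_ids,
                       constraint = c("sum", "reference")) {
  stopifnot(inherits(data, "probe_data"))
  constraint <- match.arg(constraint)
  arrays <- .check_array_subset(data, arrays, min_size = 1L)
  keep <- data$probeset == gene
  if (!any(keep))
    stop("unknown gene: ", gene)
  xg <- data$intensities[keep, arrays, drop = FALSE]
  P <- nrow(xg)
  A <- ncol(xg)
  if (P < 2L || A < 2L)
    warning("fewer than 2 probes or 2 arrays: parameter covariance is degenerate")

  y <- as.vector(xg)                      # probe index varies fastest
  arr_f <- factor(rep(arrays, each = P), levels = arrays)
  X <- stats::model.matrix(~ 0 + arr_f)
  if (P > 1L) {
    Cmat <- if (constraint == "sum") stats::contr.sum(P) else stats::contr.treatment(P)
    X <- cbind(X, Cmat[rep(seq_len(P), times = A), , drop = FALSE])
  } else {
    Cmat <- matrix(0, 1L, 0L)
  }
  colnames(X) <- c(paste0("mu_", arrays),
                   if (ncol(Cmat)) paste0("beta_", seq_len(ncol(Cmat))))

  xtx <- crossprod(X)
  xtx_inv <- tryCatch(solve(xtx), error = function(e)
    stop("rank-deficient design for gene ", gene,
         " under the '", constraint, "' constraint"))
  theta <- drop(xtx_inv %*% crossprod(X, y))
  names(theta) <- colnames(X)
  resid <- y - drop(X %*% theta)
  df_residual <- length(y) - ncol(X)      # N - (A + P - 1)
  sigma2 <- if (df_residual >= 1L) sum(resid^2) / df_residual else NA_real_
  # snap numerically-zero residual variance (noise-free data) to exact zero
  if (!is.na(sigma2) && sigma2 < 1e-20) sigma2 <- 0

  # LSMEAN_i = mu_i + mean over probes of the probe effects; rows of L give
  # the coefficient vector of each LSMEAN in theta
  L <- cbind(diag(A),
             matrix(rep(colMeans(Cmat), each = A), nrow = A))
  dimnames(L) <- list(arrays, colnames(X))
  lsmeans <- drop(L %*% theta)
  names(lsmeans) <- arrays

  structure(list(gene = gene, arrays = arrays, P = P, A = A,
                 constraint = constraint,
                 theta = theta, xtx_inv = xtx_inv,
                 sigma2 = sigma2, df_residual = df_residual,
                 cov_theta = if (is.na(sigma2)) xtx_inv * NA_real_ else sigma2 * xtx_inv,
                 L = L, lsmeans = lsmeans,
                 argmin = which.min(lsmeans)),
            class = "mindep_fit")
}

#' @export
print.mindep_fit <- function(x, ...) {
  cat(sprintf("mindep_fit: gene %s, %d probes x %d arrays ('%s' constraint)\n",
              x$gene, x$P, x$A, x$constraint))
  cat("LSMEANs:\n"); print(x$lsmeans)
  cat(sprintf("residual variance %.6g on %d df; argmin array: %s\n",
              x$sigma2, x$df_residual, x$arrays[x$argmin]))
  invisible(x)
}

#' MINDEP expression summaries from a fitted model
#'
#' The MINDEP summary for array \eqn{i} subtracts a fraction \eqn{\lambda} of
#' the minimum LSMEAN over the included arrays from the array's own LSMEAN:
#' \deqn{y_i = \mathrm{LSMEAN}_i - \lambda \min_k \mathrm{LSMEAN}_k.}
#' The subtraction acts as a pseudo background correction; because the
#' minimum is computed across arrays, any \eqn{\lambda > 0} couples every
#' array's summary to the minimizing array, and larger \eqn{\lambda}
#' introduces greater dependence.  At \eqn{\lambda = 0} the summary depends
#' only on the array's own data.  Each summary is also expressible as a
#' linear form \eqn{c_i'\hat\theta} with the minimizing array held fixed at
#' its observed index; the coefficient vectors are returned so the
#' closed-form covariance can be assembled.
#'
#' @param fit A [mindep_fit] object.
#' @param lambda Weight in `[0, 1]`.
#' @return A list with `raw` (named per-array raw summaries, possibly
#'   non-positive), `c` (arrays x parameters coefficient matrix, one row per
#'   `c_i`), `argmin` (index of the minimizing array) and `lambda`.
#' @export
mindep_summarize <- function(fit, lambda) {
  stopifnot(inherits(fit, "mindep_fit"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  m <- fit$argmin
  cmat <- fit$L - lambda * matrix(fit$L[m, ], nrow = fit$A, ncol = ncol(fit$L),
                                  byrow = TRUE)
  rownames(cmat) <- fit$arrays
  raw <- drop(cmat %*% fit$theta)
  names(raw) <- fit$arrays
  list(raw = raw, c = cmat, argmin = m, lambda = lambda)
}

#' Closed-form covariance and correlation of MINDEP summaries
#'
#' From least-squares theory, \eqn{\mathrm{Cov}(\hat\theta) =
#' \sigma^2 (X'X)^{-1}}, so with the coefficient vectors of
#' [mindep_summarize()] the between-array covariance of the summaries is
#' \deqn{\mathrm{Cov}(y_i, y_j) = c_i' \mathrm{Cov}(\hat\theta)\, c_j,}
#' treating the array attaining the minimum LSMEAN as fixed at its observed
#' index (the closed form cannot account for the minimizer switching between
#' replicates; see the package vignette).  The correlation matrix is the
#' covariance rescaled by its diagonal, with the convention that any pair
#' involving a zero-variance summary is reported as correlation 0.
#'
#' @param fit A [mindep_fit] object with positive residual degrees of
#'   freedom.
#' @param lambda Weight in `[0, 1]`.
#' @param sigma2 Error variance to plug in; defaults to the fit's residual
#'   MSE.  Supplying the known simulation variance gives the exact covariance
#'   for oracle comparisons.
#' @return A list with symmetric `covariance` and `correlation` matrices
#'   (arrays x arrays).
#' @export
mindep_covariance <- function(fit, lambda, sigma2 = fit$sigma2) {
  stopifnot(inherits(fit, "mindep_fit"))
  if (is.na(sigma2))
    stop("residual variance is unavailable (no residual degrees of freedom); ",
         "supply `sigma2` explicitly")
  s <- mindep_summarize(fit, lambda)
  if (sigma2 == 0)
    warning("zero residual variance: covariance is a zero matrix and ",
            "correlations are reported as 0 by convention")
  V <- s$c %*% (sigma2 * fit$xtx_inv) %*% t(s$c)
  V <- (V + t(V)) / 2
  d <- sqrt(pmax(diag(V), 0))
  corr <- matrix(0, fit$A, fit$A, dimnames = dimnames(V))
  ok <- d > 0
  if (any(ok))
    corr[ok, ok] <- V[ok, ok, drop = FALSE] / tcrossprod(d[ok])
  diag(corr)[ok] <- 1
  list(covariance = V, correlation = corr)
}

#' MINDEP preprocessing over a subset of arrays
#'
#' Applies the MINDEP summary to every gene: per-gene LSMEANs (column means
#' of the balanced probe matrix) minus `lambda` times their minimum over the
#' included arrays.  During jackknife runs the excluded array contributes
#' nothing — the minimum is taken over the included arrays only.
#'
#' @param data A [probe_data] object.
#' @param arrays Array labels to include.
#' @param lambda Weight in `[0, 1]`.
#' @return An [expression_matrix] with `method_tag = "mindep"`.
#' @export
summarize_mindep <- function(data, arrays = data$array_ids, lambda) {
  stopifnot(inherits(data, "probe_data"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  arrays <- .check_array_subset(data, arrays, min_size = 1L)
  genes <- gene_ids(data)
  x <- data$intensities[, arrays, drop = FALSE]
  lsm <- rowsum(x, group = data$probeset, reorder = FALSE) /
    as.vector(table(factor(data$probeset, levels = genes)))
  raw <- lsm - lambda * apply(lsm, 1, min)
  dimnames(raw) <- list(genes, arrays)
  expression_matrix(raw, method_tag = sprintf("mindep(lambda=%g)", lambda),
                    included_arrays = arrays)
}
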