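#' Compound-symmetric correlation matrix
#'
#' @param n_total Matrix dimension (total number of observations).
#' @param rho Common off-diagonal correlation.  Positive definiteness
#'   requires `rho > -1/(n_total - 1)` and `rho < 1`.
#' @return `n_total` x `n_total` matrix with 1 on the diagonal and `rho`
#'   everywhere else.  Its eigenvalues are `1 + (n_total - 1) * rho` (once)
#'   and `1 - rho` (repeated).
#' @examples
#' cs_covariance(4, 0.5)
#' @export
cs_covariance <- function(n_total, rho) {
  n_total <- as.integer(n_total)
  if (n_total < 2L)
    stop("`n_total` must be at least 2")
  if (!is.numeric(rho) || length(rho) != 1L)
    stop("`rho` must be a single number")
  if (rho >= 1 || rho <= -1 / (n_total - 1))
    stop(sprintf("rho = %g is outside the positive-definite range (%g, 1) for m = %d",
                 rho, -1 / (n_total - 1), n_total))
  m <- matrix(rho, n_total, n_total)
  diag(m) <- 1
  m
}

#' Two-sample scenario with compound-symmetric errors
#'
#' An illustrative two-group comparison with `n` replicates per group whose
#' 2n errors are jointly normal with common variance `sigma2` and common
#' pairwise correlation `rho` (compound symmetry).  The comparison is run as
#' a z-test on the slope of a two-column linear model; `beta1` is the
#' treatment effect, defined throughout as the difference in group means so
#' that the power of the tests does not depend on how the group column is
#' coded.  The scenario quantifies how much power is lost when the analyst
#' ignores a true positive dependence `rho` — the same loss that motivates
#' checking preprocessing methods for induced between-array dependence.
#'
#' @param n Replicates per group (>= 2).
#' @param rho Common error correlation; `[0, 1)` by default.  Negative values
#'   down to the positive-definite limit `-1/(2n - 1)` are allowed only with
#'   `allow_negative_rho = TRUE`.
#' @param beta1 Treatment effect (difference in group means).
#' @param alpha Two-sided test level in (0, 1); default 0.05.
#' @param sigma2 Error variance; default 1 (errors on the correlation scale).
#' @param coding Design-column convention for the group column: `"pm1"`
#'   (n -1's followed by n +1's, the default) or `"01"`.
#' @param allow_negative_rho Permit `rho < 0` within the positive-definite
#'   range.
#' @return An object of class `power_scenario`.
#' @examples
#' s <- power_scenario(n = 4, rho = 0.5, beta1 = 1)
#' c(ols = power_ols(s), wls = power_wls(s))
#' @export
power_scenario <- function(n, rho, beta1, alpha = 0.05, sigma2 = 1,
                           coding = c("pm1", "01"),
                           allow_negative_rho = FALSE) {
  coding <- match.arg(coding)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2 replicates per group")
  if (!allow_negative_rho && rho < 0)
    stop("rho < 0 requires `allow_negative_rho = TRUE`")
  if (rho >= 1 || rho <= -1 / (2L * n - 1L))
    stop("rho is outside the positive-definite range for 2n observations")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  structure(list(n = n, rho = rho, beta1 = beta1, alpha = alpha,
                 sigma2 = sigma2, coding = coding),
            class = "power_scenario")
}

# design matrix and effective slope for a scenario.  The treatment effect
# beta1 is the difference in group means; under +/-1 coding the slope on the
# group column is beta1 / 2, under 0/1 coding it is beta1 itself.
.scenario_design <- function(s) {
  m <- 2L * s$n
  col2 <- if (s$coding == "pm1") rep(c(-1, 1), each = s$n) else rep(c(0, 1), each = s$n)
  X <- cbind(intercept = rep(1, m), group = col2)
  slope <- if (s$coding == "pm1") s$beta1 / 2 else s$beta1
  list(X = X, slope = slope, m = m)
}

# the three slope variances that drive the two tests:
#   v_assumed : OLS variance under the (wrong) independence assumption
#   v_true    : true sampling variance of the OLS slope under CS errors
#   v_wls     : variance of the GLS slope, (X' Sigma^-1 X)^-1
.scenario_variances <- function(s) {
  d <- .scenario_design(s)
  R <- cs_covariance(d$m, s$rho)
  xtx_inv <- solve(crossprod(d$X))
  H <- xtx_inv %*% t(d$X)
  v_true <- s$sigma2 * (H %*% R %*% t(H))[2L, 2L]
  v_assumed <- s$sigma2 * xtx_inv[2L, 2L]
  v_wls <- s$sigma2 * solve(t(d$X) %*% solve(R) %*% d$X)[2L, 2L]
  list(v_assumed = v_assumed, v_true = v_true, v_wls = v_wls,
       slope = d$slope)
}

# two-sided rejection probability of a z-statistic distributed N(mu, sd^2)
# against +/- z_{alpha/2}
.two_sided_power <- function(mu, sd, alpha) {
  za <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((-za - mu) / sd) + 1 - stats::pnorm((za - mu) / sd)
}

#' Power of the ordinary least squares z-test (dependence ignored)
#'
#' The OLS slope is standardized by the standard error that assumes
#' independent errors, `sqrt(sigma2 * [(X'X)^-1]_22)`, while its true
#' sampling variance under compound-symmetric errors is the sandwich
#' `sigma2 * [(X'X)^-1 X' R X (X'X)^-1]_22`.  The returned value is the
#' exact two-sided rejection probability of that mis-scaled z-statistic.
#' For `rho > 0` the assumed standard error is too large, the test is
#' conservative, and power is lost relative to [power_wls()].
#'
#' @param s A [power_scenario].
#' @return Rejection probability in `[0, 1]`.
#' @export
power_ols <- function(s) {
  stopifnot(inherits(s, "power_scenario"))
  v <- .scenario_variances(s)
  .two_sided_power(mu = v$slope / sqrt(v$v_assumed),
                   sd = sqrt(v$v_true / v$v_assumed),
                   alpha = s$alpha)
}

#' Power of the weighted (generalized) least squares z-test
#'
#' The GLS slope uses the true error structure: its variance is
#' `sigma2 * [(X' R^-1 X)^-1]_22` and the z-statistic is correctly scaled,
#' so the test is exact at level `alpha` under the null for every `rho`.
#'
#' @param s A [power_scenario].
#' @return Rejection probability in `[0, 1]`.
#' @export
power_wls <- function(s) {
  stopifnot(inherits(s, "power_scenario"))
  v <- .scenario_variances(s)
  .two_sided_power(mu = v$slope / sqrt(v$v_wls), sd = 1, alpha = s$alpha)
}

#' Power grid over dependence and effect size
#'
#' Evaluates the closed-form OLS and WLS powers on a (rho, beta1) grid, the
#' analogue of the power-contour display: ignoring dependence costs power,
#' with greater losses for larger `rho` and smaller `beta1`.
#'
#' @param rhos,beta1s Grid values (rho in `[0, 1)`).
#' @param n Replicates per group.
#' @param alpha Two-sided level.
#' @param sigma2,coding Passed to [power_scenario()].
#' @return An object of class `power_grid`: list with `rhos`, `beta1s` and
#'   matrices `p_ols`, `p_wls`, `diff` (= `p_wls - p_ols`, non-negative for
#'   `rho >= 0`), rows indexed by rho and columns by beta1.
#' @examples
#' g <- power_grid(rhos = c(0, 0.5), beta1s = c(0.5, 1), n = 4)
#' g$diff
#' @export
power_grid <- function(rhos, beta1s, n, alpha = 0.05, sigma2 = 1,
                       coding = "pm1") {
  if (!length(rhos) || !length(beta1s))
    stop("`rhos` and `beta1s` must be non-empty")
  p_ols <- p_wls <- matrix(NA_real_, length(rhos), length(beta1s),
                           dimnames = list(paste0("rho=", rhos),
                                           paste0("beta1=", beta1s)))
  for (a in seq_along(rhos)) {
    for (b in seq_along(beta1s)) {
      s <- power_scenario(n = n, rho = rhos[a], beta1 = beta1s[b],
                          alpha = alpha, sigma2 = sigma2, coding = coding)
      p_ols[a, b] <- power_ols(s)
      p_wls[a, b] <- power_wls(s)
    }
  }
  structure(list(rhos = rhos, beta1s = beta1s, n = n, alpha = alpha,
                 p_ols = p_ols, p_wls = p_wls, diff = p_wls - p_ols),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("power_grid: n = %d per group, alpha = %g, %d x %d (rho x beta1)\n",
              x$n, x$alpha, length(x$rhos), length(x$beta1s)))
  cat("max power loss from ignoring dependence:", format(max(x$diff)), "\n")
  invisible(x)
}

#' @export
as.data.frame.power_grid <- function(x, ...) {
  data.frame(rho = rep(x$rhos, times = length(x$beta1s)),
             beta1 = rep(x$beta1s, each = length(x$rhos)),
             p_ols = as.vector(x$p_ols),
             p_wls = as.vector(x$p_wls),
             diff = as.vector(x$diff))
}

#' Contour display of a power grid
#'
#' @param x A [power_grid].
#' @param which `"ols"`, `"wls"` or `"diff"`.
#' @param ... Passed to [graphics::contour()].
#' @return Invisibly, `x`.
#' @export
plot.power_grid <- function(x, which = c("wls", "ols", "diff"), ...) {
  which <- match.arg(which)
  z <- switch(which, ols = x$p_ols, wls = x$p_wls, diff = x$diff)
  graphics::contour(x$rhos, x$beta1s, z, xlab = "rho", ylab = "beta1",
                    main = sprintf("%s power (n = %d/group, alpha = %g)",
                                   toupper(which), x$n, x$alpha), ...)
  invisible(x)
}

#' Monte-Carlo oracle for the closed-form powers
#'
#' Draws multivariate-normal responses with the scenario's compound-symmetric
#' error covariance, computes both z-statistics for every draw, and returns
#' the empirical two-sided rejection rates with binomial standard errors.
#' This is the independent check against which the closed forms of
#' [power_ols()] and [power_wls()] are validated.
#'
#' @param s A [power_scenario].
#' @param reps Number of simulated experiments (>= 1000).
#' @param seed Integer seed; identical seeds give identical rates.
#' @return List with elements `ols`, `wls` (rejection rates), `se_ols`,
#'   `se_wls` (binomial standard errors) and `reps`.
#' @export
mc_power_oracle <- function(s, reps, seed) {
  stopifnot(inherits(s, "power_scenario"))
  reps <- as.integer(reps)
  if (reps < 1000L) stop("`reps` must be at least 1000")
  d <- .scenario_design(s)
  v <- .scenario_variances(s)
  R <- cs_covariance(d$m, s$rho)
  U <- chol(s$sigma2 * R)
  mu_vec <- drop(d$X %*% c(0, v$slope))
  a_ols <- (solve(crossprod(d$X)) %*% t(d$X))[2L, ]
  Rinv <- solve(R)
  b_wls <- (solve(t(d$X) %*% Rinv %*% d$X) %*% t(d$X) %*% Rinv)[2L, ]
  za <- stats::qnorm(1 - s$alpha / 2)

  set.seed(seed)
  rej_ols <- 0L; rej_wls <- 0L
  block <- 50000L
  done <- 0L
  while (done < reps) {
    nb <- min(block, reps - done)
    Y <- mu_vec + crossprod(U, matrix(stats::rnorm(d$m * nb), d$m, nb))
    z_ols <- drop(a_ols %*% Y) / sqrt(v$v_assumed)
    z_wls <- drop(b_wls %*% Y) / sqrt(v$v_wls)
    rej_ols <- rej_ols + sum(abs(z_ols) > za)
    rej_wls <- rej_wls + sum(abs(z_wls) > za)
    done <- done + nb
  }
  p_ols <- rej_ols / reps
  p_wls <- rej_wls / reps
  list(ols = p_ols, wls = p_wls,
       se_ols = sqrt(p_ols * (1 - p_ols) / reps),
       se_wls = sqrt(p_wls * (1 - p_wls) / reps),
       reps = reps)
}
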