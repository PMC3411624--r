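#' Generate balanced probe-level data from the two-way model
#'
#' Simulates log2 PM intensities under the additive model that MINDEP fits:
#' for gene g, probe p and array i,
#' \deqn{x_{pig} = baseline_g + array_i + probe_{pg} + \delta_g
#'   \,[i \in treated] + N(0, \sigma^2).}
#' Gene baselines are uniform over `baseline_range`; array effects are evenly
#' spaced from 0 to `array_effect_spread`; probe effects are normal with sd
#' `probe_effect_sd`, centered to sum to zero within each gene.  A fraction
#' of genes may carry a group effect `de_effect` on the treated arrays
#' (second half by default).  The layout is exactly balanced (every probe on
#' every array), as the MINDEP fit requires, and the seed fixes every source
#' of randomness end-to-end.
#'
#' @param genes Number of genes (default 200).
#' @param probes_per_gene Probes per gene (default 11, a typical Affymetrix
#'   probeset size).
#' @param arrays Number of arrays (>= 2; default 6).
#' @param baseline_range Range of gene baselines, log2 units (default 4-10).
#' @param array_effect_spread Largest array effect; effects are evenly
#'   spaced from 0 up to this value (default 1 log2 unit).
#' @param probe_effect_sd SD of probe effects (default 0.5).
#' @param noise_sd Error SD sigma (default 0.25).
#' @param de_fraction Fraction of genes (the first ones) given the group
#'   effect (default 0).
#' @param de_effect Group effect size delta, log2 units (default 1).
#' @param treated_arrays Indices of treated arrays (default: the second
#'   half).
#' @param seed Integer seed (required for reproducibility if supplied;
#'   `NULL` leaves the RNG state alone).
#' @return A [probe_data] object with genes `g1, g2, ...`, probes
#'   `g<k>_p<m>` and arrays `A1, A2, ...`.
#' @examples
#' pd <- gen_probe_data(genes = 10, probes_per_gene = 4, arrays = 3, seed = 1)
#' dim(pd$intensities)
#' @export
gen_probe_data <- function(genes = 200, probes_per_gene = 11, arrays = 6,
                           baseline_range = c(4, 10),
                           array_effect_spread = 1,
                           probe_effect_sd = 0.5,
                           noise_sd = 0.25,
                           de_fraction = 0, de_effect = 1,
                           treated_arrays = NULL,
                           seed = NULL) {
  genes <- as.integer(genes); probes_per_gene <- as.integer(probes_per_gene)
  arrays <- as.integer(arrays)
  if (genes < 1L || probes_per_gene < 1L)
    stop("`genes` and `probes_per_gene` must be at least 1")
  if (arrays < 2L) stop("`arrays` must be at least 2")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (de_fraction < 0 || de_fraction > 1) stop("`de_fraction` must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(treated_arrays))
    treated_arrays <- seq.int(floor(arrays / 2) + 1L, arrays)
  baselines <- stats::runif(genes, baseline_range[1], baseline_range[2])
  array_eff <- seq(0, array_effect_spread, length.out = arrays)
  probe_eff <- matrix(stats::rnorm(genes * probes_per_gene, sd = probe_effect_sd),
                      genes, probes_per_gene)
  probe_eff <- probe_eff - rowMeans(probe_eff)
  n_de <- round(de_fraction * genes)

  n_probes <- genes * probes_per_gene
  g_of_row <- rep(seq_len(genes), each = probes_per_gene)
  p_of_row <- rep(seq_len(probes_per_gene), times = genes)
  mean_mat <- baselines[g_of_row] +
    probe_eff[cbind(g_of_row, p_of_row)] +
    matrix(array_eff, n_probes, arrays, byrow = TRUE)
  if (n_de > 0L)
    mean_mat[g_of_row <= n_de, treated_arrays] <-
      mean_mat[g_of_row <= n_de, treated_arrays] + de_effect
  x <- mean_mat + matrix(stats::rnorm(n_probes * arrays, sd = noise_sd),
                         n_probes, arrays)
  rownames(x) <- paste0("g", g_of_row, "_p", p_of_row)
  probe_data(x, probeset = paste0("g", g_of_row),
             array_ids = paste0("A", seq_len(arrays)))
}

#' Wrap precomputed summary matrices as a jackknife set
#'
#' Direct construction of a [jackknife_set] from raw (pre-reset) summary
#' matrices, without running any preprocessing — for worked examples and for
#' JED on summaries produced by external tools.  The reset rule is applied
#' to each matrix with its own per-array floors.
#'
#' @param full Gene x array matrix of raw full-data summaries (column names
#'   are the array labels).
#' @param loo List of gene x (A-1) matrices of raw leave-one-out summaries;
#'   `loo[[j]]` excludes array `j` (names taken from the list names, or from
#'   the missing column when unnamed).
#' @param method_tag Label recorded on the set (default `"external"`).
#' @return A [jackknife_set].
#' @examples
#' jk <- gen_jackknife_fixture(full = cbind(A1 = 8, A2 = 10),
#'                             loo = list(A1 = cbind(A2 = 7.5),
#'                                        A2 = cbind(A1 = 6)))
#' compute_jed(jk)
#' @export
gen_jackknife_fixture <- function(full, loo, method_tag = "external") {
  full <- as.matrix(full)
  arrays <- colnames(full)
  if (is.null(arrays))
    colnames(full) <- arrays <- paste0("A", seq_len(ncol(full)))
  if (is.null(rownames(full)))
    rownames(full) <- paste0("g", seq_len(nrow(full)))
  if (length(loo) != length(arrays))
    stop("`loo` must contain one matrix per array")
  if (is.null(names(loo))) {
    names(loo) <- vapply(loo, function(m) {
      miss <- setdiff(arrays, colnames(as.matrix(m)))
      if (length(miss) != 1L)
        stop("cannot infer the excluded array: each unnamed `loo` matrix must ",
             "omit exactly one array column")
      miss
    }, character(1))
  }
  loo_em <- lapply(names(loo), function(j) {
    m <- as.matrix(loo[[j]])
    if (nrow(m) != nrow(full))
      stop("shape mismatch: loo[['", j, "']] has ", nrow(m),
           " gene(s), full has ", nrow(full))
    if (is.null(colnames(m))) {
      if (ncol(m) != length(arrays) - 1L)
        stop("shape mismatch: loo[['", j, "']] must have ",
             length(arrays) - 1L, " array column(s)")
      colnames(m) <- setdiff(arrays, j)
    }
    rownames(m) <- rownames(full)
    m <- m[, setdiff(arrays, j), drop = FALSE]
    expression_matrix(m, method_tag = method_tag)
  })
  names(loo_em) <- names(loo)
  jackknife_set(expression_matrix(full, method_tag = method_tag),
                loo_em, method_tag = method_tag)
}

#' Fixture with a controlled number of jackknife sign changes
#'
#' Builds a two-array jackknife set in which the target gene's leave-one-out
#' raw summaries flip sign 0, 1 or 2 times relative to the full-data run,
#' while a second "floor-pinning" gene holds every array's smallest positive
#' summary at `floor`.  After the reset rule, one flip drives the affected
#' half of the JED to about 1/2 and two flips drive JED to about 1 (exactly,
#' as `floor / y_full` tends to 0) — the limiting band values that methods
#' with negative raw summaries exhibit.
#'
#' @param floor Small positive array floor (default `1e-6`).
#' @param pattern Number of sign changes for the target gene's array pair:
#'   0, 1 or 2.
#' @param y_full Full-data raw summary of the target gene on both arrays
#'   (default 8).
#' @param y_negative Raw value used for a flipped leave-one-out summary
#'   (default -3; any non-positive value triggers the reset).
#' @return A [jackknife_set] with genes `target` and `floorpin` and arrays
#'   `A1`, `A2`.
#' @examples
#' jed <- compute_jed(gen_sign_change_fixture(pattern = 1))
#' subset(jed, gene == "target" & array_i != array_j)$jed  # ~ 0.5
#' @export
gen_sign_change_fixture <- function(floor = 1e-6, pattern = 1, y_full = 8,
                                    y_negative = -3) {
  if (floor <= 0) stop("`floor` must be positive")
  if (!pattern %in% 0:2) stop("`pattern` must be 0, 1 or 2")
  if (y_full <= 0) stop("`y_full` must be positive")
  if (y_negative > 0) stop("`y_negative` must be non-positive")
  full <- rbind(target = c(y_full, y_full), floorpin = c(floor, floor))
  colnames(full) <- c("A1", "A2")
  # excluding A2 leaves only A1: a flip there is the "first" sign change
  loo_m2 <- rbind(target = if (pattern >= 1) y_negative else y_full,
                  floorpin = floor)
  colnames(loo_m2) <- "A1"
  loo_m1 <- rbind(target = if (pattern == 2) y_negative else y_full,
                  floorpin = floor)
  colnames(loo_m1) <- "A2"
  gen_jackknife_fixture(full, loo = list(A1 = loo_m1, A2 = loo_m2),
                        method_tag = sprintf("signchange(pattern=%d)", pattern))
}
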