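test_that("per-array summaries are plain probe means and strictly local", {
  x <- rbind(p1 = c(2, 10, 7), p2 = c(4, 12, 7))
  pd <- probe_data(x, probeset = c("g1", "g1"), array_ids = c("A1", "A2", "A3"))
  em <- summarize_per_array(pd)
  expect_equal(unname(em$summaries["g1", ]), c(3, 11, 7))

  # removing any other array leaves the remaining summaries bit-identical
  for (drop in pd$array_ids) {
    keep <- setdiff(pd$array_ids, drop)
    expect_identical(summarize_per_array(pd, keep)$summaries,
                     em$summaries[, keep, drop = FALSE])
  }

  # constant input passes through
  pdc <- probe_data(matrix(5, 3, 2), probeset = rep("g1", 3))
  expect_true(all(summarize_per_array(pdc)$summaries == 5))

  expect_error(summarize_per_array(pd, character(0)), "at least 1")
})

test_that("quantile normalization equalizes column distributions", {
  x <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
  q <- quantile_normalize(x)
  # mean-of-order-statistics rule, assigned in rank order
  expect_equal(sort(q[, "a"]), c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(unname(q[, "b"]), c(4.5, 2.5, 3.5))

  # defining property and idempotence on generic data
  set.seed(42)
  y <- matrix(rnorm(60), 20, 3)
  qy <- quantile_normalize(y)
  expect_equal(apply(qy, 2, sort), replicate(3, sort(rowMeans(apply(y, 2, sort)))))
  expect_equal(quantile_normalize(qy), qy)

  # columns already identical as multisets are left alone (up to order)
  z <- cbind(c(1, 3, 2), c(2, 1, 3))
  qz <- quantile_normalize(z)
  expect_equal(sort(qz[, 1]), sort(z[, 1]))
  expect_equal(qz[order(z[, 1]), 1], sort(z[, 1]))

  expect_warning(q1 <- quantile_normalize(matrix(1:3, 3, 1)), "2 arrays")
  expect_equal(q1, matrix(1:3, 3, 1))
  expect_error(quantile_normalize(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("median polish decomposes exactly and shrugs off an outlier", {
  # exactly additive input: zero residuals
  add <- outer(c(0, 1, 4), c(10, 11, 12, 13), "+")
  mp <- median_polish(add)
  expect_equal(max(abs(mp$residuals)), 0)
  recon <- mp$overall + outer(mp$probe_effects, mp$array_effects, "+") +
    mp$residuals
  expect_equal(recon, add, ignore_attr = TRUE)

  # exact reconstruction on generic data too
  set.seed(7)
  r <- matrix(rnorm(20), 5, 4)
  mpr <- median_polish(r)
  expect_equal(mpr$overall + outer(mpr$probe_effects, mpr$array_effects, "+") +
                 mpr$residuals, r, ignore_attr = TRUE, tolerance = 1e-12)

  # 1x1 matrix: overall only
  mp1 <- median_polish(matrix(5, 1, 1))
  expect_equal(mp1$overall, 5)
  expect_equal(unname(mp1$probe_effects), 0)
  expect_equal(unname(mp1$residuals[1, 1]), 0)

  # one outlier cell lands in the residual, not in the effects;
  # checked against an independent hand iteration of row/col median sweeps
  out <- outer(c(0, 1, 2), c(5, 6, 7), "+")
  out[2, 3] <- out[2, 3] + 100
  mpo <- median_polish(out)
  hand <- local({
    z <- out; rr <- numeric(3); cc <- numeric(3); t0 <- 0
    for (k in 1:10) {
      rd <- apply(z, 1, median); z <- z - rd; rr <- rr + rd
      d <- median(cc); cc <- cc - d; t0 <- t0 + d
      cd <- apply(z, 2, median); z <- sweep(z, 2, cd); cc <- cc + cd
      d <- median(rr); rr <- rr - d; t0 <- t0 + d
    }
    list(overall = t0, row = rr, col = cc, res = z)
  })
  expect_equal(unname(mpo$probe_effects), unname(hand$row))
  expect_equal(unname(mpo$array_effects), unname(hand$col))
  expect_equal(mpo$overall, hand$overall)
  expect_gt(abs(mpo$residuals[2, 3]), 99)
  expect_error(median_polish(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("quantile + median polish pipeline shares information across arrays", {
  # identical columns: summaries equal across the two arrays
  x <- matrix(c(1, 2, 3), 3, 2)
  pd <- probe_data(x, probeset = rep("g1", 3))
  em <- summarize_rma_like(pd)
  expect_equal(em$summaries[, 1], em$summaries[, 2])

  # additive noise-free gene: summaries equal array column means up to a
  # shared constant (median polish on additive data is exact)
  pda <- toy_probe_data(genes = 6, probes = 5, arrays = 4, noise_sd = 0)
  ema <- summarize_rma_like(pda)
  xq <- quantile_normalize(pda$intensities)
  for (g in rownames(ema$raw_summaries)) {
    cm <- colMeans(xq[pda$probeset == g, , drop = FALSE])
    expect_lt(diff(range(ema$raw_summaries[g, ] - cm)), 1e-8)
  }

  # generic random input: excluding an array changes some summary
  pdr <- toy_probe_data(genes = 10, probes = 4, arrays = 4)
  full <- summarize_rma_like(pdr)
  sub <- summarize_rma_like(pdr, setdiff(pdr$array_ids, "A4"))
  expect_gt(max(abs(full$summaries[, colnames(sub$summaries)] - sub$summaries)), 0)

  expect_error(summarize_rma_like(pdr, "A1"), "at least 2")
})
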