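test_that("negative and zero summaries are reset to the array floor", {
  em <- expression_matrix(cbind(A1 = c(-2, 0.5, 3), A2 = c(1, 2, 3)))
  expect_equal(unname(em$summaries[, "A1"]), c(0.5, 0.5, 3))
  expect_equal(unname(em$array_floors["A1"]), 0.5)

  # zero is treated like a negative
  em0 <- expression_matrix(cbind(A1 = c(0, 0.5, 3)), included_arrays = "A1")
  expect_equal(unname(em0$summaries[, 1]), c(0.5, 0.5, 3))

  # all-positive columns pass through untouched
  emp <- reset_negative_summaries(cbind(A1 = c(1, 2), A2 = c(3, 4)))
  expect_identical(emp$summaries, emp$raw_summaries)

  # single positive value becomes the floor for the whole column
  em1 <- expression_matrix(cbind(A1 = c(-1, -2, 4)), included_arrays = "A1")
  expect_equal(unname(em1$summaries[, 1]), c(4, 4, 4))

  expect_error(expression_matrix(cbind(A1 = c(-1, 0), A2 = c(1, 2))),
               "no positive raw summary.*A1")
  expect_error(expression_matrix(cbind(A1 = c(1, NA))), "finite")
})

test_that("the jackknife runs A + 1 subsets and per-array methods are inert", {
  pd <- toy_probe_data(genes = 8, probes = 3, arrays = 4)
  jk <- run_jackknife(pd, "perarray")
  expect_length(jk$loo, 4)
  for (j in pd$array_ids) {
    keep <- setdiff(pd$array_ids, j)
    expect_identical(jk$loo[[j]]$included_arrays, keep)
    # strict locality: y_{k(-j)} = y_k exactly
    expect_identical(jk$loo[[j]]$summaries, jk$full$summaries[, keep])
  }

  # A = 2: full plus two leave-one-out runs
  pd2 <- toy_probe_data(genes = 3, probes = 3, arrays = 2)
  jk2 <- run_jackknife(pd2, "perarray")
  expect_length(jk2$loo, 2)

  # cross-array method on generic data does change some summary
  jkr <- run_jackknife(pd, "rmalike")
  changed <- vapply(pd$array_ids, function(j) {
    keep <- setdiff(pd$array_ids, j)
    max(abs(jkr$loo[[j]]$summaries - jkr$full$summaries[, keep]))
  }, numeric(1))
  expect_gt(max(changed), 0)

  # a failing method names the offending subset
  boom <- function(data, arrays) {
    if (length(arrays) < 4) stop("need them all")
    summarize_per_array(data, arrays)
  }
  expect_error(run_jackknife(pd, boom), "subset excluding array A1")
  expect_error(run_jackknife(toy_probe_data(arrays = 2)$intensities, "perarray"))
})

test_that("JED matches the worked percent-change examples and conventions", {
  jk <- gen_jackknife_fixture(full = cbind(A1 = 8, A2 = 10),
                              loo = list(A1 = cbind(A2 = 7.5),
                                         A2 = cbind(A1 = 6)))
  tab <- compute_jed(jk)
  expect_equal(offdiag(tab)$jed, 0.25)            # an average 25% change
  expect_equal(tab$jed[tab$array_i == tab$array_j], c(1, 1))
  expect_equal(tab$distance[tab$array_i == tab$array_j], c(0, 0))
  expect_equal(offdiag(tab)$distance, 0.25)

  # independence: leave-one-out equal to full-data summaries gives JED 0
  jk0 <- gen_jackknife_fixture(full = cbind(A1 = c(8, 2), A2 = c(10, 4)),
                               loo = list(A1 = cbind(A2 = c(10, 4)),
                                          A2 = cbind(A1 = c(8, 2))))
  expect_equal(max(offdiag(compute_jed(jk0))$jed), 0)

  # JED is not capped at 1: a 200% relative change reads as JED 2
  jkbig <- gen_jackknife_fixture(full = cbind(A1 = 1, A2 = 1),
                                 loo = list(A1 = cbind(A2 = 3),
                                            A2 = cbind(A1 = 3)))
  expect_equal(offdiag(compute_jed(jkbig))$jed, 2)
})

test_that("JED is symmetric, non-negative and scale-equivariant", {
  pd <- toy_probe_data(genes = 10, probes = 4, arrays = 4)
  tab <- compute_jed(run_jackknife(pd, "rmalike"))
  expect_true(all(tab$jed >= 0))
  expect_true(all(tab$jed[tab$array_i == tab$array_j] == 1))

  # symmetry: relabeling/reordering the arrays leaves each pair's JED alone
  perm <- c("A3", "A1", "A4", "A2")
  pd_perm <- probe_data(pd$intensities[, perm], probeset = pd$probeset,
                        array_ids = perm)
  tab_perm <- compute_jed(run_jackknife(pd_perm, "rmalike"))
  key <- function(t) paste(t$gene, pmin(t$array_i, t$array_j),
                           pmax(t$array_i, t$array_j))
  m <- match(key(tab), key(tab_perm))
  expect_equal(tab$jed, tab_perm$jed[m], tolerance = 1e-12)

  # scale equivariance: multiplying {y_i, y_i(-j)} by c > 0 and
  # {y_j, y_j(-i)} by d > 0 leaves JED unchanged
  base <- list(yi = 8, yi_mj = 6, yj = 10, yj_mi = 7.5)
  jed_of <- function(v) {
    jk <- gen_jackknife_fixture(full = cbind(A1 = v$yi, A2 = v$yj),
                                loo = list(A1 = cbind(A2 = v$yj_mi),
                                           A2 = cbind(A1 = v$yi_mj)))
    offdiag(compute_jed(jk))$jed
  }
  for (cd in list(c(1, 1), c(3, 1), c(0.2, 7))) {
    scaled <- list(yi = base$yi * cd[1], yi_mj = base$yi_mj * cd[1],
                   yj = base$yj * cd[2], yj_mi = base$yj_mi * cd[2])
    expect_equal(jed_of(scaled), jed_of(base), tolerance = 1e-12)
  }
})

test_that("sign changes are counted per pair and drive the JED bands", {
  # one flip: raw y_i = 5 -> -1 under exclusion of j, j's summary unmoved
  jk1 <- gen_jackknife_fixture(
    full = cbind(A1 = c(5, 0.01), A2 = c(4, 0.01)),
    loo = list(A1 = cbind(A2 = c(4, 0.01)), A2 = cbind(A1 = c(-1, 0.01))))
  sc <- count_sign_changes(jk1)
  expect_equal(sc$sign_changes[sc$gene == "g1" &
                                 sc$array_i == "A1" & sc$array_j == "A2"], 1L)

  # two flips and zero flips
  expect_equal(offdiag(compute_jed(gen_sign_change_fixture(pattern = 2)))$sign_changes[1], 2L)
  expect_equal(offdiag(compute_jed(gen_sign_change_fixture(pattern = 0)))$sign_changes[1], 0L)

  # vanishing floor: one flip drives the affected half-term to 1/2, two to 1
  t1 <- offdiag(compute_jed(gen_sign_change_fixture(floor = 1e-6, pattern = 1)))
  expect_equal(t1$jed[t1$gene == "target"], 0.5, tolerance = 1e-3)
  t2 <- offdiag(compute_jed(gen_sign_change_fixture(floor = 1e-6, pattern = 2)))
  expect_equal(t2$jed[t2$gene == "target"], 1, tolerance = 1e-3)
})

test_that("JED summaries respect diagonal suppression and stratification", {
  jk0 <- gen_jackknife_fixture(full = cbind(A1 = c(8, 2), A2 = c(10, 4), A3 = c(9, 3)),
                               loo = list(A1 = cbind(A2 = c(10, 4), A3 = c(9, 3)),
                                          A2 = cbind(A1 = c(8, 2), A3 = c(9, 3)),
                                          A3 = cbind(A1 = c(8, 2), A2 = c(10, 4))))
  tab <- compute_jed(jk0)
  s <- summarize_jed(tab, suppress_diagonal = TRUE)
  expect_equal(s$max, 0)        # diagonal 1s do not leak into the max
  expect_equal(s$mean, 0)
  s2 <- summarize_jed(tab, suppress_diagonal = FALSE)
  expect_equal(s2$max, 1)

  # stratified summary: the one-sign-change stratum bands near 0.5
  tgt <- compute_jed(gen_sign_change_fixture(pattern = 1))
  strat <- summarize_jed(tgt, by_sign_changes = TRUE)
  one <- strat[strat$stratum == "sign_changes=1", ]
  expect_equal(one$median, 0.5, tolerance = 1e-3)

  expect_error(summarize_jed(tab[tab$array_i == tab$array_j, ]),
               "no JED entries")
})
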