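test_that("network generation is deterministic and honours planting", {
  a <- simulate_network(n_mirna = 20, n_mrna = 60, mean_targets = 6,
                        n_planted = 2, planted_excess_singles = 5, seed = 3)
  b <- simulate_network(n_mirna = 20, n_mrna = 60, mean_targets = 6,
                        n_planted = 2, planted_excess_singles = 5, seed = 3)
  expect_identical(a$network, b$network)
  expect_identical(a$truth, b$truth)

  # planting correctness against the brute-force NSR oracle
  nsr <- bf_nsr(a$network)
  for (m in a$truth$planted_biomarkers) expect_gte(nsr[[m]], 5)

  # planted biomarkers are a subset of planted DE miRNAs, and each has a
  # resistance-annotated dedicated single target
  expect_true(all(a$truth$planted_biomarkers %in% names(a$truth$planted_de_mirnas)))
  for (m in a$truth$planted_biomarkers) {
    targets <- a$network$mrna[a$network$mirna == m]
    singles <- targets[vapply(targets, function(g) sum(a$network$mrna == g) == 1L,
                              logical(1))]
    expect_gte(length(intersect(singles, a$truth$resistance_genes)), 1)
  }
})

test_that("network generator validates infeasible parameters", {
  expect_error(simulate_network(n_mirna = 5, n_planted = 6, seed = 1),
               class = "mirvuln_parameter_error")
  expect_error(
    simulate_network(n_mirna = 5, n_mrna = 10, n_planted = 2,
                     planted_excess_singles = 6, seed = 1),
    class = "mirvuln_parameter_error"
  )
})

test_that("zero planting leaves no dedicated single-line blocks or biomarkers", {
  z <- simulate_network(n_mirna = 20, n_mrna = 60, mean_targets = 6,
                        n_planted = 0, seed = 5)
  expect_length(z$truth$planted_biomarkers, 0)
  expect_length(z$truth$hazard_coefficients, 0)
  expect_gt(length(z$truth$resistance_genes), 0) # decoys remain
})

test_that("expression generator matches group design and the noise-free limit", {
  net <- simulate_network(n_mirna = 10, n_mrna = 30, mean_targets = 4,
                          n_planted = 2, planted_excess_singles = 3,
                          effect_log2fc = 1, seed = 7)
  ex <- simulate_expression(net$network, net$truth, n_sensitive = 31,
                            n_resistant = 37, sigma = 0.5, seed = 7)
  expect_equal(ncol(ex$mirna_expr) - 1L, 68L)
  expect_equal(table(ex$groups$group)[["sensitive"]], 31)
  expect_equal(table(ex$groups$group)[["resistant"]], 37)

  # near-zero noise: empirical group-mean difference converges to the
  # planted log2FC for planted features and to 0 for the rest
  ex0 <- simulate_expression(net$network, net$truth, n_sensitive = 10,
                             n_resistant = 10, sigma = 1e-9, seed = 7)
  x <- as.matrix(ex0$mirna_expr[, -1])
  rownames(x) <- ex0$mirna_expr$feature_id
  res <- ex0$groups$group == "resistant"
  diff <- rowMeans(x[, res]) - rowMeans(x[, !res])
  m <- net$truth$planted_biomarkers[1]
  expect_equal(unname(diff[m]), 1, tolerance = 1e-6)
  unplanted <- setdiff(rownames(x), names(net$truth$planted_de_mirnas))
  expect_lt(max(abs(diff[unplanted])), 1e-6)

  expect_error(simulate_expression(net$network, net$truth, n_sensitive = 1,
                                   n_resistant = 5, seed = 1),
               class = "mirvuln_parameter_error")
  expect_error(simulate_expression(net$network, net$truth, sigma = 0, seed = 1),
               class = "mirvuln_parameter_error")
})

test_that("clinical generator: censoring switch, PFS <= OS, hazard direction", {
  net <- simulate_network(n_mirna = 10, n_mrna = 30, mean_targets = 4,
                          n_planted = 1, planted_excess_singles = 3,
                          hazard_coefficient = 1.5, seed = 2)
  ex <- simulate_expression(net$network, net$truth, n_sensitive = 20,
                            n_resistant = 20, sigma = 0.5, seed = 2)

  cl0 <- simulate_clinical(ex$mirna_expr, net$truth, censor_rate = 0, seed = 9)
  expect_true(all(cl0$pfs_event == 1))
  expect_true(all(cl0$os_event == 1))
  expect_true(all(cl0$pfs_time <= cl0$os_time))

  # positive hazard coefficient: the biomarker-high half has shorter event
  # times in most replicates
  m <- net$truth$planted_biomarkers[1]
  v <- as.numeric(ex$mirna_expr[ex$mirna_expr$feature_id == m, -1])
  names(v) <- names(ex$mirna_expr)[-1]
  hi <- v > quantile(v, 0.75)
  shorter <- vapply(1:40, function(s) {
    cl <- simulate_clinical(ex$mirna_expr, net$truth, censor_rate = 0, seed = 100 + s)
    median(cl$os_time[hi]) < median(cl$os_time[!hi])
  }, logical(1))
  expect_gte(mean(shorter), 0.9)
})

test_that("null hazard gives calibrated log-rank p-values over replicates", {
  net <- simulate_network(n_mirna = 10, n_mrna = 30, mean_targets = 4,
                          n_planted = 0, seed = 4)
  ex <- simulate_expression(net$network, net$truth, n_sensitive = 31,
                            n_resistant = 37, sigma = 0.5, seed = 4)
  v <- as.numeric(ex$mirna_expr[1, -1])
  names(v) <- names(ex$mirna_expr)[-1]
  ps <- vapply(1:100, function(s) {
    cl <- simulate_clinical(ex$mirna_expr, net$truth, censor_rate = 0.2,
                            seed = 500 + s)
    km_logrank(v, cl, endpoint = "pfs")$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.12)
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.85)
})

test_that("simulate_study writes a complete, re-readable input bundle", {
  dir <- withr::local_tempdir()
  st <- simulate_study(seed = 13, dir = dir)
  expect_identical(read_expression(st$files$mirna_expr)$feature_id,
                   st$mirna_expr$feature_id)
  expect_identical(read_network(st$files$network), st$network)
  expect_equal(read_clinical(st$files$clinical), st$clinical)
  expect_identical(readLines(st$files$resistance_genes), st$resistance_genes)

  st2 <- simulate_study(seed = 13)
  expect_identical(st2$network, st$network)
  expect_equal(st2$mirna_expr, st$mirna_expr)
})
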