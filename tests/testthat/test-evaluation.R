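test_that("AUC reproduces pair-enumeration examples and tie conventions", {
  labels <- c("sensitive", "sensitive", "resistant", "resistant")
  expect_equal(roc_auc(c(1, 2, 3, 4), labels)$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), labels)$auc, 0.75)
  expect_equal(roc_auc(c(5, 5, 5, 5), labels)$auc, 0.5)
  expect_error(roc_auc(1:3, rep("resistant", 3)),
               class = "mirvuln_degenerate_error")
})

test_that("ROC curve is a valid staircase whose trapezoid area equals the AUC", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # induce ties sometimes
    labels <- sample(c("sensitive", "resistant"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    roc <- roc_auc(scores, labels)
    curve <- tidy(roc)
    expect_equal(curve$fpr[1], 0)
    expect_equal(curve$tpr[1], 0)
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_equal(curve$tpr[nrow(curve)], 1)
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
    trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
    expect_equal(trap, roc$auc, tolerance = 1e-12)

    # invariants: complement and strictly monotone transforms
    expect_equal(roc_auc(-scores, labels)$auc, 1 - roc$auc, tolerance = 1e-12)
    expect_equal(roc_auc(exp(scores), labels)$auc, roc$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  scores <- rnorm(40)
  labels <- sample(c("sensitive", "resistant"), 40, replace = TRUE)
  auc <- roc_auc(scores, labels)$auc
  ref <- pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("sensitive", "resistant"), direction = "<", quiet = TRUE
  ))
  expect_equal(auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("log-rank chi-square matches the hand-computed event table on a 12-subject fixture", {
  clin <- tibble::tibble(
    sample_id = sprintf("p%02d", 1:12),
    pfs_time = c(2, 4, 5, 7, 9, 12, 3, 6, 8, 10, 11, 14),
    pfs_event = c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1),
    os_time = c(4, 6, 8, 10, 12, 15, 5, 8, 11, 13, 15, 18),
    os_event = c(1, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 1)
  )
  # expression crafted so the upper-quartile split is 3 high vs 9 low
  v <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 20, 21, 22), clin$sample_id)
  km <- km_logrank(v, clin, endpoint = "pfs")
  grp <- ifelse(v > quantile(v, 0.75), "high", "low")
  expect_equal(km$logrank_chi2,
               bf_logrank(clin$pfs_time, clin$pfs_event, grp),
               tolerance = 1e-10)
  expect_equal(km$p, pchisq(km$logrank_chi2, 1, lower.tail = FALSE))
  expect_equal(km$n_high, 3)
  expect_equal(km$n_low, 9)

  # relabeling invariance: flipping which group is 'high' leaves p unchanged
  km2 <- km_logrank(-v, clin, endpoint = "pfs", quartile = 0.25)
  expect_equal(km2$p, km$p, tolerance = 1e-10)
})

test_that("KM estimate without censoring equals the empirical survival function", {
  clin <- tibble::tibble(
    sample_id = sprintf("p%02d", 1:10),
    pfs_time = c(1, 2, 2, 3, 5, 1.5, 2.5, 4, 6, 7),
    pfs_event = 1,
    os_time = c(1, 2, 2, 3, 5, 1.5, 2.5, 4, 6, 7),
    os_event = 1
  )
  v <- setNames(c(rep(0, 5), rep(10, 5)), clin$sample_id)
  km <- km_logrank(v, clin, endpoint = "os", quartile = 0.4)
  for (g in c("high", "low")) {
    ids <- if (g == "high") v > quantile(v, 0.4) else v <= quantile(v, 0.4)
    times <- clin$os_time[ids]
    cur <- dplyr::filter(tidy(km), group == g, time > 0)
    emp <- vapply(cur$time, function(t) mean(times > t), numeric(1))
    expect_equal(cur$survival, emp, tolerance = 1e-12)
  }

  # identical data in both groups: chi2 = 0, p = 1
  clin2 <- dplyr::bind_rows(clin, dplyr::mutate(clin, sample_id = paste0(sample_id, "b")))
  v2 <- setNames(rep(c(0, 10), each = 10), clin2$sample_id)
  km2 <- km_logrank(v2, clin2, endpoint = "os", quartile = 0.5)
  expect_equal(km2$logrank_chi2, 0, tolerance = 1e-10)
  expect_equal(km2$p, 1, tolerance = 1e-10)
})

test_that("degenerate survival splits raise informative errors", {
  clin <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    pfs_time = c(1, 2, 3, 4), pfs_event = c(1, 1, 1, 1),
    os_time = c(1, 2, 3, 4), os_event = c(0, 0, 0, 0)
  )
  v <- setNames(rep(1, 4), clin$sample_id) # all tied -> empty high group
  expect_error(km_logrank(v, clin, endpoint = "pfs"),
               class = "mirvuln_degenerate_error")
  v2 <- setNames(1:4, clin$sample_id)
  expect_error(km_logrank(v2, clin, endpoint = "os"),
               class = "mirvuln_degenerate_error") # no events
})

test_that("evaluate_biomarkers assembles AUC and survival p per biomarker", {
  st <- simulate_study(seed = 63)
  planted <- st$truth$planted_biomarkers
  ev <- evaluate_biomarkers(st$mirna_expr, st$groups, st$clinical, planted)
  expect_identical(ev$mirna, planted)
  expect_true(all(ev$auc > 0.5)) # planted biomarkers are up in resistant
  expect_true(all(is.finite(ev$logrank_p_pfs)))
  expect_true(all(is.finite(ev$logrank_p_os)))
  # positive hazard coefficients: survival separation should be strong
  expect_lt(median(ev$logrank_p_os), 0.01)

  empty <- evaluate_biomarkers(st$mirna_expr, st$groups, st$clinical, character(0))
  expect_equal(nrow(empty), 0)
})
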