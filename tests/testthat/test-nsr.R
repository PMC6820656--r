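test_that("NSR matches brute-force in-degree counting on 100 random toy networks", {
  set.seed(51)
  for (i in 1:100) {
    net <- random_toy_network(n_mirna = sample(2:6, 1), n_mrna = sample(3:12, 1),
                              n_edges = sample(4:18, 1))
    nsr <- compute_nsr(net)
    oracle <- bf_nsr(net)
    expect_equal(setNames(nsr$nsr, nsr$mirna), oracle[nsr$mirna])
    # each single-line mRNA is counted exactly once across miRNAs
    expect_equal(sum(nsr$nsr), sum(table(net$mrna) == 1))
  }
})

test_that("NSR toy examples match direct reasoning", {
  toy <- tibble::tibble(mirna = c("m1", "m1", "m2", "m2"),
                        mrna = c("a", "b", "b", "c"))
  nsr <- compute_nsr(toy)
  expect_equal(nsr$nsr[nsr$mirna == "m1"], 1L) # a
  expect_equal(nsr$nsr[nsr$mirna == "m2"], 1L) # c

  # every mRNA regulated by >= 2 miRNAs -> all NSR zero
  shared <- tibble::tibble(mirna = rep(c("m1", "m2"), each = 2),
                           mrna = rep(c("a", "b"), 2))
  expect_true(all(compute_nsr(shared)$nsr == 0))
})

test_that("rewiring permutations preserve both degree sequences exactly", {
  set.seed(52)
  net <- simulate_network(n_mirna = 15, n_mrna = 50, mean_targets = 5,
                          n_planted = 1, planted_excess_singles = 4,
                          seed = 52)$network
  mi_lev <- unique(net$mirna)
  mr_lev <- unique(net$mrna)
  res <- mirvuln:::rewire_nsr_null_cpp(
    match(net$mirna, mi_lev) - 1L, match(net$mrna, mr_lev) - 1L,
    length(mi_lev), length(mr_lev), n_perm = 5L, swaps_per_edge = 10L
  )
  # out-degrees fixed => each miRNA's NSR can never exceed its degree, and
  # total single count is invariant under degree-preserving rewiring
  deg <- as.integer(table(factor(net$mirna, levels = mi_lev)))
  singles <- sum(table(net$mrna) == 1)
  for (p in 1:5) {
    expect_true(all(res$nsr[p, ] <= deg))
    expect_equal(sum(res$nsr[p, ]), singles)
  }
})

test_that("small-network significance equals exhaustive matching enumeration", {
  toy <- tibble::tibble(mirna = c("m1", "m1", "m2"),
                        mrna = c("a", "b", "c"))
  expect_warning(sig <- nsr_significance(toy, n_perm = 1000, seed = 1),
                 "exact")
  oracle <- bf_exact_nsr_p(toy)
  expect_equal(setNames(sig$p_nsr, sig$mirna), oracle[sig$mirna],
               tolerance = 1e-12)

  toy2 <- tibble::tibble(mirna = c("m1", "m1", "m2", "m3", "m3"),
                         mrna = c("a", "b", "b", "c", "d"))
  expect_warning(sig2 <- nsr_significance(toy2, seed = 1), "exact")
  oracle2 <- bf_exact_nsr_p(toy2)
  expect_equal(setNames(sig2$p_nsr, sig2$mirna), oracle2[sig2$mirna],
               tolerance = 1e-12)
})

test_that("a miRNA with zero NSR has permutation p-value 1", {
  net <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m2", "m3", "m3", "m4", "m4", "m5", "m5", "m5"),
    mrna = c("a", "b", "a", "b", "c", "d", "c", "d", "e", "f", "g")
  )
  sig <- nsr_significance(net, n_perm = 200, seed = 3)
  zero <- compute_nsr(net)
  for (m in zero$mirna[zero$nsr == 0]) {
    expect_equal(sig$p_nsr[sig$mirna == m], 1)
  }
})

test_that("a planted biomarker is significant under the rewiring null", {
  st <- simulate_study(seed = 53)
  de_mi <- filter_de(moderated_t(st$mirna_expr, st$groups))
  de_mr <- filter_de(moderated_t(st$mrna_expr, st$groups))
  sub <- extract_subnetwork(st$network, de_mi, de_mr)
  sig <- nsr_significance(sub, n_perm = 1000, seed = 53)
  planted <- intersect(st$truth$planted_biomarkers, sig$mirna)
  expect_gte(length(planted), 3)
  expect_lt(median(sig$p_nsr[sig$mirna %in% planted]), 0.01)
})

test_that("rank-based significance variant runs and orders sensibly", {
  st <- simulate_study(seed = 54)
  sig <- nsr_significance(st$network, method = "rank")
  expect_true(all(sig$p_nsr >= 0 & sig$p_nsr <= 1))
  planted <- st$truth$planted_biomarkers
  expect_lt(median(sig$p_nsr[sig$mirna %in% planted]),
            median(sig$p_nsr[!sig$mirna %in% planted]))
})

test_that("rank-sum comparison reproduces closed-form and degenerate cases", {
  # complete separation, 4 vs 4: one ordering of C(8,4) = 70
  res <- compare_nsr_groups(c(11, 12, 13, 14), c(1, 2, 3, 4))
  expect_equal(res$p, 1 / 70, tolerance = 1e-12)
  expect_match(res$method, "exact")

  # all values tied: every relabelling attains the statistic, p = 1
  res2 <- compare_nsr_groups(c(2, 2, 2), c(2, 2))
  expect_equal(res2$p, 1)

  # agreement with the exact oracle on a tie-free example
  a <- c(33, 24, 5.5, 4.5)
  b <- c(1, 2, 3, 6, 7, 8, 9, 10)
  res3 <- compare_nsr_groups(a, b)
  expect_equal(res3$p,
               wilcox.test(a, b, alternative = "greater", exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("NPRG counts resistance-annotated targets and selection is monotone in it", {
  toy <- tibble::tibble(mirna = c("m1", "m1", "m2"),
                        mrna = c("a", "b", "c"))
  expect_equal(count_nprg(toy, c("b"))$nprg, c(1L, 0L))
  expect_equal(count_nprg(toy, c("x", "y"))$nprg, c(0L, 0L))

  set.seed(55)
  for (i in 1:10) {
    net <- random_toy_network(n_mirna = 4, n_mrna = 8, n_edges = 12)
    genes <- sample(unique(net$mrna), 2)
    rec <- compute_nsr(net) |>
      dplyr::mutate(p_nsr = runif(dplyr::n())) |>
      dplyr::left_join(count_nprg(net, genes), by = "mirna")
    sel1 <- select_biomarkers(rec)
    extra <- sample(setdiff(unique(net$mrna), genes), 1)
    rec2 <- dplyr::select(rec, -"nprg") |>
      dplyr::left_join(count_nprg(net, c(genes, extra)), by = "mirna")
    sel2 <- select_biomarkers(rec2)
    expect_true(all(sel1$mirna[sel1$selected] %in% sel2$mirna[sel2$selected]))
  }
})

test_that("biomarker selection applies strict cutoffs and deterministic ordering", {
  rec <- tibble::tibble(
    mirna = c("mB", "mA", "mC", "mD"),
    nsr = c(5L, 5L, 9L, 2L),
    p_nsr = c(0.001, 0.001, 0.01, 0.5),
    nprg = c(1L, 2L, 3L, 1L)
  )
  sel <- select_biomarkers(rec, nsr_alpha = 0.01)
  # sorted by NSR descending, ties lexicographic
  expect_identical(sel$mirna, c("mC", "mA", "mB", "mD"))
  # p_nsr exactly at alpha is not selected (strict)
  expect_identical(sel$mirna[sel$selected], c("mA", "mB"))
})
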