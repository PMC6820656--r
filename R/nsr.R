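#' Number of single-line regulations (NSR) per miRNA
#'
#' A target mRNA is *single-line regulated* when exactly one miRNA in the
#' analyzed network regulates it; such edges are the network's vulnerable
#' structure, and a miRNA monopolising many of them has strong independent
#' regulatory ability.  `compute_nsr()` counts, for each miRNA, its targets
#' whose in-degree is exactly 1.
#'
#' @param edges Edge tibble (`mirna`, `mrna`), non-empty.
#' @return A tibble with columns `mirna`, `degree`, `nsr`, one row per miRNA
#'   in first-appearance order.
#' @export
compute_nsr <- function(edges) {
  edges <- validate_network(edges)
  if (nrow(edges) == 0) stop_degenerate("network is empty.")
  indeg <- dplyr::count(edges, .data$mrna, name = "in_degree")
  singles <- indeg$mrna[indeg$in_degree == 1L]
  edges |>
    dplyr::group_by(mirna = factor(.data$mirna, levels = unique(.data$mirna))) |>
    dplyr::summarise(
      degree = dplyr::n(),
      nsr = sum(.data$mrna %in% singles),
      .groups = "drop"
    ) |>
    dplyr::mutate(mirna = as.character(.data$mirna),
                  degree = as.integer(.data$degree),
                  nsr = as.integer(.data$nsr))
}

#' Permutation significance of per-miRNA NSR values
#'
#' Default method `"rewire"` builds a degree-preserving null: the edge list
#' is randomized by double-edge swaps that keep every miRNA out-degree and
#' every mRNA in-degree fixed, NSR is recomputed on each permuted network,
#' and the one-sided p-value with add-one smoothing is
#' `(1 + #\{NSR_perm >= NSR_obs\}) / (1 + n_perm)`.  For networks with at most
#' 10 edges the permutation null is replaced by exact enumeration over all
#' degree-preserving edge matchings (p = exact tail probability, no
#' smoothing needed: the observed network is itself a matching, so p > 0).
#'
#' Method `"rank"` is a rank-based alternative kept for fidelity to the
#' signed-rank test named in the original method description: each miRNA's
#' per-target single-line indicators are compared one-sidedly against the
#' network-wide single-line rate with a Wilcoxon signed-rank test.  Its null
#' ignores the degree structure; the rewiring null is the recommended
#' default.
#'
#' @param edges Edge tibble (`mirna`, `mrna`), non-empty.
#' @param method `"rewire"` (default) or `"rank"`.
#' @param n_perm Number of permutations (>= 100) for `"rewire"`.
#' @param seed Integer seed or `NULL` (current RNG stream).
#' @param swaps_per_edge Accepted swaps per edge per permutation (mixing
#'   depth; default 10).
#' @return A tibble `mirna`, `nsr`, `p_nsr`, `method`.
#' @export
nsr_significance <- function(edges, method = c("rewire", "rank"),
                             n_perm = 1000L, seed = NULL,
                             swaps_per_edge = 10L) {
  edges <- validate_network(edges)
  if (nrow(edges) == 0) stop_degenerate("network is empty.")
  method <- match.arg(method)
  obs <- compute_nsr(edges)

  if (method == "rank") {
    indeg <- dplyr::count(edges, .data$mrna, name = "in_degree")
    singles <- indeg$mrna[indeg$in_degree == 1L]
    rate <- length(singles) / nrow(indeg)
    p <- vapply(obs$mirna, function(m) {
      ind <- as.numeric(edges$mrna[edges$mirna == m] %in% singles)
      if (all(ind == rate)) return(1)
      suppressWarnings(
        wilcox.test(ind, mu = rate, alternative = "greater",
                    exact = FALSE, correct = TRUE)$p.value
      )
    }, numeric(1))
    return(tibble::tibble(mirna = obs$mirna, nsr = obs$nsr,
                          p_nsr = unname(p), method = "rank"))
  }

  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  mirna_levels <- obs$mirna
  mrna_levels <- unique(edges$mrna)
  mi <- match(edges$mirna, mirna_levels) - 1L
  gi <- match(edges$mrna, mrna_levels) - 1L
  nsr_obs <- obs$nsr[match(mirna_levels, obs$mirna)]

  if (nrow(edges) <= 10L) {
    warn("<= 10 edges: permutation null replaced by exact enumeration.")
    res <- exact_nsr_null_cpp(mi, gi, length(mirna_levels),
                              length(mrna_levels), as.integer(nsr_obs))
    p <- res$ge / res$total
    return(tibble::tibble(mirna = mirna_levels, nsr = as.integer(nsr_obs),
                          p_nsr = p, method = "exact"))
  }

  res <- with_seed(seed, {
    rewire_nsr_null_cpp(mi, gi, length(mirna_levels), length(mrna_levels),
                        n_perm, check_count(swaps_per_edge, "swaps_per_edge",
                                            min = 1L))
  })
  if (!res$mixed) {
    warn("rewiring did not reach its swap quota; the network may be too rigid to mix.")
  }
  exceed <- colSums(sweep(res$nsr, 2, nsr_obs, `>=`))
  p <- (1 + exceed) / (1 + n_perm)
  tibble::tibble(mirna = mirna_levels, nsr = as.integer(nsr_obs),
                 p_nsr = unname(p), method = "rewire")
}

#' One-sided rank-sum comparison of two NSR distributions
#'
#' Tests whether `group_a`'s NSR values are stochastically greater than
#' `group_b`'s (Mann-Whitney / Wilcoxon rank-sum).  The exact distribution is
#' used when `n_a * n_b <= 10000` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.  When every
#' value in both groups is identical, every relabelling attains the same
#' statistic, so the exact one-sided tail probability is 1.
#'
#' @param group_a,group_b Numeric vectors of NSR values (non-empty).
#' @return A one-row tibble: `n_a`, `n_b`, `statistic` (Mann-Whitney U for
#'   group_a), `p`, `method`.
#' @export
compare_nsr_groups <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_parameter("both groups must be non-empty.")
  }
  if (length(unique(c(group_a, group_b))) == 1L) {
    return(tibble::tibble(
      n_a = length(group_a), n_b = length(group_b),
      statistic = length(group_a) * length(group_b) / 2,
      p = 1, method = "degenerate (all values tied)"
    ))
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) * length(group_b) <= 10000
  res <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "greater", exact = exact,
                correct = TRUE)
  )
  tibble::tibble(
    n_a = length(group_a), n_b = length(group_b),
    statistic = unname(res$statistic), p = res$p.value,
    method = if (exact) "exact rank-sum" else "normal approximation"
  )
}

#' Count resistance-annotated targets (NPRG) per miRNA
#'
#' NPRG is the number of a miRNA's targets, within the analyzed network,
#' that appear in the supplied list of chemoresistance-associated genes — the
#' knowledge-guided filter of the biomarker selection.
#'
#' @param edges Edge tibble (`mirna`, `mrna`).
#' @param resistance_genes Character vector of gene IDs, or a gene-set tibble
#'   with a `gene` column; must be non-empty.
#' @return A tibble `mirna`, `nprg` in first-appearance order.
#' @export
count_nprg <- function(edges, resistance_genes) {
  edges <- validate_network(edges)
  genes <- as_gene_list(resistance_genes)
  if (length(genes) == 0) stop_parameter("`resistance_genes` must be non-empty.")
  edges |>
    dplyr::group_by(mirna = factor(.data$mirna, levels = unique(.data$mirna))) |>
    dplyr::summarise(nprg = as.integer(sum(unique(.data$mrna) %in% genes)),
                     .groups = "drop") |>
    dplyr::mutate(mirna = as.character(.data$mirna))
}

#' Assemble per-miRNA NSR records for a network
#'
#' Convenience wrapper joining [compute_nsr()], [nsr_significance()] and
#' [count_nprg()] into one record table.
#'
#' @inheritParams nsr_significance
#' @inheritParams count_nprg
#' @param nsr_alpha Significance cutoff handed to [select_biomarkers()].
#' @return The selected/sorted record tibble from [select_biomarkers()].
#' @export
nsr_records <- function(edges, resistance_genes, method = "rewire",
                        n_perm = 1000L, seed = NULL, nsr_alpha = 0.01) {
  records <- compute_nsr(edges) |>
    dplyr::left_join(
      nsr_significance(edges, method = method, n_perm = n_perm, seed = seed) |>
        dplyr::select("mirna", "p_nsr", "method"),
      by = "mirna"
    ) |>
    dplyr::left_join(count_nprg(edges, resistance_genes), by = "mirna")
  select_biomarkers(records, nsr_alpha = nsr_alpha)
}

#' Select biomarkers from NSR records
#'
#' A miRNA is selected iff its NSR is significantly high (`p_nsr <
#' nsr_alpha`, strict) AND it regulates at least one resistance-annotated
#' gene (`nprg >= 1`).  Output is sorted by NSR descending, ties broken
#' lexicographically by miRNA ID.
#'
#' @param records Tibble with columns `mirna`, `nsr`, `p_nsr`, `nprg` (extra
#'   columns pass through).
#' @param nsr_alpha Significance cutoff (default 0.01).
#' @return The records tibble with a logical `selected` column, sorted.
#' @export
select_biomarkers <- function(records, nsr_alpha = 0.01) {
  need <- c("mirna", "nsr", "p_nsr", "nprg")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_parameter(sprintf("`records` must have columns %s.",
                           paste(need, collapse = ", ")))
  }
  check_scalar_prob(nsr_alpha, "nsr_alpha")
  records |>
    dplyr::mutate(selected = .data$p_nsr < nsr_alpha & .data$nprg >= 1L) |>
    dplyr::arrange(dplyr::desc(.data$nsr), .data$mirna)
}

#' Boxplot comparing NSR distributions across miRNA groups
#'
#' The classic diagnostic: NSR of the selected biomarkers vs all miRNAs of
#' the condition-specific subnetwork vs all miRNAs of the reference network.
#'
#' @param ... Named numeric vectors of NSR values (one box per argument).
#' @return A ggplot object.
#' @export
plot_nsr_comparison <- function(...) {
  groups <- list(...)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop_parameter("all NSR groups must be named.")
  }
  df <- purrr::imap_dfr(groups, function(v, nm) {
    tibble::tibble(group = nm, nsr = as.numeric(v))
  })
  df$group <- factor(df$group, levels = names(groups))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$nsr)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "NSR (single-line regulations)") +
    ggplot2::theme_minimal()
}
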