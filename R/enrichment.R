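#' Over-representation analysis of a gene list against gene-set collections
#'
#' For each gene set, the overlap `k` between the query and the set (both
#' intersected with the universe) is tested with the hypergeometric
#' upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`,
#' where `N` is the universe size, `K` the set size in the universe and `n`
#' the query size in the universe.  Fold enrichment is `(k/n) / (K/N)`.
#' P-values are BH-adjusted across all tested sets; a set is flagged
#' significant when `adj_p < alpha` and `fold_enrichment > fold_cut` (both
#' strict).  Sets with zero overlap are omitted.
#'
#' @param query Character vector of gene IDs; genes outside the universe are
#'   dropped (with a message stating how many).
#' @param gene_sets Long gene-set tibble (`set_id`, `description`, `gene`).
#' @param universe Character vector of background gene IDs; a self-consistent
#'   default is all mRNAs of the reference regulatory network.
#' @param alpha,fold_cut Significance cutoffs (defaults 0.05 and 1.5).
#' @return A tibble `set_id`, `description`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p`, `adj_p`, `significant`, sorted by `adj_p` then
#'   `set_id`.
#' @export
ora <- function(query, gene_sets, universe, alpha = 0.05, fold_cut = 1.5) {
  gene_sets <- validate_gene_sets(gene_sets)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_parameter("`universe` must be non-empty.")
  check_scalar_prob(alpha, "alpha")

  query <- unique(as.character(query))
  eff <- intersect(query, universe)
  dropped <- length(query) - length(eff)
  if (dropped > 0) {
    inform(sprintf("%d query gene(s) outside the universe dropped.", dropped))
  }
  if (length(eff) == 0) stop_degenerate("no query genes left after intersecting with the universe.")

  N <- length(universe)
  n <- length(eff)
  res <- gene_sets |>
    dplyr::group_by(.data$set_id, .data$description) |>
    dplyr::summarise(
      K = sum(unique(.data$gene) %in% universe),
      k = sum(unique(.data$gene) %in% eff),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k >= 1L) |>
    dplyr::mutate(
      n = n, N = N,
      fold_enrichment = (.data$k / n) / (.data$K / N),
      p = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE)
    )
  if (nrow(res) == 0) {
    return(tibble::tibble(
      set_id = character(), description = character(),
      k = integer(), K = integer(), n = integer(), N = integer(),
      fold_enrichment = numeric(), p = numeric(), adj_p = numeric(),
      significant = logical()
    ))
  }
  res |>
    dplyr::mutate(
      adj_p = bh_adjust(.data$p),
      significant = .data$adj_p < alpha & .data$fold_enrichment > fold_cut
    ) |>
    dplyr::arrange(.data$adj_p, .data$set_id)
}
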