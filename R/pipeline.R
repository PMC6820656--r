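#' Run the full biomarker-discovery pipeline
#'
#' Executes the stages in order — differential expression of miRNAs and
#' mRNAs, extraction of the condition-specific subnetwork, topology and
#' power-law analysis, NSR statistics with the degree-preserving permutation
#' null, the resistance-gene (NPRG) filter, biomarker selection,
#' distribution-level NSR comparisons, and ROC/survival evaluation — and
#' returns a structured report.  With `inputs = NULL` the study is simulated
#' from `config$simulation` first, and the report additionally scores
#' recovery of the planted biomarkers.
#'
#' All randomness (simulation and permutation null) flows from a single RNG
#' stream seeded with `seed`; a rerun with the same config and seed is
#' identical.
#'
#' @param config A `run_config` list (see [default_run_config()]).
#' @param inputs Optional list with elements `mirna_expr`, `mrna_expr`,
#'   `groups`, `network`, `resistance_genes`, and optionally `clinical`,
#'   `gene_sets`, `truth`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param output_dir Optional directory: every stage table is written as TSV
#'   and the report as JSON.
#' @return An object of class `biomarker_report` (a named list; see Details).
#'
#' @details The report carries: `config`, `seed`, `de` (per-assay feature
#' counts and DE counts), `subnetwork` (edge/node counts, power-law fit,
#' hub/bottleneck miRNAs), `nsr` (the full record table), `selected`
#' (biomarker IDs), `nsr_comparison` (selected vs subnetwork and selected vs
#' reference rank-sum p), `evaluation` (AUC and log-rank p per biomarker),
#' and — for simulated inputs — `recovery` (recall, false selections).
#' @export
run_biomarker_pipeline <- function(config = default_run_config(),
                                   inputs = NULL, seed = config$seed,
                                   output_dir = NULL) {
  config <- validate_run_config(config)
  with_seed(seed, {
    if (is.null(inputs)) {
      inputs <- simulate_study(config, seed = NULL)
    }
    truth <- inputs$truth

    de_mi <- moderated_t(inputs$mirna_expr, inputs$groups,
                         fc_hi = config$fc_hi, fc_lo = config$fc_lo,
                         alpha = config$de_alpha)
    de_mr <- moderated_t(inputs$mrna_expr, inputs$groups,
                         fc_hi = config$fc_hi, fc_lo = config$fc_lo,
                         alpha = config$de_alpha)
    de_mirnas <- filter_de(de_mi, config$fc_hi, config$fc_lo, config$de_alpha)
    de_mrnas <- filter_de(de_mr, config$fc_hi, config$fc_lo, config$de_alpha)

    empty_report <- function(reason) {
      structure(list(
        config = unclass(config), seed = seed, note = reason,
        de = list(
          n_mirna = nrow(de_mi$table), n_mirna_de = length(de_mirnas),
          n_mrna = nrow(de_mr$table), n_mrna_de = length(de_mrnas)
        ),
        subnetwork = list(n_edges = 0L, n_mirnas = 0L, n_mrnas = 0L),
        nsr = tibble::tibble(), selected = character(),
        evaluation = tibble::tibble(),
        recovery = if (!is.null(truth)) list(
          planted = truth$planted_biomarkers,
          recall = if (length(truth$planted_biomarkers) > 0) 0 else NA_real_,
          false_selections = 0L
        )
      ), class = "biomarker_report")
    }

    if (length(de_mirnas) == 0 || length(de_mrnas) == 0) {
      report <- empty_report("no differentially expressed features in one assay")
      if (!is.null(output_dir)) persist_report(report, de_mi, de_mr, NULL, output_dir)
      return(report)
    }

    subnet <- extract_subnetwork(inputs$network, de_mirnas, de_mrnas)
    if (nrow(subnet) == 0) {
      report <- empty_report("empty condition-specific subnetwork")
      if (!is.null(output_dir)) persist_report(report, de_mi, de_mr, NULL, output_dir)
      return(report)
    }

    topo <- network_topology(subnet, hub_fraction = config$hub_fraction)
    plaw <- tryCatch(glance(fit_degree_powerlaw(subnet)),
                     error = function(e) NULL)

    nsr_tab <- nsr_records(subnet, inputs$resistance_genes,
                           n_perm = config$n_perm, seed = NULL,
                           nsr_alpha = config$nsr_alpha)
    selected <- nsr_tab$mirna[nsr_tab$selected]

    full_nsr <- compute_nsr(inputs$network)
    cmp_sub <- if (length(selected) > 0) {
      compare_nsr_groups(nsr_tab$nsr[nsr_tab$selected], nsr_tab$nsr)$p
    } else NA_real_
    cmp_ref <- if (length(selected) > 0) {
      compare_nsr_groups(nsr_tab$nsr[nsr_tab$selected], full_nsr$nsr)$p
    } else NA_real_

    evaluation <- evaluate_biomarkers(
      inputs$mirna_expr, inputs$groups, inputs$clinical,
      biomarkers = selected, quartile = config$quartile
    )

    enrich <- if (!is.null(inputs$gene_sets) && length(selected) > 0) {
      targets <- unique(subnet$mrna[subnet$mirna %in% selected])
      ora(targets, inputs$gene_sets, universe = unique(inputs$network$mrna),
          alpha = config$enrich_alpha, fold_cut = config$enrich_fold)
    } else NULL

    recovery <- if (!is.null(truth)) {
      planted <- truth$planted_biomarkers
      list(
        planted = planted,
        recall = if (length(planted) > 0) {
          mean(planted %in% selected)
        } else NA_real_,
        false_selections = length(setdiff(selected, planted))
      )
    } else NULL

    mir_topo <- dplyr::filter(topo, .data$type == "mirna")
    report <- structure(list(
      config = unclass(config), seed = seed,
      de = list(
        n_mirna = nrow(de_mi$table), n_mirna_de = length(de_mirnas),
        n_mrna = nrow(de_mr$table), n_mrna_de = length(de_mrnas),
        d0_mirna = de_mi$params$d0, d0_mrna = de_mr$params$d0
      ),
      subnetwork = list(
        n_edges = nrow(subnet),
        n_mirnas = length(unique(subnet$mirna)),
        n_mrnas = length(unique(subnet$mrna)),
        powerlaw = plaw,
        hub_mirnas = mir_topo$node[mir_topo$is_hub],
        bottleneck_mirnas = mir_topo$node[mir_topo$is_bottleneck]
      ),
      nsr = nsr_tab,
      selected = selected,
      nsr_comparison = list(selected_vs_subnetwork_p = cmp_sub,
                            selected_vs_reference_p = cmp_ref),
      evaluation = evaluation,
      enrichment = enrich,
      recovery = recovery
    ), class = "biomarker_report")

    if (!is.null(output_dir)) {
      persist_report(report, de_mi, de_mr,
                     list(subnet = subnet, topo = topo, nsr = nsr_tab,
                          evaluation = evaluation),
                     output_dir)
    }
    report
  })
}

persist_report <- function(report, de_mi, de_mr, stages, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  readr::write_tsv(de_mi$table, file.path(output_dir, "de_mirna.tsv"))
  readr::write_tsv(de_mr$table, file.path(output_dir, "de_mrna.tsv"))
  if (!is.null(stages)) {
    write_network(stages$subnet, file.path(output_dir, "subnetwork.tsv"))
    readr::write_tsv(stages$topo, file.path(output_dir, "topology.tsv"))
    readr::write_tsv(stages$nsr, file.path(output_dir, "nsr_records.tsv"))
    if (nrow(stages$evaluation) > 0) {
      readr::write_tsv(stages$evaluation, file.path(output_dir, "evaluation.tsv"))
    }
  }
  write_run_report(report, file.path(output_dir, "report.json"))
  invisible(output_dir)
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("Biomarker discovery report\n")
  cat(sprintf("  DE: %d/%d miRNAs, %d/%d mRNAs\n",
              x$de$n_mirna_de, x$de$n_mirna, x$de$n_mrna_de, x$de$n_mrna))
  cat(sprintf("  Subnetwork: %d edges, %d miRNAs, %d mRNAs\n",
              x$subnetwork$n_edges, x$subnetwork$n_mirnas, x$subnetwork$n_mrnas))
  if (!is.null(x$subnetwork$powerlaw)) {
    cat(sprintf("  Degree distribution R^2 = %.3f\n", x$subnetwork$powerlaw$r_squared))
  }
  cat(sprintf("  Selected biomarkers (%d): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  if (!is.null(x$recovery) && length(x$recovery$planted) > 0) {
    cat(sprintf("  Planted recovery: recall = %.2f, false selections = %d\n",
                x$recovery$recall, x$recovery$false_selections))
  }
  invisible(x)
}

#' @export
glance.biomarker_report <- function(x, ...) {
  tibble::tibble(
    n_mirna_de = x$de$n_mirna_de, n_mrna_de = x$de$n_mrna_de,
    n_edges = x$subnetwork$n_edges, n_mirnas = x$subnetwork$n_mirnas,
    n_mrnas = x$subnetwork$n_mrnas,
    n_selected = length(x$selected),
    recall = if (!is.null(x$recovery)) x$recovery$recall else NA_real_,
    false_selections = if (!is.null(x$recovery)) x$recovery$false_selections else NA_integer_
  )
}
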