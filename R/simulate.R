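#' Simulate a bipartite miRNA-mRNA regulatory network with planted biomarkers
#'
#' Background edges are laid down by preferential attachment on mRNA
#' in-degree (attachment weight `in-degree + 1`), which yields the
#' heavy-tailed, scale-free-like degree distribution typical of regulatory
#' networks.  Each of `n_planted` biomarker miRNAs then receives
#' `planted_excess_singles` dedicated mRNAs regulated by no other miRNA, so
#' its single-line regulation count (NSR) is at least
#' `planted_excess_singles` by construction.  The dedicated targets replace
#' that many of the biomarker's shared background targets (its total target
#' count stays typical): a planted biomarker's regulatory program is
#' dominated by exclusive targets, the empirical signature of
#' network-vulnerable miRNAs.
#'
#' Ground truth for recovery experiments is returned alongside the network:
#' planted log2 fold changes (biomarker miRNAs are up-regulated with
#' `effect_log2fc`; their dedicated targets and a fraction `de_fraction` of
#' the remaining features carry `±effect_log2fc` with random sign), a
#' resistance-gene list containing at least one dedicated single-line target
#' of every planted biomarker plus `n_resistance_decoys` background genes,
#' and per-biomarker hazard coefficients for the survival simulator.
#'
#' @param n_mirna,n_mrna Node counts of the two partitions.
#' @param mean_targets Mean number of background targets per miRNA (Poisson,
#'   minimum 1).
#' @param n_planted Number of planted biomarker miRNAs (0 allowed).
#' @param planted_excess_singles Dedicated single-line targets per planted
#'   biomarker.
#' @param de_fraction Fraction of non-planted features given a true
#'   differential-expression shift.
#' @param effect_log2fc Magnitude of every planted log2 fold change.
#' @param n_resistance_decoys Background genes added to the resistance list.
#' @param hazard_coefficient Log-hazard slope per standardized unit of each
#'   planted biomarker's expression.
#' @param seed Integer seed (RNG state is restored afterwards); `NULL` uses
#'   the current RNG stream.
#' @return A list with elements `network` (edge tibble `mirna`, `mrna`) and
#'   `truth` (list: `planted_biomarkers`, `planted_de_mirnas`,
#'   `planted_de_mrnas` — named log2FC vectors —, `resistance_genes`,
#'   `hazard_coefficients`, `params`).
#' @export
simulate_network <- function(n_mirna = 50L, n_mrna = 200L, mean_targets = 20,
                             n_planted = 4L, planted_excess_singles = 10L,
                             de_fraction = 0.35, effect_log2fc = 1,
                             n_resistance_decoys = 5L,
                             hazard_coefficient = 1, seed = NULL) {
  n_mirna <- check_count(n_mirna, "n_mirna", min = 1L)
  n_mrna <- check_count(n_mrna, "n_mrna", min = 1L)
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  planted_excess_singles <- check_count(planted_excess_singles,
                                        "planted_excess_singles", min = 0L)
  if (n_planted > n_mirna) {
    stop_parameter("`n_planted` cannot exceed `n_mirna`.")
  }
  n_reserved <- n_planted * planted_excess_singles
  if (n_reserved > n_mrna) {
    stop_parameter("`n_planted * planted_excess_singles` cannot exceed `n_mrna`.")
  }
  check_scalar_prob(de_fraction, "de_fraction", open_left = FALSE, open_right = FALSE)
  if (!is.numeric(mean_targets) || mean_targets <= 0) {
    stop_parameter("`mean_targets` must be positive.")
  }

  mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
  mrnas <- sprintf("GENE%04d", seq_len(n_mrna))
  n_cand <- n_mrna - n_reserved
  if (n_cand < 1L) {
    stop_parameter("no background mRNAs left after reserving planted singles.")
  }

  with_seed(seed, {
    out_deg <- pmin(pmax(1L, rpois(n_mirna, mean_targets)), n_cand)
    planted <- if (n_planted > 0) sort(sample.int(n_mirna, n_planted)) else integer(0)
    # A planted biomarker keeps a typical total target count, but its
    # dedicated exclusive targets replace that many shared background
    # targets: its regulatory program is dominated by single-line edges,
    # the empirical signature of a network-vulnerable miRNA.
    out_deg[planted] <- pmax(0L, out_deg[planted] - planted_excess_singles)
    weight <- rep(1, n_cand) # in-degree + 1
    edge_m <- integer(0)
    edge_g <- integer(0)
    for (i in seq_len(n_mirna)) {
      taken <- logical(n_cand)
      chosen <- integer(out_deg[i])
      for (j in seq_len(out_deg[i])) {
        w <- weight
        w[taken] <- 0
        pick <- sample.int(n_cand, 1L, prob = w)
        taken[pick] <- TRUE
        chosen[j] <- pick
        weight[pick] <- weight[pick] + 1
      }
      edge_m <- c(edge_m, rep.int(i, out_deg[i]))
      edge_g <- c(edge_g, chosen)
    }

    planted_targets <- vector("list", n_planted)
    if (n_reserved > 0) {
      reserved <- n_cand + seq_len(n_reserved)
      for (k in seq_len(n_planted)) {
        block <- reserved[(k - 1L) * planted_excess_singles + seq_len(planted_excess_singles)]
        planted_targets[[k]] <- block
        edge_m <- c(edge_m, rep.int(planted[k], length(block)))
        edge_g <- c(edge_g, block)
      }
    }

    network <- tibble::tibble(mirna = mirnas[edge_m], mrna = mrnas[edge_g])

    # --- ground truth -------------------------------------------------------
    rand_sign <- function(n) sample(c(-1, 1), n, replace = TRUE)

    other_mirna <- setdiff(seq_len(n_mirna), planted)
    n_de_mi <- round(de_fraction * length(other_mirna))
    de_mi_extra <- if (n_de_mi > 0) sort(sample(other_mirna, n_de_mi)) else integer(0)
    planted_de_mirnas <- c(
      setNames(rep(effect_log2fc, n_planted), mirnas[planted]),
      setNames(effect_log2fc * rand_sign(length(de_mi_extra)), mirnas[de_mi_extra])
    )

    reserved_idx <- if (n_reserved > 0) n_cand + seq_len(n_reserved) else integer(0)
    other_mrna <- setdiff(seq_len(n_mrna), reserved_idx)
    n_de_mr <- round(de_fraction * length(other_mrna))
    de_mr_extra <- if (n_de_mr > 0) sort(sample(other_mrna, n_de_mr)) else integer(0)
    planted_de_mrnas <- c(
      setNames(effect_log2fc * rand_sign(length(reserved_idx)), mrnas[reserved_idx]),
      setNames(effect_log2fc * rand_sign(length(de_mr_extra)), mrnas[de_mr_extra])
    )

    decoy_pool <- intersect(other_mrna, unique(edge_g))
    n_decoy <- min(n_resistance_decoys, length(decoy_pool))
    decoys <- if (n_decoy > 0) sort(sample(decoy_pool, n_decoy)) else integer(0)
    anchor <- if (n_reserved > 0) {
      vapply(planted_targets, function(b) b[1], integer(1))
    } else integer(0)
    resistance_genes <- unique(c(mrnas[anchor], mrnas[decoys]))

    truth <- list(
      planted_biomarkers = mirnas[planted],
      planted_de_mirnas = planted_de_mirnas,
      planted_de_mrnas = planted_de_mrnas,
      resistance_genes = resistance_genes,
      hazard_coefficients = setNames(
        rep(hazard_coefficient, n_planted), mirnas[planted]
      ),
      params = list(
        n_mirna = n_mirna, n_mrna = n_mrna, mean_targets = mean_targets,
        n_planted = n_planted, planted_excess_singles = planted_excess_singles,
        de_fraction = de_fraction, effect_log2fc = effect_log2fc,
        n_resistance_decoys = n_resistance_decoys,
        hazard_coefficient = hazard_coefficient, seed = seed
      )
    )
    list(network = network, truth = truth)
  })
}

#' Simulate log2 expression matrices for the two patient groups
#'
#' Every network node becomes a feature.  Per-feature baseline means are
#' drawn from Normal(8, 2) on the log2 scale; per-sample values add
#' Normal(0, `sigma`) noise.  Features with a planted log2FC have their
#' resistant-group mean shifted by that amount; all other features have zero
#' shift.
#'
#' @param network Edge tibble from [simulate_network()].
#' @param truth Truth list from [simulate_network()].
#' @param n_sensitive,n_resistant Group sizes (each >= 2).
#' @param sigma Within-group standard deviation (> 0).
#' @param seed Integer seed or `NULL` (current stream).
#' @return A list with `mirna_expr`, `mrna_expr` (wide expression tibbles)
#'   and `groups` (tibble `sample_id`, `group`).
#' @export
simulate_expression <- function(network, truth, n_sensitive = 31L,
                                n_resistant = 37L, sigma = 0.5, seed = NULL) {
  network <- validate_network(network)
  n_sensitive <- check_count(n_sensitive, "n_sensitive", min = 2L)
  n_resistant <- check_count(n_resistant, "n_resistant", min = 2L)
  if (!is.numeric(sigma) || sigma <= 0) stop_parameter("`sigma` must be > 0.")

  samples <- c(sprintf("S%03d", seq_len(n_sensitive)),
               sprintf("R%03d", seq_len(n_resistant)))
  groups <- tibble::tibble(
    sample_id = samples,
    group = rep(c("sensitive", "resistant"), c(n_sensitive, n_resistant))
  )
  resistant <- groups$group == "resistant"

  gen <- function(features, shifts) {
    base <- rnorm(length(features), mean = 8, sd = 2)
    fc <- unname(shifts[features])
    fc[is.na(fc)] <- 0
    vals <- matrix(rnorm(length(features) * length(samples), sd = sigma),
                   nrow = length(features))
    vals <- vals + base
    vals[, resistant] <- vals[, resistant] + fc
    out <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
    names(out) <- samples
    dplyr::bind_cols(tibble::tibble(feature_id = features), out)
  }

  with_seed(seed, {
    mirna_expr <- gen(unique(network$mirna), truth$planted_de_mirnas)
    mrna_expr <- gen(unique(network$mrna), truth$planted_de_mrnas)
    list(mirna_expr = mirna_expr, mrna_expr = mrna_expr, groups = groups)
  })
}

#' Simulate clinical follow-up with biomarker-dependent hazard
#'
#' Overall-survival event times are exponential with per-sample rate
#' `baseline_hazard * exp(sum_m beta_m * z_m)` where `z_m` is the
#' standardized expression of planted biomarker `m` and `beta_m` its hazard
#' coefficient.  Progression times are the OS times scaled by `sqrt(U)`,
#' `U ~ Uniform(0,1)`, so PFS <= OS pathwise.  An independent exponential
#' censoring time (shared by both endpoints) is calibrated so that, under a
#' null hazard, a fraction `censor_rate` of subjects is censored;
#' `censor_rate = 0` disables censoring.
#'
#' @param mirna_expr Wide miRNA expression tibble.
#' @param truth Truth list from [simulate_network()].
#' @param baseline_hazard Events per month at zero covariates (> 0).
#' @param censor_rate Target null censoring fraction in `[0, 1)`.
#' @param seed Integer seed or `NULL` (current stream).
#' @return A clinical tibble (`sample_id`, `pfs_time`, `pfs_event`,
#'   `os_time`, `os_event`), times in months.
#' @export
simulate_clinical <- function(mirna_expr, truth, baseline_hazard = 0.05,
                              censor_rate = 0.3, seed = NULL) {
  mirna_expr <- validate_expression(mirna_expr, arg = "mirna_expr")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop_parameter("`baseline_hazard` must be > 0.")
  }
  check_scalar_prob(censor_rate, "censor_rate", open_left = FALSE)

  x <- expr_matrix(mirna_expr)
  samples <- colnames(x)
  coefs <- truth$hazard_coefficients
  loghaz <- rep(0, length(samples))
  for (m in names(coefs)) {
    if (!m %in% rownames(x)) next
    z <- as.numeric(scale(x[m, ]))
    loghaz <- loghaz + coefs[[m]] * z
  }
  rate <- baseline_hazard * exp(loghaz)

  with_seed(seed, {
    t_os <- rexp(length(samples), rate = rate)
    t_pfs <- t_os * sqrt(runif(length(samples)))
    if (censor_rate > 0) {
      cens <- rexp(length(samples),
                   rate = baseline_hazard * censor_rate / (1 - censor_rate))
    } else {
      cens <- rep(Inf, length(samples))
    }
    tibble::tibble(
      sample_id = samples,
      pfs_time = pmin(t_pfs, cens),
      pfs_event = as.integer(t_pfs <= cens),
      os_time = pmin(t_os, cens),
      os_event = as.integer(t_os <= cens)
    )
  })
}

#' Simulate a complete study (network, truth, expression, clinical)
#'
#' Runs the three generators on a single seeded RNG stream and optionally
#' writes every input file the pipeline consumes (expression TSVs, groups,
#' edge list, resistance-gene list, clinical TSV, truth JSON) into `dir`.
#'
#' @param config A `run_config` list; `config$simulation` holds all generator
#'   parameters (see [default_run_config()]).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param dir Optional output directory.
#' @return A list: `network`, `truth`, `mirna_expr`, `mrna_expr`, `groups`,
#'   `clinical`, `resistance_genes`, plus `files` when `dir` is given.
#' @export
simulate_study <- function(config = default_run_config(), seed = config$seed,
                           dir = NULL) {
  sim <- config$simulation
  with_seed(seed, {
    net <- simulate_network(
      n_mirna = sim$n_mirna, n_mrna = sim$n_mrna,
      mean_targets = sim$mean_targets, n_planted = sim$n_planted,
      planted_excess_singles = sim$planted_excess_singles,
      de_fraction = sim$de_fraction, effect_log2fc = sim$effect_log2fc,
      hazard_coefficient = sim$hazard_coefficient, seed = NULL
    )
    ex <- simulate_expression(
      net$network, net$truth,
      n_sensitive = sim$n_sensitive, n_resistant = sim$n_resistant,
      sigma = sim$sigma, seed = NULL
    )
    clin <- simulate_clinical(
      ex$mirna_expr, net$truth,
      baseline_hazard = sim$baseline_hazard, censor_rate = sim$censor_rate,
      seed = NULL
    )
    study <- list(
      network = net$network, truth = net$truth,
      mirna_expr = ex$mirna_expr, mrna_expr = ex$mrna_expr,
      groups = ex$groups, clinical = clin,
      resistance_genes = net$truth$resistance_genes
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- list(
        mirna_expr = file.path(dir, "mirna_expression.tsv"),
        mrna_expr = file.path(dir, "mrna_expression.tsv"),
        groups = file.path(dir, "sample_groups.tsv"),
        network = file.path(dir, "regulatory_network.tsv"),
        resistance_genes = file.path(dir, "resistance_genes.txt"),
        clinical = file.path(dir, "clinical.tsv"),
        truth = file.path(dir, "truth.json")
      )
      write_expression(study$mirna_expr, files$mirna_expr)
      write_expression(study$mrna_expr, files$mrna_expr)
      write_sample_groups(study$groups, files$groups)
      write_network(study$network, files$network)
      readr::write_lines(study$resistance_genes, files$resistance_genes)
      write_clinical(study$clinical, files$clinical)
      jsonlite::write_json(study$truth, files$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      study$files <- files
    }
    study
  })
}
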