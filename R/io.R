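#' Read a log2 expression matrix from TSV
#'
#' The file is tab-separated with a header row of sample IDs and the first
#' column holding feature IDs (miRNA or gene symbols).  Lines starting with
#' `#` are comments.  Values are expected on log2 scale; the package performs
#' no normalisation of its own.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `feature_id` column followed by one numeric column
#'   per sample, in file order.
#' @export
read_expression <- function(path) {
  raw <- read_tsv_cells(path)
  if (nrow(raw) < 1L) stop_format(sprintf("%s: empty file.", path))
  if (nrow(raw) < 2L) stop_format(sprintf("%s: no features.", path))
  header <- as.character(raw[1, ])
  sample_ids <- header[-1]
  if (length(sample_ids) < 1L) stop_format(sprintf("%s: no sample columns.", path))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0) {
    stop_format(sprintf("%s: duplicate sample ID '%s'.", path, dup_s[1]))
  }
  feature_ids <- as.character(raw[[1]][-1])
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f) > 0) {
    stop_format(sprintf("%s: duplicate feature ID '%s'.", path, dup_f[1]))
  }
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop_format(sprintf(
      "%s: non-numeric value '%s' at feature '%s', sample '%s'.",
      path, body[bad[1], bad[2]], feature_ids[bad[1]], sample_ids[bad[2]]
    ))
  }
  out <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
  names(out) <- sample_ids
  validate_expression(dplyr::bind_cols(tibble::tibble(feature_id = feature_ids), out))
}

#' Write an expression matrix to TSV
#'
#' @param expr Wide expression tibble (see [read_expression()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read a miRNA-to-mRNA regulatory edge list
#'
#' Two tab-separated columns (miRNA, target mRNA); a header line is detected
#' and skipped when its first field is one of `mirna`/`miRNA`.  Duplicate
#' edges in the file are collapsed, preserving first-occurrence order.  An ID
#' occurring in both columns violates the bipartite partition and is an error.
#'
#' @param path Path to a TSV edge list.
#' @return A tibble with columns `mirna`, `mrna` (one row per unique edge).
#' @export
read_network <- function(path) {
  raw <- read_tsv_cells(path)
  if (nrow(raw) < 1L || ncol(raw) < 2L) {
    stop_format(sprintf("%s: expected two tab-separated columns.", path))
  }
  if (tolower(as.character(raw[1, 1])) %in% c("mirna", "mir", "source")) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) < 1L) stop_format(sprintf("%s: no edges.", path))
  edges <- tibble::tibble(
    mirna = as.character(raw[[1]]),
    mrna  = as.character(raw[[2]])
  )
  validate_network(edges, arg = path, dedupe = TRUE)
}

#' Write a regulatory edge list to TSV
#'
#' @param edges Edge tibble with columns `mirna`, `mrna`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  edges <- validate_network(edges)
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Read sample group labels
#'
#' TSV with columns `sample_id` and `group`; labels must be `sensitive` or
#' `resistant` and both groups must be present.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_sample_groups <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  validate_groups(tab, arg = path)
}

#' Write sample group labels to TSV
#' @param groups Tibble with columns `sample_id`, `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_groups <- function(groups, path) {
  groups <- validate_groups(groups)
  readr::write_tsv(groups, path)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `pfs_time`, `pfs_event`, `os_time`,
#' `os_event`.  Times are in months and non-negative; events are 0/1.
#'
#' @param path Path to a TSV file.
#' @return A clinical tibble.
#' @export
read_clinical <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", .default = "d"
                         ))
  validate_clinical(tab, arg = path)
}

#' Write a clinical table to TSV
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Read gene sets (GMT dialect or a one-ID-per-line list)
#'
#' A GMT line is `set_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#' A file whose lines contain no tabs is read as a single gene list named
#' after the file (extension stripped).  Members are de-duplicated within a
#' set; an empty set is an error.
#'
#' @param path Path to a GMT or plain-list file.
#' @return A long tibble with columns `set_id`, `description`, `gene`.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format(sprintf("%s: empty gene-set file.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(fields) == 1L)) {
    genes <- unique(vapply(fields, `[[`, "", 1L))
    set_id <- sub("\\.[^.]*$", "", basename(path))
    return(tibble::tibble(set_id = set_id, description = basename(path), gene = genes))
  }
  rows <- purrr::map(fields, function(f) {
    if (length(f) < 3L) {
      stop_format(sprintf("%s: gene set '%s' has no members.", path, f[1]))
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop_format(sprintf("%s: gene set '%s' has no members.", path, f[1]))
    }
    tibble::tibble(set_id = f[1], description = f[2], gene = members)
  })
  validate_gene_sets(dplyr::bind_rows(rows), arg = path)
}

#' Write gene sets in GMT format
#' @param sets Long gene-set tibble (`set_id`, `description`, `gene`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  sets <- validate_gene_sets(sets)
  lines <- sets |>
    dplyr::group_by(.data$set_id, .data$description) |>
    dplyr::summarise(members = paste(.data$gene, collapse = "\t"), .groups = "drop") |>
    dplyr::mutate(line = paste(.data$set_id, .data$description, .data$members, sep = "\t"))
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Write / read a structured run report (JSON)
#'
#' Reports are serialized as JSON with scalars unboxed and numerics at full
#' precision, so a write/read round trip preserves every numeric field.
#'
#' @param report A list (typically a `biomarker_report`).
#' @param path Output path.
#' @return `path` invisibly (writer); the parsed list (reader).
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Default run configuration
#'
#' All analysis cutoffs in one place: fold-change window (`fc_hi` = 1.5,
#' `fc_lo` = 0.67), DE significance (`de_alpha` = 0.05), NSR significance
#' (`nsr_alpha` = 0.01), hub/bottleneck fraction (`hub_fraction` = 0.10),
#' survival split quantile (`quartile` = 0.75), enrichment cutoffs
#' (`enrich_alpha` = 0.05, `enrich_fold` = 1.5), permutation count and seed.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    fc_hi = 1.5, fc_lo = 0.67,
    de_alpha = 0.05, nsr_alpha = 0.01,
    hub_fraction = 0.10, quartile = 0.75,
    enrich_alpha = 0.05, enrich_fold = 1.5,
    n_perm = 1000L, seed = 1L,
    simulation = list(
      n_mirna = 50L, n_mrna = 200L, mean_targets = 20,
      n_planted = 4L, planted_excess_singles = 10L,
      de_fraction = 0.35, effect_log2fc = 1,
      n_sensitive = 31L, n_resistant = 37L, sigma = 0.5,
      hazard_coefficient = 1, baseline_hazard = 0.05, censor_rate = 0.3
    ),
    paths = list()
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [default_run_config()]; everything is
#' validated (`0 < fc_lo < 1 < fc_hi`, alphas and `hub_fraction` in (0,1)).
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(unclass(default_run_config()), user)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#' @param config A `run_config` list.
#' @return The config, invisibly usable, after checks.
#' @export
validate_run_config <- function(config) {
  if (!(is.numeric(config$fc_lo) && is.numeric(config$fc_hi) &&
        0 < config$fc_lo && config$fc_lo < 1 &&
        1 < config$fc_hi)) {
    stop_parameter("config: need 0 < fc_lo < 1 < fc_hi.")
  }
  for (a in c("de_alpha", "nsr_alpha", "enrich_alpha")) {
    check_scalar_prob(config[[a]], a)
  }
  check_scalar_prob(config$hub_fraction, "hub_fraction")
  check_scalar_prob(config$quartile, "quartile")
  check_count(config$n_perm, "n_perm", min = 1L)
  config
}

# Read every cell of a TSV file as character, ignoring '#' comment lines.
# Keeps full control over error reporting (readr would silently repair
# duplicate column names, which the format forbids).
read_tsv_cells <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- max(lengths(fields))
  mat <- vapply(fields, function(f) c(f, rep("", ncol - length(f))),
                character(ncol))
  mat <- if (ncol == 1L) matrix(mat, ncol = 1L) else t(mat)
  tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                    .name_repair = "minimal")
}
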