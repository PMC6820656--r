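# Internal validation and error helpers.  All user-facing errors carry a
# subclass so callers (and the pipeline driver) can branch on error kind:
#   mirvuln_format_error     malformed input file / table
#   mirvuln_parameter_error  invalid argument value
#   mirvuln_degenerate_error structurally valid input on which the statistic
#                            is undefined (e.g. all-zero variances)

stop_format <- function(msg, ...) {
  abort(msg, class = "mirvuln_format_error", ...)
}

stop_parameter <- function(msg, ...) {
  abort(msg, class = "mirvuln_parameter_error", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "mirvuln_degenerate_error", ...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed = NULL` means: use the current stream untouched (callers that manage
# a single stream, e.g. the pipeline driver, rely on this).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_parameter("`seed` must be a single finite number or NULL.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

check_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    stop_parameter(sprintf(
      "`%s` must be a single number in %s0, 1%s.",
      name, if (open_left) "(" else "[", if (open_right) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop_parameter(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# ---- shared table validators -----------------------------------------------

GROUP_LEVELS <- c("sensitive", "resistant")

# Expression travels as a wide tibble: `feature_id` + one numeric column per
# sample.  Returns the tibble unchanged after checking invariants.
validate_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || ncol(expr) < 2L) {
    stop_format(sprintf(
      "`%s` must be a data frame with a feature_id column and >=1 sample column.", arg
    ))
  }
  if (names(expr)[1] != "feature_id") {
    stop_format(sprintf("first column of `%s` must be named 'feature_id'.", arg))
  }
  ids <- expr$feature_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_format(sprintf("duplicate feature ID(s) in `%s`: %s", arg, dup[1]))
  }
  samp <- names(expr)[-1]
  dup_s <- samp[duplicated(samp)]
  if (length(dup_s) > 0) {
    stop_format(sprintf("duplicate sample ID(s) in `%s`: %s", arg, dup_s[1]))
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(suppressWarnings(
      matrix(as.numeric(vals), nrow = nrow(vals))
    )), arr.ind = TRUE)
    loc <- if (nrow(bad) > 0) {
      sprintf(" (feature %s, sample %s)", ids[bad[1, 1]], samp[bad[1, 2]])
    } else ""
    stop_format(sprintf("`%s` contains non-finite or non-numeric values%s.", arg, loc))
  }
  tibble::as_tibble(expr)
}

# Convert the wide expression tibble to a features x samples numeric matrix.
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$feature_id
  m
}

validate_groups <- function(groups, arg = "groups") {
  if (!is.data.frame(groups) || !all(c("sample_id", "group") %in% names(groups))) {
    stop_format(sprintf("`%s` must have columns sample_id and group.", arg))
  }
  bad <- setdiff(unique(groups$group), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop_format(sprintf(
      "`%s` has unknown group label(s): %s (expected 'sensitive'/'resistant').",
      arg, paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(groups$sample_id)) {
    stop_format(sprintf("duplicate sample ID(s) in `%s`.", arg))
  }
  if (!all(GROUP_LEVELS %in% groups$group)) {
    stop_format(sprintf("`%s` must contain both groups.", arg))
  }
  tibble::as_tibble(groups)
}

validate_network <- function(edges, arg = "edges", dedupe = FALSE) {
  if (!is.data.frame(edges) || !all(c("mirna", "mrna") %in% names(edges))) {
    stop_format(sprintf("`%s` must have columns mirna and mrna.", arg))
  }
  edges <- tibble::as_tibble(edges[, c("mirna", "mrna")])
  if (dedupe) {
    edges <- dplyr::distinct(edges)
  } else if (anyDuplicated(paste(edges$mirna, edges$mrna, sep = "\r"))) {
    stop_format(sprintf("`%s` contains duplicate edges.", arg))
  }
  both <- intersect(unique(edges$mirna), unique(edges$mrna))
  if (length(both) > 0) {
    stop_format(sprintf(
      "ID(s) appear in both the miRNA and mRNA partitions of `%s`: %s",
      arg, both[1]
    ))
  }
  edges
}

validate_clinical <- function(clinical, arg = "clinical") {
  need <- c("sample_id", "pfs_time", "pfs_event", "os_time", "os_event")
  if (!is.data.frame(clinical) || !all(need %in% names(clinical))) {
    stop_format(sprintf(
      "`%s` must have columns %s.", arg, paste(need, collapse = ", ")
    ))
  }
  clinical <- tibble::as_tibble(clinical[, need])
  times <- c(clinical$pfs_time, clinical$os_time)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_format(sprintf("`%s`: survival times must be finite and >= 0.", arg))
  }
  events <- c(clinical$pfs_event, clinical$os_event)
  if (!all(events %in% c(0, 1))) {
    stop_format(sprintf("`%s`: event indicators must be 0/1.", arg))
  }
  if (anyDuplicated(clinical$sample_id)) {
    stop_format(sprintf("duplicate sample ID(s) in `%s`.", arg))
  }
  clinical
}

validate_gene_sets <- function(sets, arg = "gene_sets") {
  if (!is.data.frame(sets) || !all(c("set_id", "description", "gene") %in% names(sets))) {
    stop_format(sprintf("`%s` must have columns set_id, description, gene.", arg))
  }
  sets <- tibble::as_tibble(sets[, c("set_id", "description", "gene")])
  if (anyDuplicated(sets[, c("set_id", "gene")])) {
    stop_format(sprintf("`%s` has duplicate members within a set.", arg))
  }
  sets
}

# Coerce a resistance-gene input (character vector or gene-set tibble) to a
# unique character vector of gene IDs.
as_gene_list <- function(x, arg = "resistance_genes") {
  if (is.data.frame(x)) {
    if (!"gene" %in% names(x)) {
      stop_format(sprintf("`%s` data frame must have a 'gene' column.", arg))
    }
    x <- x$gene
  }
  if (!is.character(x)) {
    stop_parameter(sprintf("`%s` must be a character vector or gene-set table.", arg))
  }
  unique(x)
}
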