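#' ROC curve and AUC for a single biomarker
#'
#' The positive class is `resistant` and higher scores indicate the positive
#' class.  AUC is the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)`; the curve is
#' produced by sweeping every distinct score as a threshold, which makes the
#' trapezoidal area under the curve equal the Mann-Whitney AUC, ties
#' included.
#'
#' @param scores Numeric vector (typically log2 expression of one miRNA).
#' @param labels Character vector/factor of class labels aligned with
#'   `scores`, or a `sample_id`/`group` tibble when `scores` is named.
#' @param positive Positive class label (default `"resistant"`).
#' @return An object of class `mirvuln_roc`: `auc`, `curve` (tibble `fpr`,
#'   `tpr`, starting at (0,0) and ending at (1,1)), class counts.
#' @export
roc_auc <- function(scores, labels, positive = "resistant") {
  if (is.data.frame(labels)) {
    labels <- validate_groups(labels)
    if (is.null(names(scores))) {
      stop_parameter("`scores` must be named by sample when `labels` is a table.")
    }
    labels <- labels$group[match(names(scores), labels$sample_id)]
  }
  if (length(scores) != length(labels)) {
    stop_parameter("`scores` and `labels` must have equal length.")
  }
  keep <- !is.na(labels)
  scores <- as.numeric(scores[keep])
  labels <- as.character(labels[keep])
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop_degenerate("both classes must be present to compute a ROC curve.")
  }

  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(pos & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!pos & scores >= t), numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )

  structure(list(auc = unname(auc), curve = curve, n_pos = n_pos,
                 n_neg = n_neg, positive = positive),
            class = "mirvuln_roc")
}

#' @export
tidy.mirvuln_roc <- function(x, ...) x$curve

#' @export
glance.mirvuln_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 positive = x$positive)
}

#' @export
print.mirvuln_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (positive = '%s', %d vs %d)\n",
              x$auc, x$positive, x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC curve plot
#' @param object A `mirvuln_roc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirvuln_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves and log-rank test with upper-quartile stratification
#'
#' Samples are split into a high-expression group (expression strictly above
#' the `quartile`-th empirical quantile, linear-interpolation convention) and
#' a low-expression group (the remainder).  Kaplan-Meier survival curves are
#' estimated per group and compared with the two-group log-rank test
#' (chi-square with 1 df).  Censored observations at an event time count as
#' at risk at that time (standard convention).
#'
#' @param values Named numeric vector of one miRNA's expression, names =
#'   sample IDs present in `clinical`.
#' @param clinical Clinical tibble (`sample_id`, `pfs_time`, `pfs_event`,
#'   `os_time`, `os_event`).
#' @param endpoint `"pfs"` (default) or `"os"`.
#' @param quartile Split quantile (default 0.75, the upper quartile).
#' @return An object of class `mirvuln_km`: `curves` (tibble `group`,
#'   `time`, `n_risk`, `n_event`, `survival`), `logrank_chi2`, `p`,
#'   `split_threshold`, group sizes.
#' @export
km_logrank <- function(values, clinical, endpoint = c("pfs", "os"),
                       quartile = 0.75) {
  endpoint <- match.arg(endpoint)
  clinical <- validate_clinical(clinical)
  check_scalar_prob(quartile, "quartile")
  if (is.null(names(values))) {
    stop_parameter("`values` must be named by sample ID.")
  }
  common <- intersect(names(values), clinical$sample_id)
  if (length(common) < 4) stop_parameter("need >= 4 samples with clinical data.")
  v <- as.numeric(values[common])
  cl <- clinical[match(common, clinical$sample_id), ]

  thr <- unname(quantile(v, probs = quartile, type = 7))
  grp <- ifelse(v > thr, "high", "low")
  if (min(table(factor(grp, levels = c("high", "low")))) < 2) {
    stop_degenerate(sprintf(
      "upper-quartile split at threshold %.4g leaves a group with < 2 samples.", thr
    ))
  }

  time <- if (endpoint == "pfs") cl$pfs_time else cl$os_time
  event <- if (endpoint == "pfs") cl$pfs_event else cl$os_event
  if (sum(event) == 0) stop_degenerate("no events observed for this endpoint.")

  surv <- survival::Surv(time, event)
  sf <- survival::survfit(surv ~ grp)
  sd <- survival::survdiff(surv ~ grp)
  chi2 <- unname(sd$chisq)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)

  strata <- rep(sub("^grp=", "", names(sf$strata)), sf$strata)
  curves <- tibble::tibble(
    group = strata, time = sf$time,
    n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv
  )
  curves <- dplyr::bind_rows(
    tibble::tibble(group = unique(strata), time = 0,
                   n_risk = as.integer(table(grp)[unique(strata)]),
                   n_event = 0L, survival = 1),
    curves
  ) |> dplyr::arrange(.data$group, .data$time)

  structure(list(
    curves = curves, logrank_chi2 = chi2, p = p,
    split_threshold = thr, endpoint = endpoint, quartile = quartile,
    n_high = sum(grp == "high"), n_low = sum(grp == "low")
  ), class = "mirvuln_km")
}

#' @export
tidy.mirvuln_km <- function(x, ...) x$curves

#' @export
glance.mirvuln_km <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint, logrank_chi2 = x$logrank_chi2, p = x$p,
    split_threshold = x$split_threshold,
    n_high = x$n_high, n_low = x$n_low
  )
}

#' @export
print.mirvuln_km <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier (%s): high n=%d vs low n=%d, log-rank chi2 = %.3f, p = %.4g\n",
    toupper(x$endpoint), x$n_high, x$n_low, x$logrank_chi2, x$p
  ))
  invisible(x)
}

#' Kaplan-Meier survival curve plot
#' @param object A `mirvuln_km` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirvuln_km <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (months)", y = "Survival probability",
      title = sprintf("%s: log-rank p = %.4g", toupper(object$endpoint), object$p),
      colour = "Expression"
    ) +
    ggplot2::theme_minimal()
}

#' Evaluate a set of biomarkers by ROC and survival analysis
#'
#' Per biomarker: AUC for discriminating resistant from sensitive samples,
#' and log-rank p-values for PFS and OS after upper-quartile expression
#' stratification.  A biomarker whose survival split is degenerate (e.g. a
#' group emptied by ties) gets `NA` for that endpoint with a warning.
#'
#' @param mirna_expr Wide miRNA expression tibble.
#' @param groups Sample-group tibble.
#' @param clinical Clinical tibble, or `NULL` to skip survival evaluation.
#' @param biomarkers Character vector of miRNA IDs to evaluate.
#' @param quartile Survival split quantile (default 0.75).
#' @return A tibble: `mirna`, `auc`, `split_threshold`, `logrank_p_pfs`,
#'   `logrank_p_os` (NA when `clinical` is NULL).
#' @export
evaluate_biomarkers <- function(mirna_expr, groups, clinical = NULL,
                                biomarkers, quartile = 0.75) {
  mirna_expr <- validate_expression(mirna_expr, arg = "mirna_expr")
  groups <- validate_groups(groups)
  if (length(biomarkers) == 0) {
    return(tibble::tibble(
      mirna = character(), auc = numeric(), split_threshold = numeric(),
      logrank_p_pfs = numeric(), logrank_p_os = numeric()
    ))
  }
  missing <- setdiff(biomarkers, mirna_expr$feature_id)
  if (length(missing) > 0) {
    stop_parameter(sprintf("biomarker(s) absent from expression: %s",
                           paste(missing, collapse = ", ")))
  }
  x <- expr_matrix(mirna_expr)
  safe_km <- function(v, endpoint) {
    tryCatch(
      glance(km_logrank(v, clinical, endpoint = endpoint, quartile = quartile)),
      error = function(e) {
        warn(sprintf("survival evaluation (%s) failed: %s",
                     endpoint, conditionMessage(e)))
        tibble::tibble(p = NA_real_, split_threshold = NA_real_)
      }
    )
  }
  purrr::map_dfr(biomarkers, function(m) {
    v <- x[m, ]
    roc <- roc_auc(v, groups)
    out <- tibble::tibble(
      mirna = m, auc = roc$auc,
      split_threshold = unname(quantile(v, probs = quartile, type = 7)),
      logrank_p_pfs = NA_real_, logrank_p_os = NA_real_
    )
    if (!is.null(clinical)) {
      out$logrank_p_pfs <- safe_km(v, "pfs")$p
      out$logrank_p_os <- safe_km(v, "os")$p
    }
    out
  })
}
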