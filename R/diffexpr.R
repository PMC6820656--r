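#' Moderated two-group t-statistics with empirical-Bayes variance shrinkage
#'
#' Fits the standard two-group model to every feature of a log2 expression
#' matrix and moderates the per-feature residual variances towards a common
#' prior.  The prior degrees of freedom `d0` and prior variance `s0_sq` are
#' estimated by matching the first two moments of `log(s^2)` to a scaled-F
#' model (the closed-form empirical-Bayes estimator used throughout the
#' microarray literature).  The moderated statistic for feature g is
#' \deqn{t_g = \frac{\bar x_{R,g} - \bar x_{S,g}}
#'                  {\tilde s_g \sqrt{1/n_S + 1/n_R}},\qquad
#'       \tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}}
#' with two-sided p-values from a t distribution on `d0 + d` degrees of
#' freedom.  Fold change is `2^log2fc` with the resistant group in the
#' numerator.
#'
#' Setting `d0 = 0` disables shrinkage (ordinary pooled-variance t);
#' `d0 = Inf` shrinks every variance fully to `s0_sq`.  If moment matching
#' yields a non-finite `d0`, the fit falls back to `d0 = Inf` with a warning.
#'
#' A feature with zero variance in both groups and zero mean difference gets
#' `t = 0, p = 1`; if every feature has zero residual variance the prior is
#' inestimable and a degenerate-input error is raised.
#'
#' @param expr Wide expression tibble (`feature_id` + one column per sample),
#'   log2 scale.
#' @param groups Tibble with columns `sample_id`, `group`
#'   (sensitive/resistant); at least 2 samples per group.
#' @param d0,s0_sq Optional overrides of the prior; `NULL` (default)
#'   estimates them from the data.
#' @param fc_hi,fc_lo,alpha Differential-expression cutoffs applied to the
#'   `is_de` flag: `2^log2fc > fc_hi` or `< fc_lo`, and BH-adjusted p
#'   `< alpha` (all strict).
#' @return An object of class `mirvuln_de`: list with `table` (tibble:
#'   `feature_id`, `log2fc`, `t_mod`, `df_total`, `p`, `adj_p`, `is_de`) and
#'   `params` (`d0`, `s0_sq`, `df_residual`, group sizes, cutoffs).
#' @seealso [filter_de()], [bh_adjust()]
#' @export
moderated_t <- function(expr, groups, d0 = NULL, s0_sq = NULL,
                        fc_hi = 1.5, fc_lo = 0.67, alpha = 0.05) {
  expr <- validate_expression(expr)
  groups <- validate_groups(groups)
  x <- expr_matrix(expr)
  common <- intersect(colnames(x), groups$sample_id)
  if (length(common) < ncol(x)) {
    warn(sprintf("%d sample(s) without group labels dropped.",
                 ncol(x) - length(common)))
  }
  x <- x[, common, drop = FALSE]
  lab <- groups$group[match(common, groups$sample_id)]
  n1 <- sum(lab == "sensitive")
  n2 <- sum(lab == "resistant")
  if (n1 < 2 || n2 < 2) {
    stop_parameter("need at least 2 samples per group.")
  }
  d <- n1 + n2 - 2

  xs <- x[, lab == "sensitive", drop = FALSE]
  xr <- x[, lab == "resistant", drop = FALSE]
  m1 <- rowMeans(xs)
  m2 <- rowMeans(xr)
  log2fc <- m2 - m1
  ss <- rowSums((xs - m1)^2) + rowSums((xr - m2)^2)
  s2 <- ss / d

  est <- estimate_variance_prior(s2, d)
  if (is.null(d0)) d0 <- est$d0
  if (is.null(s0_sq)) s0_sq <- est$s0_sq
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0) {
    stop_parameter("`d0` must be a single number >= 0 (Inf allowed).")
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                  log2fc / se)
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_mod), df = df_total)
  adj_p <- bh_adjust(p)
  is_de <- (2^log2fc > fc_hi | 2^log2fc < fc_lo) & adj_p < alpha

  structure(list(
    table = tibble::tibble(
      feature_id = expr$feature_id,
      log2fc = unname(log2fc), t_mod = unname(t_mod),
      df_total = df_total, p = unname(p), adj_p = unname(adj_p),
      is_de = unname(is_de)
    ),
    params = list(
      d0 = d0, s0_sq = s0_sq, df_residual = d,
      n_sensitive = n1, n_resistant = n2,
      fc_hi = fc_hi, fc_lo = fc_lo, alpha = alpha
    )
  ), class = "mirvuln_de")
}

# Closed-form moment matching of log residual variances to a scaled-F model:
# e_g = log(s_g^2) - digamma(d/2) + log(d/2) has mean log(s0^2) +
# digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2) beyond the
# sampling term trigamma(d/2).  Non-positive variances are excluded from the
# moment fit (they carry no scale information on the log scale).
estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) {
    stop_degenerate(
      "all features have zero residual variance; variance prior inestimable."
    )
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (length(e) < 2 || !is.finite(evar)) evar <- 0
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0)) {
      warn("moment matching gave non-finite prior df; falling back to d0 = Inf.")
      return(list(d0 = Inf, s0_sq = exp(emean)))
    }
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0_sq = s0_sq)
  } else {
    list(d0 = Inf, s0_sq = exp(emean))
  }
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma,
# which is nearly linear; asymptotic starts cover the extremes.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input order.
#'
#' @param pvalues Numeric vector with all values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop_parameter("`pvalues` must all lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Filter a differential-expression result to significant feature IDs
#'
#' Applies the fold-change window and adjusted-p cutoff with strict
#' inequalities: a feature passes iff `2^log2fc > fc_hi` or
#' `2^log2fc < fc_lo`, and `adj_p < alpha`.  Output preserves input order.
#'
#' @param de A `mirvuln_de` object or its [tidy()] table.
#' @param fc_hi,fc_lo,alpha Cutoffs (defaults 1.5, 0.67, 0.05).
#' @return Character vector of differentially expressed feature IDs.
#' @export
filter_de <- function(de, fc_hi = 1.5, fc_lo = 0.67, alpha = 0.05) {
  tab <- if (inherits(de, "mirvuln_de")) de$table else tibble::as_tibble(de)
  if (!all(c("feature_id", "log2fc", "adj_p") %in% names(tab))) {
    stop_parameter("`de` must carry feature_id, log2fc and adj_p.")
  }
  if (!(0 < fc_lo && fc_lo < 1 && fc_hi > 1)) {
    stop_parameter("need 0 < fc_lo < 1 < fc_hi.")
  }
  keep <- (2^tab$log2fc > fc_hi | 2^tab$log2fc < fc_lo) & tab$adj_p < alpha
  tab$feature_id[keep]
}

#' @export
tidy.mirvuln_de <- function(x, ...) x$table

#' @export
glance.mirvuln_de <- function(x, ...) {
  tibble::tibble(
    d0 = x$params$d0, s0_sq = x$params$s0_sq,
    df_residual = x$params$df_residual,
    n_sensitive = x$params$n_sensitive, n_resistant = x$params$n_resistant,
    n_features = nrow(x$table), n_de = sum(x$table$is_de)
  )
}

#' @export
print.mirvuln_de <- function(x, ...) {
  cat(sprintf(
    "Moderated differential expression: %d features, %d DE (d0 = %.3g, s0^2 = %.3g)\n",
    nrow(x$table), sum(x$table$is_de), x$params$d0, x$params$s0_sq
  ))
  print(x$table, n = 6)
  invisible(x)
}

#' Volcano plot of a moderated differential-expression result
#'
#' @param object A `mirvuln_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirvuln_de <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$adj_p), colour = .data$is_de
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = log2(c(object$params$fc_lo, object$params$fc_hi)),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "DE") +
    ggplot2::labs(x = "log2 fold change (resistant / sensitive)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
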