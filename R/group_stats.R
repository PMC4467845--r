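# One-way ANOVA from explicit sums of squares and Tukey HSD pairwise
# comparisons (Tukey-Kramer for unbalanced groups).

#' One-way analysis of variance
#'
#' F = MS_between / MS_within computed from the explicit between- and
#' within-group sums of squares; the p-value is the upper tail of the
#' F(df_between, df_within) distribution.
#'
#' @param groups named list mapping group label to a numeric vector of
#'   observations (each group needs >= 2 values).
#' @return object of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `ms_within`, `group_sizes`.
#' @export
oneway_anova <- function(groups) {
  cmp <- anova_components(groups)
  if (cmp$msw == 0 && cmp$ssb == 0) {
    stop("F undefined: zero variance both between and within groups",
         call. = FALSE)
  }
  f <- if (cmp$msw == 0) Inf else (cmp$ssb / cmp$dfb) / cmp$msw
  p <- stats::pf(f, cmp$dfb, cmp$dfw, lower.tail = FALSE)
  structure(list(
    f_statistic = f, df_between = cmp$dfb, df_within = cmp$dfw, p_value = p,
    group_means = cmp$means, ms_within = cmp$msw, group_sizes = cmp$sizes
  ), class = "anova_result")
}

anova_components <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all_x) - length(groups)
  list(means = means, sizes = sizes, ssb = ssb, ssw = ssw,
       dfb = dfb, dfw = dfw, msw = ssw / dfw)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Critical difference per pair = q(1 - alpha; k, df_within) x
#' sqrt(MS_within / n_h), with n_h the harmonic mean of the two group
#' sizes (Tukey-Kramer), so unbalanced designs are handled. A pair is
#' significant when |mean difference| exceeds its critical difference.
#'
#' @param groups as in [oneway_anova()].
#' @param alpha family-wise significance level, in (0, 1) (default 0.05).
#' @return object of class `tukey_result`: data.frame `pairwise` with
#'   `group_a`, `group_b`, `mean_difference`, `critical_difference`,
#'   `p_adj`, `significant`; plus `alpha` and the underlying
#'   `anova_result`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  cmp <- anova_components(groups)
  # degenerate all-identical data: F is undefined but every pairwise
  # difference is zero, so report no significant pairs instead of erroring
  an <- if (cmp$msw == 0 && cmp$ssb == 0) {
    structure(list(f_statistic = NA_real_, df_between = cmp$dfb,
                   df_within = cmp$dfw, p_value = NA_real_,
                   group_means = cmp$means, ms_within = cmp$msw,
                   group_sizes = cmp$sizes), class = "anova_result")
  } else oneway_anova(groups)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("group", seq_len(k))
  q_crit <- stats::qtukey(1 - alpha, k, an$df_within)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    n_h <- 2 / (1 / an$group_sizes[a] + 1 / an$group_sizes[b])
    se <- sqrt(an$ms_within / n_h)
    diff <- an$group_means[b] - an$group_means[a]
    q_obs <- if (se > 0) abs(diff) / se else ifelse(diff == 0, 0, Inf)
    data.frame(
      group_a = labs[a], group_b = labs[b],
      mean_difference = unname(diff),
      critical_difference = q_crit * se,
      p_adj = stats::ptukey(q_obs, k, an$df_within, lower.tail = FALSE),
      significant = abs(diff) > q_crit * se,
      stringsAsFactors = FALSE
    )
  })
  structure(list(pairwise = do.call(rbind, rows), alpha = alpha,
                 anova = an), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD at alpha = %g\n", x$alpha))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Location-comparison significance report
#'
#' Runs one-way ANOVA and Tukey HSD across locations for every nuclide
#' (activity table) or element (metal table) and returns a list suitable
#' for JSON serialisation.
#'
#' @param tbl long-format table with `location` plus either `nuclide` and
#'   `activity_Bq_per_kg`, or `element` and `concentration_mg_per_kg`.
#' @param alpha significance level for the Tukey step.
#' @return named list keyed by nuclide/element with `f_statistic`, `df`,
#'   `p_value`, `group_means` and the pairwise Tukey table.
#' @export
significance_report <- function(tbl, alpha = 0.05) {
  if ("nuclide" %in% names(tbl)) {
    key <- "nuclide"; val <- "activity_Bq_per_kg"
  } else if ("element" %in% names(tbl)) {
    key <- "element"; val <- "concentration_mg_per_kg"
  } else {
    stop("expected a 'nuclide' or 'element' column", call. = FALSE)
  }
  out <- list()
  for (g in unique(tbl[[key]])) {
    sub <- tbl[tbl[[key]] == g & !is.na(tbl[[val]]), ]
    groups <- split(sub[[val]], sub$location)
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (length(groups) < 2) next
    tk <- tukey_hsd(groups, alpha = alpha)
    an <- tk$anova
    out[[g]] <- list(
      f_statistic = an$f_statistic,
      df = c(an$df_between, an$df_within),
      p_value = an$p_value,
      group_means = as.list(an$group_means),
      tukey = tk$pairwise
    )
  }
  out
}
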