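#' Build a long-format group table
#'
#' One row per (condition, unit, metric, value); all group comparisons in
#' the package flow through this single shape, so any per-object or
#' per-cell metric can be compared with the same code path.
#'
#' @param condition character vector of group labels.
#' @param id unit identifier (object or cell).
#' @param metric metric name.
#' @param value numeric, finite.
#' @return data.frame of class `group_table`.
#' @export
group_table <- function(condition, id, metric, value) {
  if (any(!is.finite(value))) stop("values must be finite", call. = FALSE)
  structure(data.frame(condition = as.character(condition), id = id,
                       metric = as.character(metric), value = as.numeric(value)),
            class = c("group_table", "data.frame"))
}

#' Significance stars for a p-value
#'
#' The reporting convention `*p<0.05, **p<0.01, ***p<0.001, ****p<0.0001`;
#' raw p-values are always emitted alongside.
#' @param p numeric p-value(s).
#' @return character vector of stars ("ns" when p >= 0.05).
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****" else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**" else if (pp < 0.05) "*" else "ns"
  }, "")
}

#' Compare a metric between experimental groups
#'
#' Three designs, matching the study's reporting conventions:
#' \describe{
#'   \item{`ttest`}{unpaired two-tailed Student's t (pooled variance), two
#'     groups.}
#'   \item{`anova_plsd`}{one-way ANOVA followed by Fisher's *protected*
#'     least significant difference: pairwise t-tests on the pooled ANOVA
#'     mean-square error with `N - k` degrees of freedom, performed only
#'     when the omnibus F-test has p < 0.05 (weaker family-wise control
#'     than Tukey, by design). Requires >= 3 groups.}
#'   \item{`ks`}{two-sample Kolmogorov-Smirnov on the empirical
#'     distributions, two groups.}
#' }
#' Zero pooled variance is flagged as a degenerate result (p = NA) rather
#' than an error.
#'
#' @param table a [group_table()] (or any data.frame with columns
#'   condition, metric, value).
#' @param metric which metric to compare.
#' @param design `"ttest"`, `"anova_plsd"` or `"ks"`.
#' @return a `stats_result`: list with `test`, `statistic`, `p_value`,
#'   `posthoc` (data.frame of pairwise LSD results, or NULL), `n_per_group`,
#'   `degenerate`, `stars`.
#' @export
compare_groups <- function(table, metric,
                           design = c("ttest", "anova_plsd", "ks")) {
  design <- match.arg(design)
  d <- table[table$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("metric '", metric, "' not found", call. = FALSE)
  groups <- split(d$value, d$condition)
  k <- length(groups)
  if (k < 2L) stop("need >= 2 conditions, got ", k, call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs >= 2 values", call. = FALSE)
  n_per <- vapply(groups, length, 1L)

  if (design == "ttest") {
    if (k != 2L) stop("ttest requires exactly 2 conditions", call. = FALSE)
    x <- groups[[1]]; y <- groups[[2]]
    pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
      (length(x) + length(y) - 2)
    if (pooled_var <= 0) {
      return(structure(list(test = "ttest", statistic = NA_real_,
                            p_value = NA_real_, posthoc = NULL,
                            n_per_group = n_per, degenerate = TRUE,
                            stars = NA_character_), class = "stats_result"))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(test = "ttest", statistic = unname(tt$statistic),
                p_value = tt$p.value, posthoc = NULL, n_per_group = n_per,
                degenerate = FALSE, stars = p_stars(tt$p.value))
  } else if (design == "ks") {
    if (k != 2L) stop("ks requires exactly 2 conditions", call. = FALSE)
    kt <- suppressWarnings(stats::ks.test(groups[[1]], groups[[2]]))
    res <- list(test = "ks", statistic = unname(kt$statistic),
                p_value = kt$p.value, posthoc = NULL, n_per_group = n_per,
                degenerate = FALSE, stars = p_stars(kt$p.value))
  } else {
    if (k < 3L) stop("anova_plsd requires >= 3 conditions", call. = FALSE)
    N <- sum(n_per)
    gm <- mean(d$value)
    means <- vapply(groups, mean, 1.0)
    ss_between <- sum(n_per * (means - gm)^2)
    ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
    df1 <- k - 1L; df2 <- N - k
    mse <- ss_within / df2
    if (mse <= 0) {
      return(structure(list(test = "anova_plsd", statistic = NA_real_,
                            p_value = NA_real_, posthoc = NULL,
                            n_per_group = n_per, degenerate = TRUE,
                            stars = NA_character_), class = "stats_result"))
    }
    Fstat <- (ss_between / df1) / mse
    p_omni <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    posthoc <- NULL
    if (p_omni < 0.05) {
      cmb <- utils::combn(names(groups), 2L)
      posthoc <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
        a <- cmb[1, i]; b <- cmb[2, i]
        se <- sqrt(mse * (1 / n_per[[a]] + 1 / n_per[[b]]))
        tv <- (means[[a]] - means[[b]]) / se
        data.frame(group1 = a, group2 = b, diff = means[[a]] - means[[b]],
                   t = tv, df = df2,
                   p = 2 * stats::pt(-abs(tv), df2))
      }))
      posthoc$stars <- p_stars(posthoc$p)
      rownames(posthoc) <- NULL
    }
    res <- list(test = "anova_plsd", statistic = Fstat, p_value = p_omni,
                posthoc = posthoc, n_per_group = n_per, degenerate = FALSE,
                stars = p_stars(p_omni))
  }
  structure(res, class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("<stats_result> %s: statistic = %.4g, p = %.4g %s\n",
              x$test, x$statistic, x$p_value,
              if (is.na(x$stars)) "(degenerate)" else paste0("[", x$stars, "]")))
  if (!is.null(x$posthoc)) {
    cat("protected LSD pairwise comparisons:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
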