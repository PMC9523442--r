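#' Significance stars for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, empty
#' otherwise (strict inequalities).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star annotations.
#' @examples
#' star_annotation(c(0.0009, 0.04, 0.05))
#' @export
star_annotation <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Games-Howell post-hoc comparisons
#'
#' Pairwise comparisons after a Welch ANOVA, appropriate when group variances
#' are unequal: for each pair the Welch t statistic is referred to the
#' studentized range distribution with Welch-Satterthwaite degrees of
#' freedom, \eqn{p = P(q_{k,\nu} > |t|\sqrt{2})}.
#'
#' @param data Data frame with a grouping column and a value column.
#' @param group,value Column names (strings).
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference), `se`, `df`, `statistic`, `p_value`.
#' @export
games_howell <- function(data, group = "group", value = "value") {
  stats_tbl <- data |>
    dplyr::group_by(g = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data[[value]]),
                     v = stats::var(.data[[value]]), .groups = "drop")
  k <- nrow(stats_tbl)
  if (k < 2) rlang::abort("Need at least two groups.")
  pairs <- utils::combn(seq_len(k), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    n1 <- stats_tbl$n[i1]; n2 <- stats_tbl$n[i2]
    v1 <- stats_tbl$v[i1]; v2 <- stats_tbl$v[i2]
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    est <- stats_tbl$m[i1] - stats_tbl$m[i2]
    tstat <- est / sqrt(se2)
    tibble::tibble(
      group1 = as.character(stats_tbl$g[i1]),
      group2 = as.character(stats_tbl$g[i2]),
      estimate = est,
      se = sqrt(se2),
      df = df,
      statistic = tstat,
      p_value = stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                              lower.tail = FALSE)
    )
  })
}

#' Group comparison by the normality/variance decision tree
#'
#' Implements the standard comparison workflow for experimental group means:
#' a Shapiro-Wilk test per group is run first, then Bartlett's test for
#' variance homogeneity. Two groups are compared with an independent
#' Student's t-test, Welch-corrected when Bartlett rejects homogeneity.
#' More than two groups are compared with a one-way ANOVA followed by
#' Tukey's HSD when variances are homogeneous, or a Welch ANOVA followed by
#' Games-Howell post-hoc comparisons when they are not. If any group fails
#' the normality check the comparison proceeds on the chosen branch and the
#' violation is flagged (no nonparametric fallback is substituted).
#'
#' @param data Tidy data frame with a grouping column and a value column.
#' @param group,value Column names (strings).
#' @param alpha Significance level gating Bartlett's decision and the stars.
#' @return A `group_comparison` object; see [tidy.group_comparison()] for the
#'   pairwise table and [glance.group_comparison()] for the test choice.
#' @examples
#' df <- data.frame(group = rep(c("a", "b"), each = 10),
#'                  value = c(rnorm(10), rnorm(10, 1)))
#' decide_and_compare(df)
#' @export
decide_and_compare <- function(data, group = "group", value = "value",
                               alpha = 0.05) {
  stopifnot(is.data.frame(data), alpha > 0, alpha < 1)
  data <- dplyr::filter(data, !is.na(.data[[value]]))
  groups <- split(data[[value]], data[[group]])
  k <- length(groups)
  if (k < 2) rlang::abort("Need at least two groups.")
  ns <- vapply(groups, length, integer(1))

  flags <- character(0)
  if (any(ns < 3)) {
    return(structure(
      list(chosen_test = NA_character_, normality_p = NULL,
           variance_homogeneity_p = NA_real_, omnibus_p = NA_real_,
           pairwise = tibble::tibble(), alpha = alpha, n = ns,
           flags = "group(s) with fewer than 3 values; comparison skipped"),
      class = "group_comparison"))
  }
  if (any(vapply(groups, function(x) stats::var(x) == 0, logical(1)))) {
    return(structure(
      list(chosen_test = NA_character_, normality_p = NULL,
           variance_homogeneity_p = NA_real_, omnibus_p = NA_real_,
           pairwise = tibble::tibble(), alpha = alpha, n = ns,
           flags = "degenerate constant group(s); comparison skipped"),
      class = "group_comparison"))
  }

  normality_p <- vapply(groups, function(x) stats::shapiro.test(x)$p.value,
                        numeric(1))
  if (any(normality_p < alpha)) {
    flags <- c(flags, "normality violated in at least one group")
  }
  bart_p <- stats::bartlett.test(data[[value]], factor(data[[group]]))$p.value
  homogeneous <- bart_p >= alpha

  if (k == 2) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = homogeneous)
    chosen <- if (homogeneous) "student_t" else "welch_t"
    pairwise <- tibble::tibble(
      group1 = names(groups)[1], group2 = names(groups)[2],
      estimate = mean(groups[[1]]) - mean(groups[[2]]),
      p_value = tt$p.value
    )
    omnibus_p <- tt$p.value
  } else {
    f <- factor(data[[group]])
    if (homogeneous) {
      chosen <- "anova_tukey"
      fit <- stats::aov(data[[value]] ~ f)
      omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$f
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- tibble::tibble(
        group1 = vapply(nm, `[`, "", 1),
        group2 = vapply(nm, `[`, "", 2),
        estimate = tk[, "diff"],
        p_value = tk[, "p adj"]
      )
    } else {
      chosen <- "welch_anova_games_howell"
      omnibus_p <- stats::oneway.test(data[[value]] ~ f,
                                      var.equal = FALSE)$p.value
      pairwise <- games_howell(data, group, value)[
        c("group1", "group2", "estimate", "p_value")]
    }
  }
  pairwise$stars <- star_annotation(pairwise$p_value)
  structure(
    list(chosen_test = chosen,
         normality_p = normality_p,
         variance_homogeneity_p = bart_p,
         omnibus_p = omnibus_p,
         pairwise = pairwise,
         alpha = alpha,
         n = ns,
         flags = if (length(flags)) flags else NULL),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  if (is.na(x$chosen_test %||% NA)) {
    cat("  skipped:", x$flags, "\n")
    return(invisible(x))
  }
  cat("  test:", x$chosen_test,
      sprintf("(Bartlett p = %.3g)\n", x$variance_homogeneity_p))
  if (!is.null(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Pairwise comparison table
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return A tibble with `group1`, `group2`, `estimate`, `p_value`, `stars`.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with the chosen test, gate p-values, the
#'   omnibus p-value and flags.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    chosen_test = x$chosen_test,
    min_normality_p = if (is.null(x$normality_p)) NA_real_ else min(x$normality_p),
    variance_homogeneity_p = x$variance_homogeneity_p,
    omnibus_p = x$omnibus_p,
    n_groups = length(x$n),
    flags = paste(x$flags %||% "", collapse = "; ")
  )
}
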