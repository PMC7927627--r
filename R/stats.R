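# Group-comparison statistics matching the reporting conventions of the
# quantification pipeline (mean ± sem; Student's t for two groups, one-way
# ANOVA with Tukey-Kramer pairwise comparisons for more), plus the
# rank-based ECDF colormap transform used for expression heatmaps.

#' Compare groups of measurements
#'
#' Two groups: two-sided equal-variance Student's t-test (Welch available
#' via `welch = TRUE`). More than two groups: one-way ANOVA followed by
#' Tukey-Kramer multiple comparisons (honest significant differences with
#' unequal group sizes). Groups with zero pooled variance are flagged
#' degenerate rather than producing an error.
#'
#' @param samples named list of numeric vectors, one per group (each
#'   n >= 2).
#' @param welch use the Welch (unequal-variance) t-test for two groups.
#' @return a `group_comparison` list: `groups` (data.frame: label, n, mean,
#'   sem), `test` ("two_sample_t" or "one_way_anova_tukey"), `statistic`,
#'   `p_value`, `pairwise` (data.frame for the ANOVA path), `degenerate`.
#' @examples
#' compare_groups(list(a = rnorm(10), b = rnorm(10, 1)))
#' @export
compare_groups <- function(samples, welch = FALSE) {
  if (!is.list(samples) || length(samples) < 2L)
    stopf("need at least two groups")
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  ns <- vapply(samples, length, integer(1L))
  if (any(ns < 2L)) stopf("every group needs n >= 2")
  groups <- data.frame(label = names(samples), n = ns,
                       mean = vapply(samples, mean, numeric(1L)),
                       sem = vapply(samples, sem, numeric(1L)),
                       row.names = NULL)
  vars <- vapply(samples, stats::var, numeric(1L))
  degenerate <- all(vars == 0)
  if (length(samples) == 2L) {
    if (degenerate) {
      res <- list(statistic = NA_real_, p_value = NA_real_)
    } else {
      tt <- stats::t.test(samples[[1L]], samples[[2L]],
                          var.equal = !welch)
      res <- list(statistic = unname(tt$statistic),
                  p_value = tt$p.value)
    }
    out <- list(groups = groups, test = "two_sample_t",
                statistic = res$statistic, p_value = res$p_value,
                pairwise = NULL, degenerate = degenerate)
  } else {
    values <- unlist(samples, use.names = FALSE)
    g <- factor(rep(names(samples), ns), levels = names(samples))
    if (degenerate) {
      out <- list(groups = groups, test = "one_way_anova_tukey",
                  statistic = NA_real_, p_value = NA_real_,
                  pairwise = NULL, degenerate = TRUE)
    } else {
      fit <- stats::aov(values ~ g)
      an <- summary(fit)[[1L]]
      tk <- stats::TukeyHSD(fit)$g
      pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                             lwr = tk[, "lwr"], upr = tk[, "upr"],
                             p_adj = tk[, "p adj"], row.names = NULL)
      out <- list(groups = groups, test = "one_way_anova_tukey",
                  statistic = an[["F value"]][1L],
                  p_value = an[["Pr(>F)"]][1L],
                  pairwise = pairwise, degenerate = FALSE)
    }
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s%s\n", x$test,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  print(x$groups, row.names = FALSE)
  if (!is.na(x$p_value))
    cat(sprintf("statistic = %.4g, p = %.4g %s\n", x$statistic, x$p_value,
                significance_stars(x$p_value)))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

# Display-only significance stars at the conventional reporting thresholds.
significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 1e-4) "***" else if (p < 5e-3) "**"
  else if (p < 0.05) "*" else "n.s."
}

#' Rank-based ECDF colormap transform
#'
#' Maps each value to its empirical cumulative distribution position
#' (average rank for ties, scaled to (0, 1]), so that distinct sorted
#' values become equally spaced: indexing a colormap on the transformed
#' values gives equal color separation between data points regardless of
#' their numeric spacing. Depends only on ranks, hence invariant under any
#' strictly increasing transform of the input.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector in (0, 1]; NAs propagate.
#' @examples
#' ecdf_colormap_transform(c(1, 10, 100, 1000))  # 0.25 0.50 0.75 1.00
#' @export
ecdf_colormap_transform <- function(values) {
  if (!length(values)) stopf("empty input")
  ok <- is.finite(values)
  if (!any(ok)) stopf("no finite values")
  out <- rep(NA_real_, length(values))
  out[ok] <- rank(values[ok], ties.method = "average") / sum(ok)
  out
}

#' Apply the ECDF transform over a matrix at a chosen scope
#'
#' @param mat numeric matrix (e.g. genes x samples).
#' @param scope `"global"` (one ECDF over all entries), `"row"` or
#'   `"column"`.
#' @return matrix of the same shape with transformed entries.
#' @export
ecdf_transform_matrix <- function(mat, scope = c("global", "row", "column")) {
  scope <- match.arg(scope)
  switch(scope,
    global = matrix(ecdf_colormap_transform(as.vector(mat)), nrow(mat),
                    ncol(mat), dimnames = dimnames(mat)),
    row = t(apply(mat, 1L, ecdf_colormap_transform)),
    column = apply(mat, 2L, ecdf_colormap_transform))
}
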