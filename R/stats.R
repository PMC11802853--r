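#' Multivariate group comparison via MANOVA (Pillai's trace)
#'
#' Compares a sample x feature matrix between groups with a two-sided
#' multivariate analysis of variance using Pillai's trace and its F
#' approximation. Zero-variance features are dropped and reported via
#' `attr(, "dropped")`. With a single (post-drop) feature the comparison
#' reduces to a univariate ANOVA. When the within-group covariance is
#' singular (e.g. more features than residual degrees of freedom) the
#' function falls back to feature-wise univariate tests with a warning and
#' reports the smallest Benjamini-Hochberg-adjusted p-value.
#'
#' @param x numeric matrix (samples x features) or data.frame.
#' @param groups group label per row; >= 2 groups with >= 2 samples each.
#' @return list of class `group_comparison`: `statistic` (Pillai's trace,
#'   `NA` on fallback), `p_value`, `per_feature` (data.table `feature`,
#'   `p_value`, `direction`), `method`.
#' @export
manova_compare <- function(x, groups) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  vars <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[vars == 0]
  keep <- which(vars > 0)
  if (!length(keep)) {
    # all features constant: groups are indistinguishable
    out <- list(statistic = 0, p_value = 1,
                per_feature = data.table::data.table(
                  feature = character(), p_value = numeric(),
                  direction = numeric()),
                method = "degenerate")
    class(out) <- "group_comparison"
    attr(out, "dropped") <- dropped
    return(out)
  }
  x <- x[, keep, drop = FALSE]
  glev <- levels(droplevels(groups))
  direction <- if (length(glev) == 2L) {
    vapply(seq_len(ncol(x)), function(j) {
      sign(mean(x[groups == glev[1L], j]) - mean(x[groups == glev[2L], j]))
    }, numeric(1))
  } else rep(NA_real_, ncol(x))
  per_feature <- data.table::data.table(
    feature = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    p_value = vapply(seq_len(ncol(x)), function(j) {
      stats::anova(stats::lm(x[, j] ~ groups))[["Pr(>F)"]][1L]
    }, numeric(1)),
    direction = direction)
  if (ncol(x) == 1L) {
    out <- list(statistic = NA_real_, p_value = per_feature$p_value[1L],
                per_feature = per_feature, method = "anova")
  } else {
    fit <- tryCatch({
      m <- stats::manova(x ~ groups)
      sm <- summary(m, test = "Pillai")
      st <- sm$stats
      list(statistic = st[1L, "Pillai"], p_value = st[1L, "Pr(>F)"])
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$p_value)) {
      warning("singular within-group covariance; falling back to ",
              "feature-wise univariate tests", call. = FALSE)
      out <- list(statistic = NA_real_,
                  p_value = min(stats::p.adjust(per_feature$p_value, "BH")),
                  per_feature = per_feature, method = "univariate_fallback")
    } else {
      out <- list(statistic = unname(fit$statistic),
                  p_value = unname(fit$p_value),
                  per_feature = per_feature, method = "manova_pillai")
    }
  }
  class(out) <- "group_comparison"
  attr(out, "dropped") <- dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample cell-type composition table
#'
#' Tabulates, per sample, the proportion of cells in each category of a
#' label column; proportions sum to 1 within the chosen denominator and
#' zero-count categories are included as 0. With `within` set (e.g. a
#' lineage column), proportions are computed inside each (sample, within)
#' stratum instead of over all cells of the sample.
#'
#' @param meta per-cell metadata.
#' @param label_col column holding the category labels.
#' @param sample_col sample identifier column (default `"sample_id"`).
#' @param within optional column defining the denominator stratum.
#' @return data.table `sample_id`, optional stratum column, `label`, `n`,
#'   `prop`.
#' @export
composition_table <- function(meta, label_col = "subset",
                              sample_col = "sample_id", within = NULL) {
  dt <- data.table::as.data.table(meta)
  stopifnot(label_col %in% names(dt), sample_col %in% names(dt))
  levs <- sort(unique(dt[[label_col]]))
  bycols <- c(sample_col, within)
  out <- dt[, {
    tab <- table(factor(get(label_col), levels = levs))
    data.table::data.table(label = levs, n = as.integer(tab),
                           prop = as.numeric(tab) / sum(tab))
  }, by = bycols]
  data.table::setorderv(out, c(bycols, "label"))
  out[]
}
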