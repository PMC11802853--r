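#' Signature module score with bin-matched control genes
#'
#' Per cell, the score is the mean log-normalised expression of the set
#' genes minus the mean over control genes. Controls are drawn per set
#' gene: genes are ranked by dataset-mean log-normalised expression and cut
#' into `n_bins` equal-frequency bins; `n_ctrl` control genes are sampled
#' (seeded) from the bin of each set gene, and the control mean is taken
#' over the drawn multiset. Counts are library-size normalised to 10,000
#' and log1p-transformed internally.
#'
#' @param mat genes x cells raw count matrix.
#' @param gene_set character vector of set genes.
#' @param n_bins number of average-expression bins (default 24; the matrix
#'   must contain at least `n_bins` genes).
#' @param n_ctrl control genes drawn per set gene (default 100; sampled
#'   with replacement only when a bin is smaller than `n_ctrl`).
#' @param seed integer seed for the control draw.
#' @return data.table `cell_id`, `score`, with parameters in attributes.
#' @export
module_score <- function(mat, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  genes <- rownames(mat)
  if (length(genes) < n_bins) {
    stop("matrix must contain at least n_bins genes", call. = FALSE)
  }
  present <- intersect(gene_set, genes)
  if (!length(present)) {
    stop("no gene of the set is in the matrix; missing: ",
         paste(gene_set, collapse = ", "), call. = FALSE)
  }
  libs <- Matrix::colSums(mat)
  libs[libs == 0] <- 1
  ln <- log1p(t(t(as.matrix(mat)) / libs) * 1e4)
  avg <- rowMeans(ln)
  # equal-frequency bins on the rank of the dataset-mean expression
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / (length(genes) / n_bins))
  bin <- pmin(bin, n_bins)
  names(bin) <- genes
  ctrl_genes <- withr::with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- genes[bin == bin[[g]]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- colMeans(ln[present, , drop = FALSE])
  ctrl_mean <- colMeans(ln[ctrl_genes, , drop = FALSE])
  out <- data.table::data.table(cell_id = colnames(mat) %||%
                                  paste0("cell", seq_len(ncol(mat))),
                                score = unname(set_mean - ctrl_mean))
  data.table::setattr(out, "params",
                      list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                           genes_used = present))
  out[]
}

#' Learn a classification threshold between two score distributions
#'
#' Fits a univariate logistic regression of class (positive = 1) on score
#' and returns the score at which the predicted probability is 0.5. If the
#' groups are perfectly separable the threshold is the midpoint of the
#' separating gap; if the distributions are indistinguishable a warning is
#' raised and the pooled median returned.
#'
#' @param scores_positive scores of the known-positive population (e.g.
#'   dendritic cells for the pAPC score).
#' @param scores_negative scores of the known-negative population (e.g.
#'   CD8 T cells).
#' @return numeric threshold.
#' @export
fit_score_threshold <- function(scores_positive, scores_negative) {
  stopifnot(length(scores_positive) > 0, length(scores_negative) > 0)
  pos <- scores_positive[is.finite(scores_positive)]
  neg <- scores_negative[is.finite(scores_negative)]
  if (max(neg) < min(pos)) return((max(neg) + min(pos)) / 2)
  if (max(pos) < min(neg)) return((max(pos) + min(neg)) / 2)
  x <- c(pos, neg)
  y <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  b <- stats::coef(fit)
  if (!all(is.finite(b)) || abs(b[2L]) < 1e-10) {
    warning("score distributions are indistinguishable; ",
            "threshold set to the pooled median", call. = FALSE)
    return(stats::median(x))
  }
  unname(-b[1L] / b[2L])
}

#' Classify professional antigen-presenting cells and their pool
#' composition
#'
#' Cells scoring strictly above the learned threshold are flagged as pAPCs;
#' the pool composition is, per patient, the fraction of pAPCs contributed
#' by each cell type (fractions sum to 1 over cell types with >= 1 pAPC).
#'
#' @param scores data.table `cell_id`, `score` from [module_score()].
#' @param threshold learned threshold from [fit_score_threshold()].
#' @param meta per-cell metadata with `cell_id`, `patient` and the cell
#'   type column.
#' @param type_col metadata column naming the cell type (default
#'   `"subset"`).
#' @return list with `cells` (`cell_id`, `score`, `papc`) and
#'   `composition` (`patient`, cell type, `n`, `fraction`).
#' @export
classify_papc <- function(scores, threshold, meta, type_col = "subset") {
  sc <- data.table::as.data.table(scores)
  sc[, papc := score > threshold]
  dt <- merge(sc, data.table::as.data.table(meta), by = "cell_id")
  comp <- dt[papc == TRUE, .(n = .N), by = c("patient", type_col)]
  if (nrow(comp)) comp[, fraction := n / sum(n), by = patient]
  else comp[, fraction := numeric(0)]
  list(cells = sc[], composition = comp[])
}

#' Read gate rules from a YAML file
#'
#' Each rule has a `label`, a unique `priority` (smaller = evaluated
#' first) and a list of `predicates`, each with `feature`, `comparator`
#' (`>`, `>=`, `<`, `<=`, `==`), `threshold` and `aggregation` (`cell`,
#' `cluster-mean` or `cluster-fraction`).
#'
#' @param path YAML file path.
#' @return list of rules suitable for [gate_cells()].
#' @export
read_gate_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- cfg$rules %||% cfg
  lapply(rules, function(r) {
    stopifnot(!is.null(r$label), !is.null(r$priority),
              length(r$predicates) >= 1L)
    r
  })
}

#' Threshold-gate cells or clusters into labels
#'
#' Declarative rule gating: rules are applied in priority order (smaller
#' priority first); the first rule whose predicates all hold assigns its
#' label, remaining cells get the fallback. Predicate aggregations:
#' `cell` uses the per-cell feature value; `cluster-mean` the mean feature
#' value of the cell's cluster; `cluster-fraction` the fraction of the
#' cluster's cells with a nonzero (or TRUE) feature value.
#'
#' @param features data.frame/data.table of per-cell feature columns;
#'   cluster aggregations require a `cluster` column.
#' @param rules list of gate rules (see [read_gate_rules()]); priorities
#'   must be unique and thresholds finite.
#' @param fallback label for cells matching no rule.
#' @return character vector of labels, one per row of `features`.
#' @export
gate_cells <- function(features, rules, fallback = "unassigned") {
  ft <- data.table::as.data.table(features)
  prios <- vapply(rules, function(r) as.numeric(r$priority), numeric(1))
  if (anyDuplicated(prios)) stop("rule priorities must be unique",
                                 call. = FALSE)
  thr_ok <- vapply(rules, function(r) {
    all(vapply(r$predicates,
               function(p) is.finite(as.numeric(p$threshold)), logical(1)))
  }, logical(1))
  if (!all(thr_ok)) stop("rule thresholds must be finite", call. = FALSE)
  labels <- rep(NA_character_, nrow(ft))
  for (r in rules[order(prios)]) {
    mask <- rep(TRUE, nrow(ft))
    for (p in r$predicates) {
      agg <- p$aggregation %||% "cell"
      if (!p$feature %in% names(ft)) {
        stop("rule '", r$label, "' references unknown feature: ",
             p$feature, call. = FALSE)
      }
      v <- ft[[p$feature]]
      if (agg %in% c("cluster-mean", "cluster-fraction")) {
        if (!"cluster" %in% names(ft)) {
          stop("cluster aggregation requires a 'cluster' column",
               call. = FALSE)
        }
        v <- if (agg == "cluster-mean") {
          stats::ave(as.numeric(v), ft$cluster, FUN = mean)
        } else {
          stats::ave(as.numeric(v) != 0, ft$cluster, FUN = mean)
        }
      }
      cmp <- switch(p$comparator,
                    ">" = v > p$threshold, ">=" = v >= p$threshold,
                    "<" = v < p$threshold, "<=" = v <= p$threshold,
                    "==" = v == p$threshold,
                    stop("unknown comparator: ", p$comparator,
                         call. = FALSE))
      mask <- mask & cmp
    }
    assign_now <- is.na(labels) & mask
    labels[assign_now] <- r$label
  }
  labels[is.na(labels)] <- fallback
  labels
}
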