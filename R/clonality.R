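#' Depth-normalised intra-subset clonality
#'
#' Repeatedly subsamples a fixed number of cells (without replacement) from
#' one subset of one sample and measures the percentage of sampled cells
#' whose clone has at least 2 members *within the subsample*; the reported
#' value is the mean over replicates. Recounting clone sizes inside each
#' subsample is what makes the statistic comparable across sequencing
#' depths. Subsets smaller than `depth` return
#' `status = "insufficient_cells"` rather than sampling with replacement.
#'
#' @param clone_ids per-cell clone identifiers for the cells of one subset
#'   and sample (`NA` = unassigned cells, always counted as non-clonal).
#' @param depth cells per subsample (default 5; must be >= 2).
#' @param reps number of subsamples (default 1000).
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @param sample_id,subset identifiers carried into the result.
#' @return one-row data.table (`sample_id`, `subset`, `metric = "intra"`,
#'   `value` in \[0, 100\] or `NA`, `se` Monte-Carlo standard error,
#'   `depth`, `reps`, `n_available`, `status`).
#' @export
intra_subset_clonality <- function(clone_ids, depth = 5L, reps = 1000L,
                                   seed = 1L, sample_id = NA_character_,
                                   subset = NA_character_) {
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  n <- length(clone_ids)
  if (n < depth) {
    return(data.table::data.table(
      sample_id = sample_id, subset = subset, metric = "intra",
      value = NA_real_, se = NA_real_, depth = as.integer(depth),
      reps = as.integer(reps), n_available = n,
      status = "insufficient_cells"))
  }
  cl <- as.character(clone_ids)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      s <- cl[sample.int(n, depth)]
      s <- s[!is.na(s)]
      if (!length(s)) return(0)
      sizes <- table(s)
      100 * sum(sizes[sizes >= 2L]) / depth
    }, numeric(1))
  })
  data.table::data.table(
    sample_id = sample_id, subset = subset, metric = "intra",
    value = mean(vals), se = stats::sd(vals) / sqrt(reps),
    depth = as.integer(depth), reps = as.integer(reps),
    n_available = n, status = "ok")
}

#' Depth-normalised inter-subset clonality
#'
#' Subsamples a fixed number of cells across *all* subsets of one lineage
#' (B, CD4 or CD8) in a sample; within each subsample, a cell counts as
#' clonal when its clone has at least 3 sampled members across all subsets.
#' Per subset, the statistic is the percentage of that subset's sampled
#' cells that are clonal; replicates in which a subset receives no sampled
#' cells contribute no observation for it.
#'
#' @param clone_ids per-cell clone identifiers for all lineage cells of one
#'   sample.
#' @param subsets per-cell subset labels (same length as `clone_ids`).
#' @param depth cells per subsample (default 50; must be >= 2).
#' @param reps number of subsamples (default 1000).
#' @param seed integer seed.
#' @param sample_id identifier carried into the result.
#' @return data.table with one row per subset (`metric = "inter"`; columns
#'   as in [intra_subset_clonality()]).
#' @export
inter_subset_clonality <- function(clone_ids, subsets, depth = 50L,
                                   reps = 1000L, seed = 1L,
                                   sample_id = NA_character_) {
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  stopifnot(length(clone_ids) == length(subsets))
  n <- length(clone_ids)
  subset_levels <- sort(unique(as.character(subsets)))
  if (n < depth) {
    return(data.table::data.table(
      sample_id = sample_id, subset = subset_levels, metric = "inter",
      value = NA_real_, se = NA_real_, depth = as.integer(depth),
      reps = as.integer(reps), n_available = n,
      status = "insufficient_cells"))
  }
  cl <- as.character(clone_ids)
  sub <- as.character(subsets)
  k <- length(subset_levels)
  sums <- numeric(k); sqs <- numeric(k); cnts <- integer(k)
  names(sums) <- names(sqs) <- names(cnts) <- subset_levels
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sample.int(n, depth)
      scl <- cl[idx]; ssub <- sub[idx]
      sizes <- table(scl[!is.na(scl)])
      big <- names(sizes)[sizes >= 3L]
      clonal <- !is.na(scl) & scl %in% big
      for (s in unique(ssub)) {
        here <- ssub == s
        v <- 100 * sum(clonal[here]) / sum(here)
        sums[s] <- sums[s] + v
        sqs[s] <- sqs[s] + v^2
        cnts[s] <- cnts[s] + 1L
      }
    }
  })
  value <- ifelse(cnts > 0L, sums / cnts, NA_real_)
  varv <- ifelse(cnts > 1L, pmax(0, (sqs - sums^2 / cnts) / (cnts - 1L)),
                 NA_real_)
  data.table::data.table(
    sample_id = sample_id, subset = subset_levels, metric = "inter",
    value = as.numeric(value), se = sqrt(varv / pmax(cnts, 1L)),
    depth = as.integer(depth), reps = as.integer(reps),
    n_available = n, status = "ok")
}

#' Per-sample repertoire feature matrix
#'
#' Assembles, per sample, a numeric feature vector of (i) clonality values,
#' (ii) heavy-chain V-gene family usage proportions and (iii) isotype usage
#' proportions, suitable for PCA of repertoire state across samples. The
#' V-usage and isotype blocks each sum to 1 per sample; features missing in
#' a sample are zero-filled and flagged in the attached logical mask
#' `attr(, "observed")`.
#'
#' @param chains chain assignments (with `heavy_v_call`, `heavy_c_call`)
#'   joined to `meta` by `cell_id`.
#' @param meta per-cell metadata with `cell_id` and `sample_id`.
#' @param clonality optional data.table (`sample_id`, `value`) of
#'   clonality estimates to include as a `clonality` column.
#' @param receptor `"BCR"` or `"TCR"`: which receptor class feeds the
#'   usage blocks.
#' @return numeric matrix samples x features.
#' @export
repertoire_feature_matrix <- function(chains, meta, clonality = NULL,
                                      receptor = c("BCR", "TCR")) {
  receptor <- match.arg(receptor)
  dt <- merge(data.table::as.data.table(chains),
              data.table::as.data.table(meta)[, .(cell_id, sample_id)],
              by = "cell_id")
  dt <- dt[receptor_class == receptor & !is.na(heavy_v_call)]
  samples <- sort(unique(dt$sample_id))
  vfam <- gene_family(dt$heavy_v_call)
  vtab <- prop_block(dt$sample_id, vfam, samples, "vgene_")
  iso_ok <- !is.na(dt$heavy_c_call) & dt$heavy_c_call != ""
  itab <- prop_block(dt$sample_id[iso_ok], dt$heavy_c_call[iso_ok],
                     samples, "isotype_")
  out <- cbind(vtab$mat, itab$mat)
  observed <- cbind(vtab$obs, itab$obs)
  if (!is.null(clonality)) {
    cv <- data.table::as.data.table(clonality)
    cvec <- cv$value[match(samples, cv$sample_id)]
    obs_c <- !is.na(cvec)
    cvec[!obs_c] <- 0
    out <- cbind(clonality = cvec, out)
    observed <- cbind(clonality = obs_c, observed)
  }
  rownames(out) <- rownames(observed) <- samples
  attr(out, "observed") <- observed
  out
}

# Proportion block helper: rows samples, cols prefixed categories.
prop_block <- function(sample_id, category, samples, prefix) {
  tab <- table(factor(sample_id, levels = samples), category)
  mat <- unclass(tab)
  obs <- matrix(rowSums(mat) > 0, nrow = nrow(mat), ncol = ncol(mat))
  tot <- pmax(rowSums(mat), 1)
  mat <- mat / tot
  colnames(mat) <- colnames(obs) <- paste0(prefix, colnames(tab))
  list(mat = mat, obs = obs)
}
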