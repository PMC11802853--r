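# Downsample one cell's counts to a UMI target without replacement
# (multivariate hypergeometric); cells at or below the target are kept.
downsample_cell <- function(counts, target) {
  tot <- sum(counts)
  if (tot <= target) return(counts)
  drawn <- sample.int(tot, target)
  # map molecule indices back to genes via cumulative counts
  as.integer(tabulate(findInterval(drawn, cumsum(counts), left.open = TRUE)
                      + 1L, nbins = length(counts)))
}

#' Downsample a count matrix to a fixed number of UMIs per cell
#'
#' @param mat genes x cells count matrix.
#' @param target UMIs per cell; cells below the target are kept as-is.
#' @param seed integer seed.
#' @return dense integer matrix of the same shape.
#' @export
downsample_counts <- function(mat, target = 2000L, seed = 1L) {
  m <- as.matrix(mat)
  withr::with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      m[, j] <- downsample_cell(m[, j], target)
    }
  })
  m
}

#' Gene correlation modules across samples
#'
#' Per sample: cells are downsampled to `umi_target` UMIs, genes with fewer
#' than `min_gene_umis` total UMIs (post-downsampling) are excluded,
#' expression is log(1 + UMI)-transformed and a gene-gene Pearson
#' correlation matrix computed. Correlations are averaged across samples
#' after Fisher z-transformation and transformed back, and genes are
#' grouped by complete-linkage hierarchical clustering of (1 - correlation)
#' distances cut into `n_modules` modules. Only genes eligible in every
#' sample enter the average.
#'
#' @param mats named list of genes x cells count matrices, one per sample.
#' @param umi_target per-cell downsampling depth (default 2000).
#' @param min_gene_umis per-sample minimum gene UMI total (default 5).
#' @param n_modules number of modules to cut the dendrogram into.
#' @param seed integer seed (downsampling).
#' @return named integer vector gene -> module, with the `hclust` tree and
#'   the averaged correlation matrix in attributes.
#' @export
gene_modules <- function(mats, umi_target = 2000L, min_gene_umis = 5L,
                         n_modules = 2L, seed = 1L) {
  stopifnot(length(mats) >= 1L)
  cors <- list()
  for (i in seq_along(mats)) {
    m <- downsample_counts(mats[[i]], umi_target,
                           seed = derive_seed(seed, paste0("ds", i)))
    keep <- rowSums(m) >= min_gene_umis
    m <- log1p(m[keep, , drop = FALSE])
    cors[[i]] <- suppressWarnings(stats::cor(t(m)))
  }
  common <- Reduce(intersect, lapply(cors, rownames))
  if (length(common) < 2L) {
    stop("fewer than 2 genes pass the UMI filter in all samples",
         call. = FALSE)
  }
  zs <- lapply(cors, function(cm) {
    r <- cm[common, common]
    r[!is.finite(r)] <- 0            # zero-variance genes contribute 0
    atanh(pmin(pmax(r, -0.9999999), 0.9999999))
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  avg <- tanh(zbar)
  diag(avg) <- 1
  hc <- stats::hclust(stats::as.dist(1 - avg), method = "complete")
  modules <- stats::cutree(hc, k = min(n_modules, length(common)))
  attr(modules, "hclust") <- hc
  attr(modules, "correlation") <- avg
  modules
}
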