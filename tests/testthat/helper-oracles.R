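# Independent oracles used by the unit and acceptance tests. These
# deliberately use brute-force / closed-form routes distinct from the
# package implementation.

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# O(n^2) all-pairs Hamming-1 edge scan (the spec's brute-force network
# oracle); returns a 2-column index matrix.
brute_hamming1_edges <- function(seqs) {
  n <- length(seqs)
  out <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        h <- hamming(seqs[i], seqs[j])
        if (!is.na(h) && h == 1) out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  do.call(rbind, out)
}

# Brute-force clone partition: evaluate the pairwise relation on every cell
# pair (all-pairs scan, vectorised over the second index), then take
# connected components with igraph (independent of the union-find
# implementation in the package).
brute_clone_partition <- function(dt, receptor = c("bcr", "tcr")) {
  receptor <- match.arg(receptor)
  n <- nrow(dt)
  edges <- c()
  if (receptor == "bcr") {
    # relation: equal-length Hamming <= 1 CDR3 (identical sequences share a
    # network node), OR identical CDR3 + same V/J family (subsumed by the
    # former but evaluated anyway, as the spec relation states it)
    lens <- nchar(dt$heavy_junction)
    for (len in unique(lens)) {
      idx <- which(lens == len)
      if (length(idx) < 2) next
      M <- do.call(rbind, strsplit(dt$heavy_junction[idx], ""))
      for (a in 1:(length(idx) - 1)) {
        rest <- (a + 1):length(idx)
        d <- rowSums(M[rest, , drop = FALSE] !=
                       matrix(M[a, ], length(rest), len, byrow = TRUE))
        ident <- d == 0
        crit_b <- ident &
          gene_family(dt$heavy_v_call[idx[rest]]) ==
            gene_family(dt$heavy_v_call[idx[a]]) &
          gene_family(dt$heavy_j_call[idx[rest]]) ==
            gene_family(dt$heavy_j_call[idx[a]])
        rel <- (d <= 1) | crit_b
        for (b in rest[rel]) edges <- c(edges, idx[a], idx[b])
      }
    }
  } else {
    key <- paste(dt$heavy_junction, strip_allele(dt$heavy_v_call),
                 strip_allele(dt$heavy_j_call))
    tra <- if ("light_junction" %in% names(dt)) dt$light_junction else
      rep(NA_character_, n)
    for (idx in split(seq_len(n), key)) {
      if (length(idx) < 2) next
      for (a in 1:(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) {
          ta <- tra[idx[a]]; tb <- tra[idx[b]]
          if (is.na(ta) || is.na(tb) || ta == "" || tb == "" ||
              identical(ta, tb)) {
            edges <- c(edges, idx[a], idx[b])
          }
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Two labelings describe the same partition iff the label pairing is a
# bijection.
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  key <- paste(a, b)
  length(unique(key)) == length(unique(a)) &&
    length(unique(key)) == length(unique(b))
}

# Exact intra-subset clonality expectation by enumerating all C(n, depth)
# subsamples.
enumerate_intra <- function(clone_ids, depth) {
  n <- length(clone_ids)
  combos <- combn(n, depth)
  vals <- apply(combos, 2, function(idx) {
    s <- clone_ids[idx]
    s <- s[!is.na(s)]
    if (!length(s)) return(0)
    sizes <- table(s)
    100 * sum(sizes[sizes >= 2]) / depth
  })
  mean(vals)
}

# Exact inter-subset clonality: per subset, the conditional expectation over
# subsamples containing at least one cell of the subset.
enumerate_inter <- function(clone_ids, subsets, depth) {
  n <- length(clone_ids)
  combos <- combn(n, depth)
  levs <- sort(unique(subsets))
  sums <- setNames(numeric(length(levs)), levs)
  cnts <- setNames(numeric(length(levs)), levs)
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    scl <- clone_ids[idx]; ssub <- subsets[idx]
    sizes <- table(scl[!is.na(scl)])
    big <- names(sizes)[sizes >= 3]
    clonal <- !is.na(scl) & scl %in% big
    for (s in unique(ssub)) {
      here <- ssub == s
      sums[s] <- sums[s] + 100 * sum(clonal[here]) / sum(here)
      cnts[s] <- cnts[s] + 1
    }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

# Discrete truncated power-law maximum-likelihood fit (support 1..kmax,
# matching the generator's support); returns alpha-hat and its SE from the
# numeric observed information.
powerlaw_mle <- function(sizes, kmax = 500) {
  loglik <- function(alpha) {
    -alpha * sum(log(sizes)) - length(sizes) * log(sum((1:kmax)^(-alpha)))
  }
  fit <- optimize(loglik, c(1.01, 6), maximum = TRUE)
  a <- fit$maximum
  h <- 1e-4
  info <- -(loglik(a + h) - 2 * loglik(a) + loglik(a - h)) / h^2
  list(alpha = a, se = 1 / sqrt(info))
}

# Naive O(n^3) complete-linkage agglomeration; returns sorted merge heights.
naive_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Pillai's trace computed from the hypothesis and error SSCP matrices by
# hand: tr(H (H + E)^-1).
pillai_by_hand <- function(x, groups) {
  x <- as.matrix(x)
  g <- as.factor(groups)
  grand <- colMeans(x)
  H <- matrix(0, ncol(x), ncol(x))
  E <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    mi <- colMeans(xi)
    H <- H + nrow(xi) * tcrossprod(mi - grand)
    E <- E + crossprod(sweep(xi, 2, mi))
  }
  sum(diag(H %*% solve(H + E)))
}

# Convenience: a small chain-assignment table for clone-calling tests.
mk_chains <- function(cell_id, junction, v = "IGHV3-23*01", j = "IGHJ4*02",
                      tra = NULL, receptor = "BCR") {
  dt <- data.table::data.table(
    cell_id = cell_id, receptor_class = receptor,
    heavy_junction = junction,
    heavy_v_call = rep_len(v, length(cell_id)),
    heavy_j_call = rep_len(j, length(cell_id)))
  if (!is.null(tra)) dt[, light_junction := tra]
  dt
}

# Random clone-calling instance (mixed relatedness) for oracle-equivalence
# tests; n cells, BCR or TCR columns.
random_clone_instance <- function(n, receptor = c("bcr", "tcr")) {
  receptor <- match.arg(receptor)
  base_pool <- replicate(max(2, n %/% 5),
                         paste(sample(c("A", "C", "G", "T"), 12,
                                      replace = TRUE), collapse = ""))
  juncs <- vapply(seq_len(n), function(i) {
    s <- sample(base_pool, 1)
    if (runif(1) < 0.5) {
      ch <- strsplit(s, "")[[1]]
      p <- sample(length(ch), 1)
      ch[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(ch, collapse = "")
    } else s
  }, character(1))
  vpool <- if (receptor == "bcr") {
    c("IGHV3-23*01", "IGHV3-7*01", "IGHV1-2*01", "IGHV4-34*01")
  } else c("TRBV2*01", "TRBV19*01", "TRBV28*01")
  jpool <- if (receptor == "bcr") {
    c("IGHJ4*02", "IGHJ6*01", "IGHJ3*01")
  } else c("TRBJ1-1*01", "TRBJ2-7*01")
  dt <- data.table::data.table(
    cell_id = sprintf("c%04d", seq_len(n)),
    receptor_class = if (receptor == "bcr") "BCR" else "TCR",
    heavy_junction = juncs,
    heavy_v_call = sample(vpool, n, replace = TRUE),
    heavy_j_call = sample(jpool, n, replace = TRUE))
  if (receptor == "tcr") {
    tra_pool <- c("ACGTAA", "ACGTCC", NA_character_)
    dt[, light_junction := sample(tra_pool, n, replace = TRUE)]
  }
  dt
}
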