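# deterministic toy matrix: two expression tiers so bin membership is known
mk_score_fixture <- function() {
  # 6 genes, 4 cells; genes g1-g3 low tier, g4-g6 high tier; within a tier
  # all genes share the same per-cell profile, so any control draw from the
  # right bin is deterministic
  low <- c(1, 2, 1, 2)
  high <- c(8, 6, 10, 4)
  mat <- rbind(g1 = low, g2 = low, g3 = low,
               g4 = high, g5 = high, g6 = high)
  colnames(mat) <- paste0("c", 1:4)
  mat
}

test_that("module score matches the hand-computed binned-control recipe", {
  mat <- mk_score_fixture()
  sc <- module_score(mat, c("g4", "g5"), n_bins = 2, n_ctrl = 2, seed = 1)
  # oracle: log-normalised expression, set mean minus control mean; with
  # identical profiles inside each bin the control mean equals the tier
  # profile regardless of which genes were drawn
  libs <- colSums(mat)
  ln <- log1p(t(t(mat) / libs) * 1e4)
  expected <- colMeans(ln[c("g4", "g5"), ]) - ln["g6", ]  # any high gene
  expect_equal(sc$score, unname(expected), tolerance = 1e-9)

  # distinct set-gene profile, n_ctrl = bin size: the without-replacement
  # draw returns the whole bin, so the oracle is fully hand-computable
  mat2 <- rbind(g1 = c(1, 2, 1, 2), g2 = c(1, 2, 1, 2), g3 = c(1, 2, 1, 2),
                g4 = c(12, 4, 9, 3), g5 = c(7, 7, 7, 7), g6 = c(7, 7, 7, 7))
  colnames(mat2) <- paste0("c", 1:4)
  sc2 <- module_score(mat2, "g4", n_bins = 2, n_ctrl = 3, seed = 99)
  ln2 <- log1p(t(t(mat2) / colSums(mat2)) * 1e4)
  expected2 <- ln2["g4", ] - colMeans(ln2[c("g4", "g5", "g6"), ])
  expect_equal(sc2$score, unname(expected2), tolerance = 1e-9)
})

test_that("uniform matrices score 0 and up-shifts raise the score", {
  mat <- matrix(5, 8, 6, dimnames = list(paste0("g", 1:8),
                                         paste0("c", 1:6)))
  sc <- module_score(mat, c("g1", "g2"), n_bins = 2, n_ctrl = 3, seed = 2)
  expect_equal(sc$score, rep(0, 6), tolerance = 1e-12)

  mat2 <- mk_score_fixture()
  shifted <- mat2
  shifted[c("g4", "g5"), 1:2] <- shifted[c("g4", "g5"), 1:2] + 50
  s0 <- module_score(mat2, c("g4", "g5"), n_bins = 2, n_ctrl = 2, seed = 3)
  s1 <- module_score(shifted, c("g4", "g5"), n_bins = 2, n_ctrl = 2,
                     seed = 3)
  expect_gt(mean(s1$score[1:2]) - mean(s1$score[3:4]),
            mean(s0$score[1:2]) - mean(s0$score[3:4]))
})

test_that("module score errors and reproducibility", {
  mat <- mk_score_fixture()
  expect_error(module_score(mat, c("nope"), n_bins = 2, n_ctrl = 2),
               "no gene")
  expect_error(module_score(mat, "g1", n_bins = 50), "n_bins")
  s1 <- module_score(mat, "g4", n_bins = 2, n_ctrl = 2, seed = 9)
  s2 <- module_score(mat, "g4", n_bins = 2, n_ctrl = 2, seed = 9)
  expect_identical(s1, s2)
})

test_that("threshold fitting: symmetry, equivariance, degeneracy", {
  expect_equal(fit_score_threshold(rep(1, 10), rep(-1, 10)), 0)
  # shift equivariance on an overlapping case
  withr::with_seed(4, {
    pos <- rnorm(200, 1); neg <- rnorm(200, -1)
  })
  thr <- fit_score_threshold(pos, neg)
  thr_shift <- fit_score_threshold(pos + 3, neg + 3)
  expect_equal(thr_shift, thr + 3, tolerance = 1e-6)
  # identical distributions -> warning + pooled median
  x <- c(1, 2, 3, 4, 5)
  expect_warning(t0 <- fit_score_threshold(x, x), "indistinguishable")
  expect_equal(t0, median(c(x, x)))
  # reversed separable groups still give the gap midpoint
  expect_equal(fit_score_threshold(rep(-2, 5), rep(2, 5)), 0)
})

test_that("pAPC classification composition sums to 1 and is forced for
           subset-specific signatures", {
  scores <- data.table::data.table(cell_id = paste0("c", 1:6),
                                   score = c(2, 3, 0.5, -1, 4, -2))
  meta <- data.table::data.table(
    cell_id = paste0("c", 1:6), patient = c("P1", "P1", "P1", "P2", "P2",
                                            "P2"),
    subset = c("DC", "B", "T", "T", "DC", "T"))
  res <- classify_papc(scores, 1, meta)
  expect_equal(res$cells$papc, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$composition[, sum(fraction), by = patient]$V1, c(1, 1))
  # all below threshold -> empty composition
  res0 <- classify_papc(scores, 10, meta)
  expect_equal(nrow(res0$composition), 0)
  # signature expressed only in DC -> composition 100% DC
  cf <- sim_config(n_patients = 2, cells_per_sample = 150, seed = 31)
  f <- cf$expr_fractions
  papc_genes <- c("CD74", "HLA-DRA", "HLA-DRB1", "CD80", "CD86")
  f[papc_genes, ] <- 0
  f[papc_genes, "DC"] <- 1
  cf2 <- sim_config(n_patients = 2, cells_per_sample = 150,
                    expr_fractions = f, seed = 31)
  meta2 <- simulate_repertoire(cf2)$meta
  mat <- simulate_expression(cf2, meta2)
  sc <- module_score(mat, papc_genes, n_bins = 10, n_ctrl = 10, seed = 1)
  scm <- merge(sc, meta2, by = "cell_id")
  thr <- fit_score_threshold(scm[subset == "DC", score],
                             scm[subset == "CD8_effector", score])
  out <- classify_papc(sc, thr, meta2)
  expect_equal(unique(out$composition$subset), "DC")
})

test_that("gate_cells applies the rulebook with priorities and fallback", {
  rules <- read_gate_rules(system.file("extdata", "gate_rules.yaml",
                                       package = "immunoclone"))
  features <- data.table::data.table(
    percBCR_high = c(0.5, 0.3, 0.05, 0.05),
    PC_score = c(0.05, 0.05, 0, 0),
    frac_unmutated = c(0, 0, 0.9, 0.2),
    frac_IGHDM = c(0, 0, 0.99, 0.2),
    CD27 = c(0, 0, 0, 0.5),
    cluster = c("k1", "k2", "k3", "k4"))
  labels <- gate_cells(features, rules, fallback = "B cell")
  expect_equal(labels, c("plasma cell", "plasmablast", "B cell naive",
                         "B cell memory"))
  # cells matching nothing fall back
  none <- data.table::copy(features)[, `:=`(percBCR_high = 0, PC_score = 0,
                                            frac_unmutated = 0,
                                            frac_IGHDM = 0, CD27 = 0)]
  expect_equal(unique(gate_cells(none, rules, fallback = "B cell")),
               "B cell")
  # higher priority wins regardless of rule-file order
  both <- data.table::data.table(percBCR_high = 0.5, PC_score = 0.05,
                                 frac_unmutated = 0, frac_IGHDM = 0,
                                 CD27 = 0, cluster = "k")
  expect_equal(gate_cells(both, rev(rules)), "plasma cell")
  # unknown feature and duplicate priorities are config errors
  bad <- list(list(label = "x", priority = 1,
                   predicates = list(list(feature = "nope",
                                          comparator = ">",
                                          threshold = 1,
                                          aggregation = "cell"))))
  expect_error(gate_cells(features, bad), "unknown feature")
  dup <- rules
  dup[[2]]$priority <- 1
  expect_error(gate_cells(features, dup), "unique")
})

test_that("cluster aggregations compute means and fractions", {
  ft <- data.table::data.table(CD27 = c(1, 0, 0, 0), cluster = c("a", "a",
                                                                 "b", "b"))
  rules <- list(list(label = "memory", priority = 1,
                     predicates = list(list(feature = "CD27",
                                            comparator = ">",
                                            threshold = 0.3,
                                            aggregation = "cluster-mean"))))
  expect_equal(gate_cells(ft, rules, "other"),
               c("memory", "memory", "other", "other"))
  rules2 <- list(list(label = "hi", priority = 1,
                      predicates = list(list(feature = "CD27",
                                             comparator = ">=",
                                             threshold = 0.5,
                                             aggregation =
                                               "cluster-fraction"))))
  expect_equal(gate_cells(ft, rules2, "lo"), c("hi", "hi", "lo", "lo"))
})

test_that("gene modules recover block structure and match the oracle", {
  withr::with_seed(11, {
    n_cells <- 40
    base1 <- rpois(n_cells, 20)
    base2 <- rpois(n_cells, 20)
    mk_mat <- function() {
      m <- rbind(
        t(vapply(1:4, function(i) base1 + rpois(n_cells, 1), numeric(n_cells))),
        t(vapply(1:4, function(i) base2 + rpois(n_cells, 1), numeric(n_cells))))
      rownames(m) <- paste0("g", 1:8)
      colnames(m) <- paste0("c", 1:n_cells)
      m
    }
    mats <- list(s1 = mk_mat(), s2 = mk_mat())
  })
  mods <- gene_modules(mats, umi_target = 100, min_gene_umis = 5,
                       n_modules = 2, seed = 3)
  expect_equal(length(unique(mods[paste0("g", 1:4)])), 1)
  expect_equal(length(unique(mods[paste0("g", 5:8)])), 1)
  expect_false(mods[["g1"]] == mods[["g5"]])
  # identical matrices in all samples: averaged correlation equals the
  # single-sample correlation (Fisher-z identity on equal inputs);
  # umi_target above every cell total so downsampling is a no-op and the
  # per-sample inputs are exactly equal
  mods1 <- gene_modules(mats[c(1, 1)], umi_target = 10000, seed = 3)
  single <- gene_modules(mats[1], umi_target = 10000, seed = 3)
  expect_equal(attr(mods1, "correlation"), attr(single, "correlation"),
               tolerance = 1e-9)
  # dendrogram heights equal the naive complete-linkage oracle
  avg <- attr(mods, "correlation")
  hc <- attr(mods, "hclust")
  expect_equal(sort(hc$height),
               naive_complete_linkage_heights(as.dist(1 - avg)),
               tolerance = 1e-9)
  expect_error(gene_modules(list(matrix(0, 2, 3)), min_gene_umis = 5),
               "fewer than 2 genes")
})

test_that("SVM label transfer recovers separable classes and respects
           dimensionality checks", {
  withr::with_seed(21, {
    centers <- matrix(rnorm(4 * 5), 4, 5) * 6
    ref <- do.call(rbind, lapply(1:4, function(k) {
      sweep(matrix(rnorm(40 * 5), 40, 5), 2, centers[k, ], `+`)
    }))
    labels <- rep(paste0("class", 1:4), each = 40)
  })
  res <- svm_label_transfer(ref, labels, ref, cells_per_class = 20,
                            reps = 5, seed = 2)
  expect_equal(mean(res$label == labels), 1)
  expect_equal(unique(res$probability), 1)
  votes <- attr(res, "votes")
  expect_equal(unname(rowSums(votes)), rep(1, nrow(ref)))
  expect_error(svm_label_transfer(ref, labels, ref[, 1:3]),
               "dimensionality")
  # determinism
  res2 <- svm_label_transfer(ref, labels, ref, cells_per_class = 20,
                             reps = 5, seed = 2)
  expect_identical(res, res2)
})
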