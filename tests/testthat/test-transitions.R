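mk_cells <- function(clone, subset, compartment = NULL, patient = "P1") {
  n <- length(clone)
  dt <- data.table::data.table(
    cell_id = sprintf("c%03d", seq_len(n)),
    clone_id = clone, subset = subset, patient = patient)
  if (!is.null(compartment)) dt[, compartment := compartment]
  dt
}

test_that("clonal overlap counts cells per the stated rule", {
  # all clones confined to one subset -> zero matrix
  m0 <- clonal_overlap(mk_cells(c("a", "a", "b"), c("X", "X", "Y")))
  expect_true(all(m0 == 0))
  # one clone: 2 cells in A, 3 in B -> entry 5
  m1 <- clonal_overlap(mk_cells(rep("a", 5),
                                c("A", "A", "B", "B", "B")))
  expect_equal(m1["A", "B"], 5)
  expect_equal(m1["B", "A"], 5)
  expect_equal(diag(m1), c(A = 0, B = 0))
})

test_that("overlap equals brute-force per-clone tally on a random instance", {
  withr::with_seed(31, {
    cells <- data.table::data.table(
      cell_id = sprintf("c%03d", 1:100),
      clone_id = sample(c(paste0("cl", 1:25), NA), 100, replace = TRUE),
      subset = sample(c("A", "B", "C"), 100, replace = TRUE))
  })
  m <- clonal_overlap(cells)
  levs <- rownames(m)
  oracle <- matrix(0, length(levs), length(levs),
                   dimnames = list(levs, levs))
  for (cl in unique(na.omit(cells$clone_id))) {
    tab <- table(cells[clone_id == cl, subset])
    present <- names(tab)[tab > 0]
    if (length(present) < 2) next
    for (pair in asplit(combn(present, 2), 2)) {
      i <- pair[1]; j <- pair[2]
      oracle[i, j] <- oracle[i, j] + tab[[i]] + tab[[j]]
      oracle[j, i] <- oracle[i, j]
    }
  }
  expect_equal(unclass(m), oracle, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(m)))
})

test_that("normalisation scales to 1 and excludes all-zero samples", {
  m <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  z <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  norm <- normalize_overlap(list(s1 = m, s2 = z))
  expect_equal(names(norm), "s1")
  expect_equal(attr(norm, "excluded"), "s2")
  expect_equal(sum(norm$s1), 1, tolerance = 1e-12)
  # entry ratios preserved
  expect_equal(norm$s1["A", "B"] / norm$s1["A", "C"], 2 / 3)
})

test_that("compartment classification and its swap symmetry", {
  ct <- data.table::data.table(cell_id = paste0("c", 1:5),
                               clone_id = c("a", "a", "b", "b", "c"))
  meta <- data.table::data.table(
    cell_id = paste0("c", 1:5),
    compartment = c("blood", "tumour", "blood", "blood", "tumour"))
  calls <- classify_compartments(ct, meta)
  expect_equal(calls[clone_id == "a", call], "recirculating")
  expect_equal(calls[clone_id == "b", call], "blood_only")
  expect_equal(calls[clone_id == "c", call], "tumour_only")
  # swapping compartments swaps blood/tumour labels, fixes recirculating
  swapped <- data.table::copy(meta)[
    , compartment := ifelse(compartment == "blood", "tumour", "blood")]
  calls2 <- classify_compartments(ct, swapped)
  expect_equal(calls2[clone_id == "a", call], "recirculating")
  expect_equal(calls2[clone_id == "b", call], "tumour_only")
  expect_equal(calls2[clone_id == "c", call], "blood_only")
  meta$compartment[1] <- "lymph"
  expect_error(classify_compartments(ct, meta), "unknown compartment")
})

test_that("recirculating fraction recovers the generator parameter", {
  cf <- sim_config(n_patients = 4, cells_per_sample = 400,
                   shared_clone_prob = 0.3, shm_rate = 0, seed = 77)
  rep <- simulate_repertoire(cf)
  # evaluate on ground-truth clones of >= 2 cells (eligible for sharing)
  info <- rep$meta[!is.na(true_clone),
                   .(n = .N, rec = any(true_recirculating)),
                   by = true_clone][n >= 2]
  phat <- mean(info$rec)
  ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / nrow(info))
  expect_lt(abs(phat - 0.3), ci)
  # and the classifier agrees with the generator labels
  clones <- rep$meta[!is.na(true_clone),
                     .(cell_id, clone_id = true_clone)]
  calls <- classify_compartments(clones, rep$meta)
  obs <- merge(calls, info, by.x = "clone_id", by.y = "true_clone")
  expect_equal(obs[, call == "recirculating"], obs$rec)
})

test_that("migration linkage matches brute-force enumeration", {
  ct <- data.table::data.table(
    cell_id = paste0("c", 1:7),
    clone_id = c("a", "a", "b", "b", "b", "c", "c"))
  meta <- data.table::data.table(
    cell_id = paste0("c", 1:7),
    compartment = c("blood", "tumour", "blood", "tumour", "tumour",
                    "blood", "blood"),
    subset = c("naive", "memory", "naive", "memory", "effector",
               "naive", "naive"),
    patient = "P1")
  mig <- migration_linkage(ct, meta)
  # clone a: naive(blood) x memory(tumour); clone b: naive x {memory,
  # effector}; clone c: blood only
  raw <- mig$per_patient$P1
  expect_equal(raw["naive", "memory"], 2)
  expect_equal(raw["naive", "effector"], 1)
  expect_equal(sum(raw), 3)
  expect_equal(sum(mig$mean), 1)
  # single recirculating clone case
  mig1 <- migration_linkage(ct[1:2], meta[1:2])
  expect_equal(mig1$per_patient$P1["naive", "memory"], 1)
  expect_equal(sum(mig1$per_patient$P1), 1)
  # no recirculating clones -> zero matrix
  mig0 <- migration_linkage(ct[6:7], meta[6:7])
  expect_true(all(mig0$mean == 0) || prod(dim(mig0$mean)) == 0)
})

test_that("known-TCR screening matches exactly and recovers decoy rate", {
  chains <- data.table::data.table(
    cell_id = paste0("c", 1:3), receptor_class = "TCR",
    heavy_junction_aa = c("CASSLG", "CASSXX", "CASSLG"),
    heavy_v_call = c("TRBV2*01", "TRBV2*01", "TRBV19*01"))
  ref <- data.table::data.table(cdr3_aa = "CASSLG", v_gene = "TRBV2",
                                antigen_category = "CMV")
  scr <- screen_known_tcrs(chains, ref)
  expect_equal(scr$cells[cell_id == "c1", matched], TRUE)
  expect_equal(scr$cells[cell_id == "c1", antigen_category], "CMV")
  expect_equal(scr$cells[cell_id == "c2", matched], FALSE)
  expect_equal(scr$cells[cell_id == "c3", matched], FALSE)  # V mismatch
  # empty reference -> zero matches
  scr0 <- screen_known_tcrs(chains,
                            data.table::data.table(cdr3_aa = character(),
                                                   antigen_category =
                                                     character()))
  expect_false(any(scr0$cells$matched))
  expect_error(screen_known_tcrs(chains, data.table::data.table(x = 1)),
               "cdr3_aa")

  # reference built from 10% of simulated clone CDR3s
  cf <- sim_config(n_patients = 2, cells_per_sample = 300, seed = 55)
  rep <- simulate_repertoire(cf)
  ch <- select_chains(rep$contigs)
  tcr <- ch[receptor_class == "TCR" & !is.na(heavy_junction_aa)]
  cl <- data.table::rbindlist(lapply(
    split(merge(tcr, rep$meta[, .(cell_id, patient)], by = "cell_id"),
          by = "patient"),
    function(x) call_tcr_clones(x)[, clone_id := paste(x$patient[1],
                                                       clone_id)]))
  clm <- merge(cl, tcr[, .(cell_id, heavy_junction_aa)], by = "cell_id")
  clone_cdr3 <- unique(clm[, .(clone_id, heavy_junction_aa)])
  withr::with_seed(5, {
    picked <- clone_cdr3[sample(.N, round(0.1 * .N))]
  })
  ref2 <- data.table::data.table(cdr3_aa = picked$heavy_junction_aa,
                                 antigen_category = "decoy")
  scr2 <- screen_known_tcrs(tcr, ref2)
  per_clone <- merge(cl, scr2$cells, by = "cell_id")[
    , .(matched = any(matched)), by = clone_id]
  frac <- mean(per_clone$matched)
  ci <- qnorm(0.995) * sqrt(0.1 * 0.9 / nrow(per_clone))
  # shared CDR3 across clones can only push the match rate up
  expect_gt(frac, 0.1 - ci)
  expect_lt(frac, 0.1 + ci + 0.02)
})
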