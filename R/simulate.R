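#' Default immune subset composition for simulation
#'
#' Nine subsets spanning the three lymphocyte lineages (B, CD4, CD8) plus two
#' myeloid populations without VDJ rearrangements. Frequencies emulate a
#' CD45-enriched tumour/blood sample with a T-cell-dominated infiltrate.
#'
#' @return data.frame with columns `name`, `freq` (sums to 1) and `lineage`
#'   (`"B"`, `"CD4"`, `"CD8"` or `"none"` for non-lymphoid subsets).
#' @export
default_subsets <- function() {
  data.frame(
    name = c("B_naive", "B_memory", "Plasma",
             "CD4_naive", "CD4_Treg",
             "CD8_effector", "CD8_exhausted",
             "DC", "Macrophage"),
    freq = c(0.12, 0.10, 0.04, 0.14, 0.08, 0.22, 0.14, 0.08, 0.08),
    lineage = c("B", "B", "B", "CD4", "CD4", "CD8", "CD8", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Default per-subset expressing fractions for the simulated gene panel
#'
#' A curated immune panel (lineage markers, chemokine receptors and ligands,
#' checkpoint molecules, MHC-II/accessory pathway genes) with a baseline
#' expressing probability and biologically motivated elevations, e.g. FOXP3
#' and CCR4/CCR8 in regulatory CD4 T cells, the MHC-II programme in dendritic
#' cells, macrophages and B cells.
#'
#' @param subsets subset definition as from [default_subsets()].
#' @param baseline probability a gene is detected in a subset with no
#'   specific elevation.
#' @return numeric matrix genes x subsets with entries in \[0, 1\].
#' @export
default_expr_fractions <- function(subsets = default_subsets(),
                                   baseline = 0.05) {
  genes <- c(
    # lineage markers
    "CD19", "MS4A1", "CD27", "CD3E", "CD4", "CD8A", "FOXP3", "GZMB",
    "PDCD1", "HAVCR2", "LAG3", "TIGIT", "CTLA4",
    # chemokine receptors / ligands
    "CCR4", "CCR8", "CXCR4", "CXCR6", "CCR7",
    "CCL17", "CCL22", "CCL1", "CXCL12", "CXCL16", "CXCL9", "CXCL10",
    "CXCL13", "CCL5", "CCL2", "CCR2", "CXCR3", "CXCR5",
    # cytokines and receptors
    "IL2", "IL2RA", "IL10", "IL10RA", "TGFB1", "TGFBR1", "IL6", "IL6R",
    "TNF", "TNFRSF1A", "IL7R", "CSF1", "CSF1R", "IL15", "IL2RB",
    "CD40LG", "ICOS", "ICOSLG",
    "CCL3", "CCL4", "CCR1", "CCR5", "XCL1", "XCR1",
    "IL7", "IL4", "IL4R", "IL21", "IL21R", "IL1B", "IL1R1",
    "CSF2", "CSF2RA", "FLT3LG", "FLT3", "TNFSF13B", "TNFRSF13B", "CD28",
    # MHC-II / accessory (pAPC programme)
    "CD74", "HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1", "HLA-DMA",
    "CD40", "CD80", "CD86", "CD274", "PDCD1LG2", "LGALS9"
  )
  f <- matrix(baseline, nrow = length(genes), ncol = nrow(subsets),
              dimnames = list(genes, subsets$name))
  set_f <- function(gene, subset, p) {
    keep <- intersect(subset, colnames(f))
    f[gene, keep] <<- p
  }
  bsub <- subsets$name[subsets$lineage == "B"]
  t4 <- subsets$name[subsets$lineage == "CD4"]
  t8 <- subsets$name[subsets$lineage == "CD8"]
  tall <- c(t4, t8)
  set_f("CD19", bsub, 0.9); set_f("MS4A1", setdiff(bsub, "Plasma"), 0.9)
  set_f("CD27", c("B_memory", "Plasma"), 0.8)
  set_f("CD3E", tall, 0.95); set_f("CD4", t4, 0.9); set_f("CD8A", t8, 0.9)
  set_f("FOXP3", "CD4_Treg", 0.9)
  set_f("GZMB", c("CD8_effector"), 0.7)
  set_f(c("PDCD1", "HAVCR2", "LAG3", "TIGIT"), "CD8_exhausted", 0.7)
  set_f("CTLA4", c("CD4_Treg", "CD8_exhausted"), 0.6)
  set_f(c("CCR4", "CCR8"), "CD4_Treg", 0.75)
  set_f("CXCR4", c(bsub, tall), 0.45)
  set_f("CXCR6", c("CD8_exhausted", "CD4_Treg"), 0.6)
  set_f("CCR7", c("B_naive", "CD4_naive"), 0.8)
  set_f(c("CCL17", "CCL22"), "DC", 0.7)
  set_f(c("CCL17", "CCL22", "CCL2", "CXCL9", "CXCL10", "CXCL16"),
        "Macrophage", 0.55)
  set_f("CXCL12", "Macrophage", 0.4)
  set_f("CXCL13", "CD4_Treg", 0.3)
  set_f("CCL5", t8, 0.7)
  set_f("IL2RA", "CD4_Treg", 0.8)
  set_f("IL10", c("CD4_Treg", "Macrophage"), 0.5)
  set_f("TGFB1", c("CD4_Treg", "Macrophage"), 0.5)
  set_f("IL7R", c("CD4_naive", "CD8_effector"), 0.7)
  set_f(c("CSF1R", "TNFRSF1A", "IL6", "TNF"), "Macrophage", 0.6)
  set_f("ICOS", c("CD4_Treg"), 0.6); set_f("ICOSLG", "DC", 0.5)
  set_f("CD40LG", t4, 0.5)
  set_f(c("CCL3", "CCL4", "IL1B", "FLT3LG"), "Macrophage", 0.5)
  set_f(c("CCR5", "XCR1"), t8, 0.4)
  set_f("CD28", tall, 0.7)
  set_f("TNFSF13B", c("DC", "Macrophage"), 0.4)
  set_f("TNFRSF13B", bsub, 0.5)
  papc <- c("CD74", "HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1",
            "HLA-DMA", "CD40", "CD80", "CD86")
  set_f(papc, "DC", 0.92)
  set_f(papc, "Macrophage", 0.65)
  set_f(papc, setdiff(bsub, "Plasma"), 0.6)
  set_f(c("CD274", "PDCD1LG2", "LGALS9"), c("DC", "Macrophage"), 0.5)
  f
}

#' Build a validated simulation configuration
#'
#' Defaults describe a paired blood/tumour cohort: each patient contributes
#' one blood and one tumour sample of `cells_per_sample` cells, with clone
#' sizes following a discrete power law and a fixed probability that a
#' multi-cell clone recirculates between compartments.
#'
#' @param n_patients number of patients (each with a blood and a tumour
#'   sample).
#' @param cells_per_sample expected cells per sample.
#' @param subsets data.frame (`name`, `freq`, `lineage`); `freq` sums to 1.
#' @param clone_size_law list, either `list(law = "power_law", alpha = 2.5)`
#'   or `list(law = "geometric", p = 0.5)`; sizes are in cells.
#' @param shared_clone_prob probability a clone of >= 2 cells spans blood and
#'   tumour ("recirculating").
#' @param cross_subset_prob probability a multi-cell lymphocyte clone spans
#'   two subsets of its lineage.
#' @param shm_rate expected somatic point mutations per BCR V segment
#'   (Poisson mean); TCRs do not mutate.
#' @param isotype_probs named per-isotype probabilities (sum 1) for B-cell
#'   heavy chains.
#' @param expr_fractions genes x subsets matrix of expressing probabilities,
#'   as from [default_expr_fractions()].
#' @param depth_mean expected UMIs per cell used to scale simulated counts.
#' @param decoy_prob probability a droplet carries a second, lower-UMI contig
#'   on its heavy locus (exercises most-probable-chain selection).
#' @param seed master integer seed; identical config + seed gives
#'   byte-identical outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 4,
                       cells_per_sample = 250,
                       subsets = default_subsets(),
                       clone_size_law = list(law = "power_law", alpha = 2.5),
                       shared_clone_prob = 0.2,
                       cross_subset_prob = 0.2,
                       shm_rate = 2,
                       isotype_probs = c(IGHM = 0.35, IGHD = 0.05,
                                         IGHG1 = 0.20, IGHG2 = 0.10,
                                         IGHG3 = 0.05, IGHA1 = 0.15,
                                         IGHA2 = 0.05, IGHE = 0.05),
                       expr_fractions = default_expr_fractions(subsets),
                       depth_mean = 2000,
                       decoy_prob = 0.1,
                       seed = 1L) {
  stopifnot(n_patients >= 1, cells_per_sample >= 1)
  stopifnot(is.data.frame(subsets),
            all(c("name", "freq", "lineage") %in% names(subsets)))
  stopifnot(all(subsets$lineage %in% c("B", "CD4", "CD8", "none")))
  check_prob_vector(subsets$freq, "subset frequencies")
  check_prob_vector(isotype_probs, "isotype_probs")
  for (p in c(shared_clone_prob, cross_subset_prob, decoy_prob)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!clone_size_law$law %in% c("power_law", "geometric")) {
    stop("clone_size_law$law must be 'power_law' or 'geometric'",
         call. = FALSE)
  }
  if (clone_size_law$law == "power_law" &&
      (is.null(clone_size_law$alpha) || clone_size_law$alpha <= 1)) {
    stop("power_law requires alpha > 1", call. = FALSE)
  }
  if (clone_size_law$law == "geometric" &&
      (is.null(clone_size_law$p) || clone_size_law$p <= 0 ||
       clone_size_law$p > 1)) {
    stop("geometric requires p in (0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(expr_fractions),
            all(expr_fractions >= 0), all(expr_fractions <= 1),
            all(colnames(expr_fractions) %in% subsets$name) ||
              all(subsets$name %in% colnames(expr_fractions)))
  if (shm_rate < 0) stop("shm_rate must be >= 0", call. = FALSE)
  stopifnot(depth_mean > 0)
  structure(list(
    n_patients = as.integer(n_patients),
    cells_per_sample = as.integer(cells_per_sample),
    subsets = subsets,
    clone_size_law = clone_size_law,
    shared_clone_prob = shared_clone_prob,
    cross_subset_prob = cross_subset_prob,
    shm_rate = shm_rate,
    isotype_probs = isotype_probs,
    expr_fractions = expr_fractions,
    depth_mean = depth_mean,
    decoy_prob = decoy_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw one clone size from the configured law. Power-law support is the
# discrete range 1..500 cells.
draw_clone_size <- function(law) {
  if (law$law == "power_law") {
    kmax <- 500L
    pr <- (1:kmax)^(-law$alpha)
    sample.int(kmax, 1L, prob = pr / sum(pr))
  } else {
    rgeom(1L, law$p) + 1L
  }
}

# Random CDR3 DNA of a fixed amino-acid length (length divisible by 3).
random_junction <- function(n_nt = 45L) {
  paste(sample(c("A", "C", "G", "T"), n_nt, replace = TRUE), collapse = "")
}

# Apply n point substitutions at distinct positions.
mutate_dna <- function(seq, nmut) {
  if (nmut <= 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  nmut <- min(nmut, length(ch))
  pos <- sample.int(length(ch), nmut)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

.vdj_pools <- list(
  B = list(
    heavy_v = c("IGHV1-2*01", "IGHV1-69*01", "IGHV3-23*01", "IGHV3-7*01",
                "IGHV4-34*01", "IGHV4-59*01", "IGHV5-51*01"),
    heavy_j = c("IGHJ1*01", "IGHJ3*01", "IGHJ4*02", "IGHJ6*01"),
    light_locus = c("IGK", "IGL"),
    light_v = list(IGK = c("IGKV1-39*01", "IGKV3-20*01", "IGKV4-1*01"),
                   IGL = c("IGLV1-44*01", "IGLV2-14*01", "IGLV3-1*01")),
    light_j = list(IGK = c("IGKJ1*01", "IGKJ2*01"),
                   IGL = c("IGLJ2*01", "IGLJ3*02"))
  ),
  T = list(
    heavy_v = c("TRBV2*01", "TRBV5-1*01", "TRBV6-5*01", "TRBV19*01",
                "TRBV20-1*01", "TRBV28*01"),
    heavy_j = c("TRBJ1-1*01", "TRBJ2-1*01", "TRBJ2-3*01", "TRBJ2-7*01"),
    light_v = c("TRAV1-2*01", "TRAV8-4*01", "TRAV12-1*01", "TRAV29DV5*01"),
    light_j = c("TRAJ33*01", "TRAJ42*01", "TRAJ49*01")
  )
)

#' Simulate a paired blood/tumour single-cell VDJ repertoire
#'
#' Cells are generated clone-first: clone sizes follow the configured law,
#' each clone has a founder CDR3 DNA sequence copied to its member cells with
#' Poisson point substitutions at rate `shm_rate` (BCR only), multi-cell
#' clones recirculate between blood and tumour with probability
#' `shared_clone_prob`, and droplets receive an optional lower-UMI decoy
#' contig on the heavy locus. Non-lymphoid subsets yield cells without
#' contigs.
#'
#' @param config a [sim_config()].
#' @return list with `contigs` (AIRR-style data.table: one row per contig)
#'   and `meta` (per-cell data.table with `cell_id`, `patient`, `sample_id`,
#'   `compartment`, `subset`, `lineage`, `group`, and the generator ground
#'   truth `true_clone`).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, "repertoire"), {
    subs <- config$subsets
    contig_rows <- list()
    meta_rows <- list()
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%02d", p)
      group <- if (p <= ceiling(config$n_patients / 2)) "ME" else "AE"
      n_total <- 2L * config$cells_per_sample
      # draw clones until the patient's cell budget is filled
      n_alloc <- 0L
      clones <- list()
      while (n_alloc < n_total) {
        primary <- sample(subs$name, 1L, prob = subs$freq)
        lin <- subs$lineage[match(primary, subs$name)]
        size <- if (lin == "none") 1L else {
          draw_clone_size(config$clone_size_law)
        }
        size <- min(size, n_total - n_alloc)
        clones[[length(clones) + 1L]] <-
          list(primary = primary, lineage = lin, size = size)
        n_alloc <- n_alloc + size
      }
      cell_counter <- 0L
      for (ci in seq_along(clones)) {
        cl <- clones[[ci]]
        clone_id <- sprintf("%s_clone%04d", pid, ci)
        size <- cl$size
        # subsets spanned by this clone
        cl_subsets <- cl$primary
        if (cl$lineage != "none" && size > 1L &&
            runif(1) < config$cross_subset_prob) {
          others <- setdiff(subs$name[subs$lineage == cl$lineage], cl$primary)
          if (length(others)) cl_subsets <- c(cl_subsets, sample(others, 1L))
        }
        cell_subsets <- sample(cl_subsets, size, replace = TRUE)
        # compartments: only multi-cell clones can recirculate
        if (size >= 2L && runif(1) < config$shared_clone_prob) {
          comp <- c("blood", "tumour",
                    sample(c("blood", "tumour"), size - 2L, replace = TRUE))
          comp <- sample(comp)         # shuffle which cells got the forced pair
          recirculating <- TRUE
        } else {
          comp <- rep(sample(c("blood", "tumour"), 1L), size)
          recirculating <- FALSE
        }
        # founder VDJ
        is_b <- cl$lineage == "B"
        pool <- if (is_b) .vdj_pools$B else .vdj_pools$T
        hv <- sample(pool$heavy_v, 1L)
        hj <- sample(pool$heavy_j, 1L)
        founder_h <- random_junction(45L)
        founder_l <- random_junction(33L)
        if (is_b) {
          llocus <- sample(pool$light_locus, 1L, prob = c(0.6, 0.4))
          lv <- sample(pool$light_v[[llocus]], 1L)
          lj <- sample(pool$light_j[[llocus]], 1L)
          lc <- if (llocus == "IGK") "IGKC" else "IGLC2"
        } else {
          llocus <- "TRA"; lv <- sample(pool$light_v, 1L)
          lj <- sample(pool$light_j, 1L); lc <- "TRAC"
        }
        vlen <- 300L
        for (k in seq_len(size)) {
          cell_counter <- cell_counter + 1L
          cid <- sprintf("%s_cell%05d", pid, cell_counter)
          meta_rows[[length(meta_rows) + 1L]] <- data.table::data.table(
            cell_id = cid, patient = pid,
            compartment = comp[k],
            sample_id = paste(pid, comp[k], sep = "_"),
            subset = cell_subsets[k], lineage = cl$lineage, group = group,
            true_clone = if (cl$lineage == "none") NA_character_ else clone_id,
            true_recirculating = recirculating,
            true_clone_size = size
          )
          if (cl$lineage == "none") next
          hlocus <- if (is_b) "IGH" else "TRB"
          mut_v <- if (is_b) rpois(1L, config$shm_rate) else 0L
          mut_j <- if (is_b) rpois(1L, config$shm_rate * 45 / vlen) else 0L
          hjunc <- mutate_dna(founder_h, mut_j)
          ljunc <- founder_l
          base_umi <- if (cell_subsets[k] == "Plasma") 30L else 3L
          humi <- rpois(1L, base_umi) + 2L
          lumi <- rpois(1L, base_umi) + 2L
          ccall <- if (is_b) {
            sample(names(config$isotype_probs), 1L,
                   prob = config$isotype_probs)
          } else "TRBC1"
          rows <- data.table::data.table(
            cell_id = cid,
            contig_id = paste0(cid, "_contig_", 1:2),
            locus = c(hlocus, llocus),
            v_call = c(hv, lv), j_call = c(hj, lj),
            c_call = c(ccall, lc),
            junction = c(hjunc, ljunc),
            umi_count = c(humi, lumi),
            read_count = c(humi, lumi) * (10L + rpois(2L, 5L)),
            v_identity = c(round(100 * (1 - min(mut_v, vlen) / vlen), 4),
                           100),
            v_sequence_length = vlen
          )
          if (runif(1) < config$decoy_prob && humi >= 2L) {
            rows <- rbind(rows, data.table::data.table(
              cell_id = cid,
              contig_id = paste0(cid, "_contig_3"),
              locus = hlocus,
              v_call = sample(pool$heavy_v, 1L),
              j_call = sample(pool$heavy_j, 1L),
              c_call = ccall,
              junction = random_junction(45L),
              umi_count = sample.int(humi - 1L, 1L),
              read_count = 10L,
              v_identity = 100, v_sequence_length = vlen
            ))
          }
          contig_rows[[length(contig_rows) + 1L]] <- rows
        }
      }
    }
    contigs <- data.table::rbindlist(contig_rows)
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(contigs$junction), if.fuzzy.codon = "X")))
    contigs[, junction_aa := aa]
    data.table::setcolorder(contigs, c(
      "cell_id", "contig_id", "locus", "v_call", "j_call", "c_call",
      "junction", "junction_aa", "umi_count", "read_count", "v_identity",
      "v_sequence_length"))
    meta <- data.table::rbindlist(meta_rows)
    list(contigs = contigs[], meta = meta[])
  })
}

#' Simulate a cell x gene count matrix conditioned on subset identity
#'
#' Each gene is detected in a cell with exactly the configured per-subset
#' expressing probability; detected genes receive a shifted negative-binomial
#' count scaled to the configured sequencing depth, so the probability of a
#' nonzero count equals `expr_fractions[gene, subset]` by construction.
#'
#' @param config a [sim_config()].
#' @param meta per-cell metadata from [simulate_repertoire()].
#' @return sparse `dgCMatrix` (genes x cells) with dimnames.
#' @export
simulate_expression <- function(config, meta) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$expr_fractions
  unknown <- setdiff(unique(meta$subset), colnames(f))
  if (length(unknown)) {
    stop("unknown subset(s) in meta: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(derive_seed(config$seed, "expression"), {
    genes <- rownames(f)
    n_genes <- length(genes)
    mu <- config$depth_mean / (2 * n_genes)
    cols <- lapply(seq_len(nrow(meta)), function(i) {
      pr <- f[, meta$subset[i]]
      expressed <- runif(n_genes) < pr
      counts <- integer(n_genes)
      nexp <- sum(expressed)
      if (nexp) counts[expressed] <- rnbinom(nexp, mu = mu, size = 2) + 1L
      counts
    })
    m <- Matrix::Matrix(
      matrix(unlist(cols), nrow = n_genes,
             dimnames = list(genes, meta$cell_id)),
      sparse = TRUE)
    methods::as(m, "CsparseMatrix")
  })
}

#' Write contigs as an AIRR Rearrangement TSV
#' @param contigs contig table from [simulate_repertoire()] or
#'   [parse_contigs()].
#' @param path output TSV path.
#' @export
write_airr <- function(contigs, path) {
  out <- data.table::as.data.table(contigs)
  data.table::setnames(out, c("contig_id", "umi_count", "read_count"),
                       c("sequence_id", "duplicate_count", "consensus_count"),
                       skip_absent = TRUE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a count matrix as an MTX bundle (matrix.mtx, barcodes.tsv,
#' features.tsv)
#' @param mat genes x cells sparse matrix.
#' @param dir output directory (created if needed).
#' @export
write_mtx_bundle <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat, file.path(dir, "matrix.mtx"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read an MTX bundle written by [write_mtx_bundle()]
#' @param dir directory containing matrix.mtx, barcodes.tsv, features.tsv.
#' @return sparse genes x cells matrix with dimnames.
#' @export
read_mtx_bundle <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  methods::as(m, "CsparseMatrix")
}
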