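#' Raw clonal-overlap matrix between subsets
#'
#' For each unordered pair of distinct subsets (i, j), sums over clones with
#' at least one cell in each of i and j the absolute number of the clone's
#' cells in i plus its cells in j. Cells (not clones or pairs) are counted;
#' a clone spanning three subsets contributes to each pair independently.
#'
#' @param cells data.table with `cell_id`, `clone_id` and `subset` for one
#'   sample (cells without a clone are ignored).
#' @param subset_levels optional character vector fixing matrix dimensions.
#' @return symmetric numeric matrix with zero diagonal, class
#'   `overlap_matrix` with `attr(, "normalised") = FALSE`.
#' @export
clonal_overlap <- function(cells, subset_levels = NULL) {
  dt <- data.table::as.data.table(cells)[!is.na(clone_id)]
  levs <- if (is.null(subset_levels)) sort(unique(dt$subset)) else
    subset_levels
  m <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  if (nrow(dt)) {
    counts <- dt[, .(n = .N), by = .(clone_id, subset)]
    for (cl in split(counts, by = "clone_id")) {
      if (nrow(cl) < 2L) next
      for (a in seq_len(nrow(cl) - 1L)) {
        for (b in (a + 1L):nrow(cl)) {
          i <- cl$subset[a]; j <- cl$subset[b]
          m[i, j] <- m[i, j] + cl$n[a] + cl$n[b]
          m[j, i] <- m[i, j]
        }
      }
    }
  }
  structure(m, class = c("overlap_matrix", class(m)), normalised = FALSE)
}

#' Normalise clonal-overlap matrices to sum to 1
#'
#' Samples with at least one nonzero entry are scaled so all entries sum to
#' 1 (jointly over subset pairs, per sample); all-zero samples are excluded
#' and reported via `attr(, "excluded")`.
#'
#' @param matrices named list of raw matrices from [clonal_overlap()].
#' @return named list of normalised matrices (`attr(, "normalised") = TRUE`
#'   each), with attribute `excluded` naming the dropped samples.
#' @export
normalize_overlap <- function(matrices) {
  sums <- vapply(matrices, sum, numeric(1))
  excluded <- names(matrices)[sums == 0]
  out <- lapply(matrices[sums > 0], function(m) {
    r <- m / sum(m)
    attr(r, "normalised") <- TRUE
    r
  })
  attr(out, "excluded") <- excluded
  out
}

#' Classify clones by compartment span
#'
#' A clone with cells in both blood and tumour is recirculating; otherwise
#' it is labelled by its single compartment.
#'
#' @param clone_table clone assignments (`cell_id`, `clone_id`).
#' @param meta per-cell metadata with `cell_id` and `compartment`
#'   (`"blood"` or `"tumour"`).
#' @return data.table `clone_id`, `call` in
#'   `{"recirculating", "blood_only", "tumour_only"}`.
#' @export
classify_compartments <- function(clone_table, meta) {
  dt <- merge(data.table::as.data.table(clone_table),
              data.table::as.data.table(meta)[, .(cell_id, compartment)],
              by = "cell_id")
  bad <- setdiff(unique(dt$compartment), c("blood", "tumour"))
  if (length(bad)) {
    stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dt[, .(call = {
    comps <- unique(compartment)
    if (length(comps) == 2L) "recirculating"
    else if (comps == "blood") "blood_only" else "tumour_only"
  }), by = clone_id]
}

#' Clonal migration linkage between blood and tumour phenotypes
#'
#' For each recirculating clone, every (blood phenotype, tumour phenotype)
#' combination present in the clone contributes weight 1. Per-patient
#' matrices are normalised to sum to 1 and averaged across patients with at
#' least one recirculating clone ("relative means").
#'
#' @param clone_table clone assignments.
#' @param meta per-cell metadata with `cell_id`, `compartment`, `subset`,
#'   `patient`.
#' @return list with `mean` (blood-phenotype x tumour-phenotype matrix) and
#'   `per_patient` (named list of raw count matrices).
#' @export
migration_linkage <- function(clone_table, meta) {
  metadt <- data.table::as.data.table(meta)
  dt <- merge(data.table::as.data.table(clone_table),
              metadt[, .(cell_id, compartment, subset, patient)],
              by = "cell_id")
  calls <- classify_compartments(clone_table, metadt)
  recirc <- calls[call == "recirculating", clone_id]
  blood_levs <- sort(unique(metadt[compartment == "blood", subset]))
  tum_levs <- sort(unique(metadt[compartment == "tumour", subset]))
  empty <- matrix(0, length(blood_levs), length(tum_levs),
                  dimnames = list(blood_levs, tum_levs))
  per_patient <- list()
  for (p in sort(unique(dt$patient))) {
    m <- empty
    pdt <- dt[patient == p & clone_id %in% recirc]
    for (cl in split(pdt, by = "clone_id")) {
      bp <- unique(cl[compartment == "blood", subset])
      tp <- unique(cl[compartment == "tumour", subset])
      if (length(bp) && length(tp)) m[bp, tp] <- m[bp, tp] + 1
    }
    per_patient[[p]] <- m
  }
  nonzero <- Filter(function(m) sum(m) > 0, per_patient)
  mean_mat <- if (length(nonzero)) {
    Reduce(`+`, lapply(nonzero, function(m) m / sum(m))) / length(nonzero)
  } else empty
  list(mean = mean_mat, per_patient = per_patient)
}

#' Screen TCRs against a known-specificity reference
#'
#' Exact-string matching of the beta-chain CDR3 amino-acid sequence against
#' a VDJdb/McPAS-style reference (`cdr3_aa`, optional `v_gene`,
#' `antigen_category`); when the reference row carries a V gene it must
#' also match (allele-stripped). Returns per-cell annotations and, when
#' compartment calls are supplied, the fraction of clones matched per
#' compartment class.
#'
#' @param chains TCR chain assignments from [select_chains()].
#' @param reference reference data.table/data.frame; column `cdr3_aa`
#'   required.
#' @param clone_table optional clone assignments used for the per-class
#'   enrichment summary.
#' @param compartment_calls optional output of [classify_compartments()].
#' @return list with `cells` (`cell_id`, `matched`, `antigen_category`) and
#'   `by_class` (`call`, `n_clones`, `n_matched`, `fraction`) or `NULL`.
#' @export
screen_known_tcrs <- function(chains, reference, clone_table = NULL,
                              compartment_calls = NULL) {
  ref <- data.table::as.data.table(reference)
  if (!"cdr3_aa" %in% names(ref)) {
    stop("reference must have a cdr3_aa column", call. = FALSE)
  }
  if (!"antigen_category" %in% names(ref)) {
    ref[, antigen_category := "unknown"]
  }
  has_v <- "v_gene" %in% names(ref)
  dt <- data.table::as.data.table(chains)
  dt <- dt[receptor_class == "TCR" & !is.na(heavy_junction_aa)]
  ann <- dt[, {
    hits <- ref[cdr3_aa == heavy_junction_aa]
    if (has_v && nrow(hits)) {
      hits <- hits[is.na(v_gene) | v_gene == "" |
                     strip_allele(v_gene) == strip_allele(heavy_v_call)]
    }
    .(matched = nrow(hits) > 0L,
      antigen_category = if (nrow(hits)) {
        paste(sort(unique(hits$antigen_category)), collapse = ";")
      } else NA_character_)
  }, by = cell_id]
  by_class <- NULL
  if (!is.null(clone_table) && !is.null(compartment_calls)) {
    ct <- merge(data.table::as.data.table(clone_table),
                ann[, .(cell_id, matched)], by = "cell_id")
    per_clone <- ct[, .(matched = any(matched)), by = clone_id]
    per_clone <- merge(per_clone,
                       data.table::as.data.table(compartment_calls),
                       by = "clone_id")
    by_class <- per_clone[, .(n_clones = .N, n_matched = sum(matched),
                              fraction = mean(matched)), by = call]
  }
  list(cells = ann[], by_class = by_class)
}
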