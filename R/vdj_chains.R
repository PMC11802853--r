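#' Parse per-droplet VDJ contig annotations
#'
#' Reads either an AIRR Rearrangement TSV (columns `cell_id`, `locus`,
#' `v_call`, `j_call`, `c_call`, `junction`, `junction_aa`,
#' `duplicate_count`, `v_identity`; optional `consensus_count`,
#' `v_sequence_length`, `sequence_id`) or a 10x
#' `filtered_contig_annotations.csv` (columns `barcode`, `chain`, `v_gene`,
#' `j_gene`, `c_gene`, `cdr3_nt`, `cdr3`, `umis`, `reads`). Rows whose UMI
#' count cannot be parsed as a non-negative number are skipped; the skip
#' count is attached as `attr(, "skipped")`.
#'
#' @param path input file.
#' @param dialect `"airr"` or `"10x_contig_csv"`.
#' @return data.table of contig records with canonical columns `cell_id`,
#'   `contig_id`, `locus`, `v_call`, `j_call`, `c_call`, `junction`,
#'   `junction_aa`, `umi_count`, `read_count`, `v_identity`,
#'   `v_sequence_length`.
#' @export
parse_contigs <- function(path, dialect = c("airr", "10x_contig_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "airr") {
    raw <- data.table::fread(path, sep = "\t", header = TRUE)
    required <- c("cell_id", "locus", "v_call", "j_call", "junction",
                  "duplicate_count")
    rename <- c(sequence_id = "contig_id", duplicate_count = "umi_count",
                consensus_count = "read_count")
  } else {
    raw <- data.table::fread(path, sep = ",", header = TRUE)
    required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt", "umis")
    rename <- c(barcode = "cell_id", chain = "locus", v_gene = "v_call",
                j_gene = "j_call", c_gene = "c_call", cdr3_nt = "junction",
                cdr3 = "junction_aa", umis = "umi_count",
                reads = "read_count")
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s input is missing required column(s): %s",
                 dialect, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  old <- intersect(names(rename), names(raw))
  if (length(old)) data.table::setnames(raw, old, unname(rename[old]))
  for (col in c("contig_id", "c_call", "junction_aa")) {
    if (!col %in% names(raw)) raw[, (col) := NA_character_]
  }
  for (col in c("read_count", "v_identity", "v_sequence_length")) {
    if (!col %in% names(raw)) raw[, (col) := NA_real_]
  }
  for (col in c("junction", "junction_aa", "c_call", "contig_id")) {
    raw[, (col) := as.character(get(col))]
  }
  umi <- suppressWarnings(as.numeric(raw$umi_count))
  bad <- !is.finite(umi) | umi < 0
  out <- raw[!bad]
  out[, umi_count := as.integer(umi[!bad])]
  out[, read_count := suppressWarnings(as.numeric(read_count))]
  out[, v_identity := suppressWarnings(as.numeric(v_identity))]
  cols <- c("cell_id", "contig_id", "locus", "v_call", "j_call", "c_call",
            "junction", "junction_aa", "umi_count", "read_count",
            "v_identity", "v_sequence_length")
  out <- out[, cols, with = FALSE]
  data.table::setattr(out, "skipped", sum(bad))
  out[]
}

.bcr_loci <- c("IGH", "IGK", "IGL")
.tcr_loci <- c("TRA", "TRB")

#' Select the most probable chain pair per droplet
#'
#' For each droplet, keep the contig with maximal UMI count in each chain
#' class: heavy (IGH) / beta (TRB), and light (IGK and IGL compete in a
#' single slot) / alpha (TRA). Ties break by higher read count, then by the
#' lexicographically smallest contig identifier, so the result does not
#' depend on input row order. Droplets carrying both BCR and TCR loci are
#' flagged `receptor_class = "ambiguous"` and get no chains.
#'
#' @param contigs contig table from [parse_contigs()].
#' @return data.table with one row per droplet: `cell_id`,
#'   `receptor_class` (`"BCR"`, `"TCR"` or `"ambiguous"`), `complete_pair`,
#'   and the selected chains flattened as `heavy_*` / `light_*` columns
#'   (`heavy_` = IGH or TRB, `light_` = IGK/IGL or TRA).
#' @export
select_chains <- function(contigs) {
  dt <- data.table::as.data.table(contigs)
  known <- dt[locus %in% c(.bcr_loci, .tcr_loci)]
  # deterministic ordering: umi desc, reads desc, contig id asc
  setorderv(known,
            c("cell_id", "umi_count", "read_count", "contig_id"),
            order = c(1L, -1L, -1L, 1L), na.last = TRUE)
  cls <- known[, .(
    has_bcr = any(locus %in% .bcr_loci),
    has_tcr = any(locus %in% .tcr_loci)
  ), by = cell_id]
  cls[, receptor_class := data.table::fifelse(
    has_bcr & has_tcr, "ambiguous",
    data.table::fifelse(has_bcr, "BCR", "TCR"))]
  known[, slot := data.table::fifelse(locus %in% c("IGH", "TRB"),
                                      "heavy", "light")]
  picks <- known[cls[receptor_class != "ambiguous"], on = "cell_id"][
    , .SD[1L], by = .(cell_id, slot)]
  chain_cols <- c("contig_id", "locus", "v_call", "j_call", "c_call",
                  "junction", "junction_aa", "umi_count", "v_identity",
                  "v_sequence_length")
  wide <- data.table::dcast(
    picks, cell_id ~ slot,
    value.var = chain_cols)
  # dcast names are <col>_<slot>; flip to <slot>_<col>
  for (col in chain_cols) {
    for (sl in c("heavy", "light")) {
      oldn <- paste(col, sl, sep = "_")
      if (oldn %in% names(wide)) {
        data.table::setnames(wide, oldn, paste(sl, col, sep = "_"))
      }
    }
  }
  out <- merge(cls[, .(cell_id, receptor_class)], wide,
               by = "cell_id", all.x = TRUE)
  for (col in c(paste0("heavy_", chain_cols), paste0("light_", chain_cols))) {
    if (!col %in% names(out)) out[, (col) := NA]
  }
  out[, complete_pair := !is.na(heavy_contig_id) & !is.na(light_contig_id)]
  data.table::setorder(out, cell_id)
  out[]
}

#' Somatic hypermutation count from V-segment identity
#'
#' Converts the percent identity of the aligned V segment into an integer
#' point-mutation count: `round((1 - v_identity/100) * v_sequence_length)`.
#'
#' @param v_identity percent identity in \[0, 100\] (vectorised).
#' @param v_sequence_length aligned V-segment length in nucleotides (> 0).
#' @return integer mutation count(s), >= 0.
#' @export
shm_count <- function(v_identity, v_sequence_length) {
  if (any(!is.finite(v_identity)) || any(v_identity < 0) ||
      any(v_identity > 100)) {
    stop("v_identity must lie in [0, 100]", call. = FALSE)
  }
  if (any(!is.finite(v_sequence_length)) || any(v_sequence_length <= 0)) {
    stop("v_sequence_length must be > 0", call. = FALSE)
  }
  as.integer(round((1 - v_identity / 100) * v_sequence_length))
}

#' Isotype usage proportions per sample and group
#'
#' For BCR droplets with a heavy-chain constant-region call, tabulates the
#' proportion of each isotype per sample and grouping variable. Cells
#' lacking a `c_call` are excluded; their number is attached as
#' `attr(, "excluded")`.
#'
#' @param assignments chain assignments from [select_chains()].
#' @param meta per-cell metadata with `cell_id`, `sample_id` and the
#'   grouping column.
#' @param by metadata column to group by within sample (default
#'   `"subset"`).
#' @return data.table `sample_id`, group column, `isotype`, `n`, `prop`;
#'   proportions sum to 1 within each (sample, group).
#' @export
isotype_usage <- function(assignments, meta, by = "subset") {
  dt <- merge(
    data.table::as.data.table(assignments)[receptor_class == "BCR",
                                           .(cell_id, heavy_c_call)],
    data.table::as.data.table(meta), by = "cell_id")
  excluded <- dt[is.na(heavy_c_call) | heavy_c_call == "", .N]
  dt <- dt[!is.na(heavy_c_call) & heavy_c_call != ""]
  counts <- dt[, .(n = .N), by = c("sample_id", by, "heavy_c_call")]
  data.table::setnames(counts, "heavy_c_call", "isotype")
  counts[, prop := n / sum(n), by = c("sample_id", by)]
  data.table::setorderv(counts, c("sample_id", by, "isotype"))
  data.table::setattr(counts, "excluded", excluded)
  counts[]
}
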