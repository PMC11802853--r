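#' Build a point-mutation network over equal-role DNA sequences
#'
#' Nodes are the unique sequences; an undirected edge joins two sequences of
#' equal length at Hamming distance exactly 1. Edges are found with a
#' positional-wildcard hash (each sequence is keyed L times with one
#' position masked), which is O(nL) rather than all-pairs.
#'
#' @param sequences character vector of nucleotide strings (A/C/G/T/N).
#' @return an [igraph::graph] whose vertex `name`s are the unique sequences.
#' @export
build_mutation_network <- function(sequences) {
  seqs <- unique(sequences)
  if (length(seqs) && any(grepl("[^ACGTN]", seqs))) {
    stop("sequences must contain only A, C, G, T or N", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = length(seqs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = seqs)
  if (length(seqs) < 2L) return(g)
  edges <- mutation_edge_list(seqs)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  g
}

# Hamming-distance-1 pairs among unique sequences, as index pairs (i < j).
mutation_edge_list <- function(seqs) {
  pairs <- list()
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    if (length(idx) < 2L) next
    mat <- do.call(rbind, strsplit(seqs[idx], ""))
    for (p in seq_len(len)) {
      key <- apply(mat[, -p, drop = FALSE], 1L, paste, collapse = "")
      grp <- split(idx, key)
      for (members in grp[lengths(grp) > 1L]) {
        cmb <- utils::combn(sort(members), 2L)
        pairs[[length(pairs) + 1L]] <-
          data.table::data.table(i = cmb[1L, ], j = cmb[2L, ])
      }
    }
  }
  if (!length(pairs)) return(data.table::data.table(i = integer(),
                                                    j = integer()))
  # sequences sharing a masked key at position p differ only at p; distinct
  # sequences therefore have Hamming distance exactly 1
  unique(data.table::rbindlist(pairs))
}

# Deterministic clone ids from a component labelling: size desc, then
# smallest member cell_id. Returns character vector parallel to cells.
label_clones <- function(comp, cell_id, prefix) {
  dt <- data.table::data.table(comp = comp, cell_id = cell_id)
  info <- dt[, .(size = .N, first_cell = min(cell_id)), by = comp]
  data.table::setorder(info, -size, first_cell)
  info[, clone_id := sprintf("%s%04d", prefix, .I)]
  info$clone_id[match(comp, info$comp)]
}

# Clone-id prefix: embeds the patient when present so per-patient calls can
# be concatenated without id collisions.
clone_prefix <- function(dt, base) {
  if ("patient" %in% names(dt) && nrow(dt) &&
      !is.na(dt$patient[1L])) paste0(dt$patient[1L], "_", base) else base
}

#' Call B-cell clones from heavy-chain assignments
#'
#' Clones are the connected components of the union of two pairwise
#' relations on cells of one patient: (a) mutation-network edges between
#' heavy-chain CDR3 DNA sequences of equal length at Hamming distance 1
#' (identical sequences share a network node), and (b) identical CDR3 DNA
#' with the same IGHV family and IGHJ family. Components are merged with
#' union-find; clone identifiers are ordered by size (descending), ties by
#' smallest member cell id.
#'
#' @param chains chain-assignment table from [select_chains()] (BCR rows
#'   with a heavy chain are used); columns `cell_id`, `heavy_junction`,
#'   `heavy_v_call`, `heavy_j_call` and optionally `patient`.
#' @return data.table `cell_id`, `clone_id`, `clone_size`,
#'   `receptor_class = "BCR"`. If `chains` carries a `patient` column it
#'   must hold a single value (clones never span patients) and clone ids
#'   are prefixed with it, so per-patient results concatenate safely.
#' @export
call_bcr_clones <- function(chains) {
  dt <- data.table::as.data.table(chains)
  if ("patient" %in% names(dt) && length(unique(dt$patient)) > 1L) {
    stop("cells from more than one patient; call clones per patient",
         call. = FALSE)
  }
  if ("receptor_class" %in% names(dt)) dt <- dt[receptor_class == "BCR"]
  dt <- dt[!is.na(heavy_junction) & heavy_junction != ""]
  if (!nrow(dt)) {
    return(data.table::data.table(cell_id = character(),
                                  clone_id = character(),
                                  clone_size = integer(),
                                  receptor_class = character()))
  }
  n <- nrow(dt)
  uf <- new_union_find(n)
  # criterion (a): same network node (identical CDR3 DNA) ...
  grp <- split(seq_len(n), dt$heavy_junction)
  for (members in grp[lengths(grp) > 1L]) {
    for (k in seq_along(members)[-1L]) uf$union(members[1L], members[k])
  }
  # ... or Hamming-distance-1 CDR3 DNA (SHM edge)
  useq <- unique(dt$heavy_junction)
  edges <- mutation_edge_list(useq)
  if (nrow(edges)) {
    rep_of <- vapply(split(seq_len(n), dt$heavy_junction),
                     function(ix) ix[1L], integer(1))
    for (r in seq_len(nrow(edges))) {
      uf$union(rep_of[[useq[edges$i[r]]]], rep_of[[useq[edges$j[r]]]])
    }
  }
  # criterion (b): identical CDR3 DNA + same IGHV and IGHJ family
  keyb <- paste(dt$heavy_junction, gene_family(dt$heavy_v_call),
                gene_family(dt$heavy_j_call), sep = "|")
  grpb <- split(seq_len(n), keyb)
  for (members in grpb[lengths(grpb) > 1L]) {
    for (k in seq_along(members)[-1L]) uf$union(members[1L], members[k])
  }
  comp <- uf$components()
  out <- data.table::data.table(
    cell_id = dt$cell_id,
    clone_id = label_clones(comp, dt$cell_id, clone_prefix(dt, "B_clone")),
    receptor_class = "BCR")
  out[, clone_size := .N, by = clone_id]
  data.table::setorder(out, clone_id, cell_id)
  out[, .(cell_id, clone_id, clone_size, receptor_class)]
}

#' Call T-cell clones from TRB (and optional TRA) assignments
#'
#' Two cells are clonally related when their TRB CDR3 DNA, TRBV gene and
#' TRBJ gene are identical and, when both cells carry a TRA chain, their TRA
#' CDR3 DNA also matches (a TRA mismatch separates them). Clones are the
#' transitive closure of this pairwise relation.
#'
#' @param chains chain-assignment table from [select_chains()] (TCR rows
#'   with a beta chain are used).
#' @return data.table `cell_id`, `clone_id`, `clone_size`,
#'   `receptor_class = "TCR"`; patient handling as in [call_bcr_clones()].
#' @export
call_tcr_clones <- function(chains) {
  dt <- data.table::as.data.table(chains)
  if ("patient" %in% names(dt) && length(unique(dt$patient)) > 1L) {
    stop("cells from more than one patient; call clones per patient",
         call. = FALSE)
  }
  if ("receptor_class" %in% names(dt)) dt <- dt[receptor_class == "TCR"]
  dt <- dt[!is.na(heavy_junction) & heavy_junction != ""]
  if (!nrow(dt)) {
    return(data.table::data.table(cell_id = character(),
                                  clone_id = character(),
                                  clone_size = integer(),
                                  receptor_class = character()))
  }
  n <- nrow(dt)
  uf <- new_union_find(n)
  trb_key <- paste(dt$heavy_junction, strip_allele(dt$heavy_v_call),
                   strip_allele(dt$heavy_j_call), sep = "|")
  tra <- if ("light_junction" %in% names(dt)) dt$light_junction else
    rep(NA_character_, n)
  for (members in split(seq_len(n), trb_key)) {
    if (length(members) < 2L) next
    for (a in seq_along(members)[-length(members)]) {
      for (b in (a + 1L):length(members)) {
        i <- members[a]; j <- members[b]
        ta <- tra[i]; tb <- tra[j]
        if (is.na(ta) || ta == "" || is.na(tb) || tb == "" ||
            identical(ta, tb)) {
          uf$union(i, j)
        }
      }
    }
  }
  comp <- uf$components()
  out <- data.table::data.table(
    cell_id = dt$cell_id,
    clone_id = label_clones(comp, dt$cell_id, clone_prefix(dt, "T_clone")),
    receptor_class = "TCR")
  out[, clone_size := .N, by = clone_id]
  data.table::setorder(out, clone_id, cell_id)
  out[, .(cell_id, clone_id, clone_size, receptor_class)]
}

#' Clone-size histogram per sample
#'
#' Clone sizes are recounted within each sample (a clone spanning samples
#' contributes its per-sample cell counts), so each histogram's total equals
#' the number of assigned cells in that sample.
#'
#' @param clone_table output of [call_bcr_clones()] / [call_tcr_clones()].
#' @param meta optional per-cell metadata with `cell_id` and `sample_id`;
#'   without it all cells form one sample `"all"`.
#' @return data.table `sample_id`, `size`, `n_clones`, `n_cells`.
#' @export
clone_size_spectrum <- function(clone_table, meta = NULL) {
  dt <- data.table::as.data.table(clone_table)
  if (is.null(meta)) {
    dt[, sample_id := "all"]
  } else {
    dt <- merge(dt, data.table::as.data.table(meta)[, .(cell_id, sample_id)],
                by = "cell_id")
  }
  per_clone <- dt[, .(size = .N), by = .(sample_id, clone_id)]
  hist <- per_clone[, .(n_clones = .N), by = .(sample_id, size)]
  hist[, n_cells := size * n_clones]
  data.table::setorder(hist, sample_id, size)
  hist[]
}

#' Summarise clones against cell metadata
#'
#' @param clone_table clone assignments.
#' @param meta per-cell metadata with `cell_id`, `subset`, `compartment`,
#'   `patient`.
#' @return data.table per clone: size, subsets spanned, compartments
#'   spanned, patient.
#' @export
clone_summary <- function(clone_table, meta) {
  dt <- merge(data.table::as.data.table(clone_table),
              data.table::as.data.table(meta), by = "cell_id")
  dt[, .(
    size = .N,
    receptor_class = receptor_class[1L],
    subsets = paste(sort(unique(subset)), collapse = ";"),
    compartments = paste(sort(unique(compartment)), collapse = ";"),
    patient = paste(sort(unique(patient)), collapse = ";")
  ), by = clone_id]
}
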