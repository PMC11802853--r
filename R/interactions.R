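#' Fraction of cells expressing a gene
#'
#' Expression means raw count > 0, making the fraction invariant to
#' per-cell count rescaling.
#'
#' @param mat genes x cells count matrix (sparse or dense) with dimnames.
#' @param cells character vector of cell ids (columns of `mat`).
#' @param gene gene name; absent genes return `NA` with a message.
#' @return fraction in \[0, 1\], or `NA` when the gene is absent.
#' @export
expressing_fraction <- function(mat, cells, gene) {
  stopifnot(length(cells) > 0)
  if (!gene %in% rownames(mat)) {
    message("gene not in matrix, reported as missing: ", gene)
    return(NA_real_)
  }
  mean(mat[gene, cells, drop = TRUE] > 0)
}

#' Load the bundled receptor-ligand pair table
#'
#' A small curated immune-specific ligand/receptor reference (columns
#' `ligand`, `receptor`, `tag`) shipped with the package; users may supply
#' their own table of the same shape to [interaction_strengths()].
#'
#' @return data.table `ligand`, `receptor`, `tag`.
#' @export
default_lr_pairs <- function() {
  data.table::fread(system.file("extdata", "lr_pairs.csv",
                                package = "immunoclone"))
}

#' Cell-count-independent receptor-ligand interaction strengths
#'
#' For each patient and each ordered (sender subset, receiver subset) pair
#' -- self-pairs included by default -- the strength of a ligand-receptor
#' pair is the product of the fraction of sender cells expressing the
#' ligand and the fraction of receiver cells expressing the receptor. Only
#' subsets with at least `min_cells` cells in the patient are eligible, so
#' strengths are independent of subset abundance.
#'
#' @param mat genes x cells count matrix.
#' @param meta per-cell metadata with `cell_id`, `patient`, `subset`.
#' @param pairs ligand/receptor table (`ligand`, `receptor`; see
#'   [default_lr_pairs()]).
#' @param min_cells minimum subset size per patient (default 3).
#' @param include_self include sender == receiver pairs (default TRUE).
#' @return data.table (`patient`, `sender`, `receiver`, `ligand`,
#'   `receptor`, `strength` in \[0, 1\]) of class `interaction_tensor`;
#'   pairs whose ligand or receptor is absent from the matrix are dropped
#'   and listed in `attr(, "missing_genes")`; eligible subsets per patient
#'   in `attr(, "eligible")`.
#' @export
interaction_strengths <- function(mat, meta, pairs = default_lr_pairs(),
                                  min_cells = 3L, include_self = TRUE) {
  metadt <- data.table::as.data.table(meta)
  pr <- data.table::as.data.table(pairs)
  stopifnot(all(c("ligand", "receptor") %in% names(pr)))
  genes_needed <- unique(c(pr$ligand, pr$receptor))
  missing_genes <- setdiff(genes_needed, rownames(mat))
  if (length(missing_genes)) {
    message("dropping pairs with gene(s) absent from matrix: ",
            paste(missing_genes, collapse = ", "))
    pr <- pr[!(ligand %in% missing_genes) & !(receptor %in% missing_genes)]
  }
  out <- list()
  eligible <- list()
  for (p in sort(unique(metadt$patient))) {
    pm <- metadt[patient == p]
    sizes <- pm[, .N, by = subset]
    elig <- sort(sizes[N >= min_cells, subset])
    eligible[[p]] <- elig
    if (!length(elig) || !nrow(pr)) next
    # expressing fractions: subsets x needed genes
    gneed <- unique(c(pr$ligand, pr$receptor))
    frac <- vapply(elig, function(s) {
      cells <- pm[subset == s, cell_id]
      Matrix::rowMeans(mat[gneed, cells, drop = FALSE] > 0)
    }, numeric(length(gneed)))
    frac <- matrix(frac, nrow = length(gneed),
                   dimnames = list(gneed, elig))
    grid <- data.table::CJ(sender = elig, receiver = elig)
    if (!include_self) grid <- grid[sender != receiver]
    block <- grid[, {
      data.table::data.table(
        ligand = pr$ligand, receptor = pr$receptor,
        strength = frac[pr$ligand, sender] * frac[pr$receptor, receiver])
    }, by = .(sender, receiver)]
    block[, patient := p]
    out[[p]] <- block
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(sender = character(), receiver = character(),
                           ligand = character(), receptor = character(),
                           strength = numeric(), patient = character())
  data.table::setcolorder(res, c("patient", "sender", "receiver",
                                 "ligand", "receptor", "strength"))
  data.table::setattr(res, "missing_genes", missing_genes)
  data.table::setattr(res, "eligible", eligible)
  data.table::setattr(res, "class",
                      c("interaction_tensor", class(res)))
  res[]
}

#' Incoming and outgoing link counts per subset
#'
#' A link is a nonzero interaction strength; outgoing counts tally links by
#' sender, incoming by receiver, per patient. The totals are conserved:
#' sum of outgoing equals sum of incoming equals the number of nonzero
#' entries.
#'
#' @param tensor output of [interaction_strengths()].
#' @return data.table `patient`, `subset`, `outgoing`, `incoming`.
#' @export
link_counts <- function(tensor) {
  dt <- data.table::as.data.table(tensor)[strength > 0]
  outd <- dt[, .(outgoing = .N), by = .(patient, subset = sender)]
  ind <- dt[, .(incoming = .N), by = .(patient, subset = receiver)]
  res <- merge(outd, ind, by = c("patient", "subset"), all = TRUE)
  for (col in c("outgoing", "incoming")) {
    res[is.na(get(col)), (col) := 0L]
  }
  data.table::setorder(res, patient, subset)
  res[]
}

#' Ranked receptor interactions toward one receiver subset
#'
#' Averages strengths across patients for every (sender subset, ligand,
#' receptor) targeting the given receiver subset through the named
#' receptors, and returns the strongest `top_k` entries (ties broken
#' lexicographically by sender, ligand, receptor).
#'
#' @param tensor output of [interaction_strengths()].
#' @param receiver receiver subset name.
#' @param receptors character vector of receptor genes of interest.
#' @param top_k maximum entries returned (default 20).
#' @return data.table `sender`, `ligand`, `receptor`, `mean_strength`.
#' @export
rank_receptor_interactions <- function(tensor, receiver, receptors,
                                       top_k = 20L) {
  dt <- data.table::as.data.table(tensor)
  known <- unique(dt$receptor)
  unknown <- setdiff(receptors, known)
  if (length(unknown)) {
    stop("unknown receptor(s): ", paste(unknown, collapse = ", "),
         "; known receptors: ", paste(sort(known), collapse = ", "),
         call. = FALSE)
  }
  recv <- receiver
  sub <- dt[receiver == recv & receptor %in% receptors]
  if (!nrow(sub)) {
    return(data.table::data.table(sender = character(),
                                  ligand = character(),
                                  receptor = character(),
                                  mean_strength = numeric()))
  }
  agg <- sub[, .(mean_strength = mean(strength)),
             by = .(sender, ligand, receptor)]
  agg <- agg[mean_strength > 0]
  data.table::setorderv(agg, c("mean_strength", "sender", "ligand",
                               "receptor"), order = c(-1L, 1L, 1L, 1L))
  head(agg, top_k)
}

#' Compare interaction edges between patient groups
#'
#' For each (sender, receiver) edge, the per-patient vectors of
#' ligand-receptor strengths are compared between groups with a two-sided
#' MANOVA (Pillai's trace; see [manova_compare()]). Direction is the sign
#' of (mean strength in the first group level) minus (second level), so
#' swapping the group labels flips every direction.
#'
#' @param tensor output of [interaction_strengths()].
#' @param groups named character vector or data.table (`patient`, `group`)
#'   mapping patient -> group; exactly 2 groups, each with >= 2 patients.
#' @return data.table `sender`, `receiver`, `statistic`, `p_value`,
#'   `direction`.
#' @export
compare_edge_groups <- function(tensor, groups) {
  dt <- data.table::as.data.table(tensor)
  if (is.data.frame(groups)) {
    gmap <- setNames(as.character(groups$group), groups$patient)
  } else {
    gmap <- groups
  }
  dt[, group := gmap[patient]]
  if (anyNA(dt$group)) stop("every patient needs a group", call. = FALSE)
  glev <- sort(unique(gmap))
  if (length(glev) != 2L) stop("exactly 2 groups required", call. = FALSE)
  sizes <- table(gmap)
  if (any(sizes < 2L)) {
    stop("each group needs >= 2 patients", call. = FALSE)
  }
  res <- list()
  for (key in split(dt, by = c("sender", "receiver"))) {
    wide <- data.table::dcast(key, patient + group ~ ligand + receptor,
                              value.var = "strength", fill = NA)
    feat <- as.matrix(wide[, -(1:2)])
    keep <- stats::complete.cases(feat)
    wide <- wide[keep]; feat <- feat[keep, , drop = FALSE]
    if (length(unique(wide$group)) < 2L || any(table(wide$group) < 2L)) next
    cmp <- suppressWarnings(manova_compare(feat, wide$group))
    m1 <- mean(feat[wide$group == glev[1L], , drop = FALSE])
    m2 <- mean(feat[wide$group == glev[2L], , drop = FALSE])
    res[[length(res) + 1L]] <- data.table::data.table(
      sender = key$sender[1L], receiver = key$receiver[1L],
      statistic = cmp$statistic, p_value = cmp$p_value,
      direction = sign(m1 - m2))
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, sender, receiver)
  out[]
}
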