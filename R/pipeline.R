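#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration, collects *all* violations (unknown keys,
#' invalid parameter values, missing referenced paths) rather than failing
#' at the first, and returns a normalized `run_config` with defaults
#' filled in. Seeds are mandatory: subsampled statistics are only
#' comparable across runs when reproducible.
#'
#' @param path YAML config path, or an already-parsed list.
#' @return object of class `run_config`; errors (with every violation
#'   listed) if invalid.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  } else path
  errs <- character(0)
  known_top <- c("seed", "outdir", "simulate", "inputs", "clonality",
                 "interactions", "scoring")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) {
    errs <- c(errs, "seed is mandatory (wall-clock seeding is not allowed)")
  } else if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    errs <- c(errs, "seed must be a single integer")
  }
  sim_known <- c("n_patients", "cells_per_sample", "shared_clone_prob",
                 "cross_subset_prob", "shm_rate", "depth_mean",
                 "clone_size_law", "decoy_prob")
  sim <- cfg$simulate %||% list()
  bad_sim <- setdiff(names(sim), sim_known)
  if (length(bad_sim)) {
    errs <- c(errs, paste0("unknown simulate key(s): ",
                           paste(bad_sim, collapse = ", ")))
  }
  clon <- cfg$clonality %||% list()
  bad_cl <- setdiff(names(clon), c("intra_depth", "inter_depth", "reps"))
  if (length(bad_cl)) {
    errs <- c(errs, paste0("unknown clonality key(s): ",
                           paste(bad_cl, collapse = ", ")))
  }
  clon$intra_depth <- clon$intra_depth %||% 5L
  clon$inter_depth <- clon$inter_depth %||% 50L
  clon$reps <- clon$reps %||% 1000L
  for (k in c("intra_depth", "inter_depth")) {
    if (!is.numeric(clon[[k]]) || clon[[k]] < 2) {
      errs <- c(errs, paste0("clonality ", k, " must be >= 2"))
    }
  }
  if (!is.numeric(clon$reps) || clon$reps < 1) {
    errs <- c(errs, "clonality reps must be >= 1")
  }
  inter <- cfg$interactions %||% list()
  bad_in <- setdiff(names(inter), c("min_cells", "include_self", "pairs"))
  if (length(bad_in)) {
    errs <- c(errs, paste0("unknown interactions key(s): ",
                           paste(bad_in, collapse = ", ")))
  }
  inter$min_cells <- inter$min_cells %||% 3L
  inter$include_self <- inter$include_self %||% TRUE
  if (!is.null(inter$pairs) && !file.exists(inter$pairs)) {
    errs <- c(errs, paste0("interactions pairs file not found: ",
                           inter$pairs))
  }
  scoring <- cfg$scoring %||% list()
  bad_sc <- setdiff(names(scoring),
                    c("gene_set", "positive_subset", "negative_subset",
                      "n_bins", "n_ctrl"))
  if (length(bad_sc)) {
    errs <- c(errs, paste0("unknown scoring key(s): ",
                           paste(bad_sc, collapse = ", ")))
  }
  inputs <- cfg$inputs %||% list()
  for (k in intersect(names(inputs), c("contigs", "meta", "matrix_dir"))) {
    if (!is.null(inputs[[k]]) && !file.exists(inputs[[k]])) {
      errs <- c(errs, paste0("input path not found: ", k, " = ",
                             inputs[[k]]))
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(seed = as.integer(cfg$seed), outdir = cfg$outdir,
                 simulate = sim, inputs = inputs, clonality = clon,
                 interactions = inter, scoring = scoring),
            class = "run_config")
}

# md5 of the normalized config, via a temp JSON file (no extra deps).
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> chain assignment -> clone calling -> clonality ->
#' transitions -> interactions -> scoring in dependency order, writing each
#' stage's outputs as TSV with a provenance header (tool version, config
#' hash, seed) plus a `manifest.json` of output md5 sums. Reruns with the
#' same config are byte-identical. A failing stage aborts with the stage
#' named; outputs of completed stages are retained next to a
#' `FAILED_<stage>` marker.
#'
#' @param config a `run_config` from [validate_config()] (or a path to a
#'   YAML config).
#' @param outdir output directory; defaults to the config's `outdir`.
#' @return invisibly, the manifest as a named list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) || !inherits(config, "run_config")) {
    config <- validate_config(config)
  }
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("an output directory is required",
                            call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(tool = paste0("immunoclone ",
                          as.character(utils::packageVersion("immunoclone"))),
            config_hash = config_hash(config),
            seed = as.character(config$seed))
  stage <- "init"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(outdir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- run_stage("simulate", {
    sim_args <- config$simulate
    if (!is.null(sim_args$clone_size_law)) {
      sim_args$clone_size_law <- as.list(sim_args$clone_size_law)
    }
    cf <- do.call(sim_config, c(sim_args, list(seed = config$seed)))
    rep <- simulate_repertoire(cf)
    expr <- simulate_expression(cf, rep$meta)
    write_tsv_provenance(rep$contigs, file.path(outdir, "contigs.tsv"), prov)
    write_tsv_provenance(rep$meta, file.path(outdir, "meta.tsv"), prov)
    write_mtx_bundle(expr, file.path(outdir, "matrix"))
    list(contigs = rep$contigs, meta = rep$meta, mat = expr, cf = cf)
  })

  chains <- run_stage("assign_chains", {
    ch <- select_chains(sim$contigs)
    write_tsv_provenance(ch, file.path(outdir, "chains.tsv"), prov)
    ch
  })

  clones <- run_stage("call_clones", {
    chm <- merge(chains,
                 sim$meta[, .(cell_id, patient)], by = "cell_id")
    parts <- list()
    for (p in sort(unique(chm$patient))) {
      pc <- chm[patient == p]
      # patient-prefixed clone ids keep per-patient calls collision-free
      parts[[p]] <- rbind(call_bcr_clones(pc), call_tcr_clones(pc))
    }
    cl <- data.table::rbindlist(parts)
    write_tsv_provenance(cl, file.path(outdir, "clones.tsv"), prov)
    cl
  })

  run_stage("clonality", {
    dt <- merge(clones, sim$meta, by = "cell_id")
    res <- list()
    for (s in sort(unique(dt$sample_id))) {
      sdt <- dt[sample_id == s]
      for (sub in sort(unique(sdt$subset))) {
        res[[length(res) + 1L]] <- intra_subset_clonality(
          sdt[subset == sub, clone_id],
          depth = config$clonality$intra_depth,
          reps = config$clonality$reps,
          seed = derive_seed(config$seed, paste0("intra|", s, "|", sub)),
          sample_id = s, subset = sub)
      }
      for (lin in sort(unique(sdt$lineage))) {
        ldt <- sdt[lineage == lin]
        res[[length(res) + 1L]] <- inter_subset_clonality(
          ldt$clone_id, ldt$subset,
          depth = config$clonality$inter_depth,
          reps = config$clonality$reps,
          seed = derive_seed(config$seed, paste0("inter|", s, "|", lin)),
          sample_id = s)
      }
    }
    out <- data.table::rbindlist(res)
    write_tsv_provenance(out, file.path(outdir, "clonality.tsv"), prov)
    out
  })

  run_stage("transitions", {
    dt <- merge(clones, sim$meta, by = "cell_id")
    mats <- list()
    for (s in sort(unique(dt$sample_id))) {
      mats[[s]] <- clonal_overlap(dt[sample_id == s])
    }
    norm <- normalize_overlap(mats)
    long <- data.table::rbindlist(lapply(names(norm), function(s) {
      m <- norm[[s]]
      idx <- which(upper.tri(m), arr.ind = TRUE)
      data.table::data.table(sample_id = s,
                             subset_i = rownames(m)[idx[, 1L]],
                             subset_j = colnames(m)[idx[, 2L]],
                             overlap = m[idx])
    }))
    write_tsv_provenance(long, file.path(outdir, "overlap.tsv"), prov)
    calls <- classify_compartments(clones, sim$meta)
    write_tsv_provenance(calls, file.path(outdir, "compartments.tsv"), prov)
    mig <- migration_linkage(clones, sim$meta)
    midx <- which(!is.na(mig$mean), arr.ind = TRUE)
    mlong <- data.table::data.table(
      blood_phenotype = rownames(mig$mean)[midx[, 1L]],
      tumour_phenotype = colnames(mig$mean)[midx[, 2L]],
      weight = mig$mean[midx])
    write_tsv_provenance(mlong, file.path(outdir, "migration.tsv"), prov)
    NULL
  })

  run_stage("interactions", {
    pairs <- if (!is.null(config$interactions$pairs)) {
      data.table::fread(config$interactions$pairs)
    } else default_lr_pairs()
    tens <- suppressMessages(interaction_strengths(
      sim$mat, sim$meta, pairs,
      min_cells = config$interactions$min_cells,
      include_self = config$interactions$include_self))
    write_tsv_provenance(tens, file.path(outdir, "interactions.tsv"), prov)
    lc <- link_counts(tens)
    write_tsv_provenance(lc, file.path(outdir, "link_counts.tsv"), prov)
    NULL
  })

  run_stage("scoring", {
    gene_set <- config$scoring$gene_set %||%
      c("CD74", "HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1", "HLA-DMA",
        "CD40", "CD80", "CD86")
    n_genes <- nrow(sim$mat)
    sc <- module_score(sim$mat, gene_set,
                       n_bins = min(config$scoring$n_bins %||% 24L,
                                    n_genes),
                       n_ctrl = config$scoring$n_ctrl %||% 100L,
                       seed = derive_seed(config$seed, "module_score"))
    scm <- merge(sc, sim$meta, by = "cell_id")
    pos <- scm[subset == (config$scoring$positive_subset %||% "DC"), score]
    neg <- scm[subset == (config$scoring$negative_subset %||%
                            "CD8_effector"), score]
    thr <- fit_score_threshold(pos, neg)
    papc <- classify_papc(sc, thr, sim$meta)
    res <- merge(papc$cells, sim$meta[, .(cell_id, subset)], by = "cell_id")
    data.table::setorder(res, cell_id)
    write_tsv_provenance(res, file.path(outdir, "papc_scores.tsv"), prov)
    write_tsv_provenance(papc$composition,
                         file.path(outdir, "papc_composition.tsv"), prov)
    writeLines(sprintf("threshold\t%.10g", thr),
               file.path(outdir, "papc_threshold.tsv"))
    NULL
  })

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    tool = unname(prov[["tool"]]),
    config_hash = unname(prov[["config_hash"]]),
    seed = config$seed,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
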