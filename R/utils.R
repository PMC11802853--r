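#' Derive a stage-specific seed from one master seed
#'
#' One global integer seed fans out deterministically to per-stage seeds so
#' that individual pipeline stages can be regenerated in isolation while the
#' whole run stays reproducible.
#'
#' @param seed master integer seed.
#' @param stage character stage name (e.g. `"repertoire"`, `"expression"`).
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # multiplicative hash kept in double precision; modulus is a prime < 2^31
  as.integer((abs(seed) %% 65537 * 30011 + h * 7919 + 17) %% 2147483587)
}

#' Union-find (disjoint set) over n elements
#'
#' Minimal iterative implementation with path halving; used by the clone
#' callers. Exposed for reuse in tests.
#'
#' @param n number of elements.
#' @return an environment with `find(i)`, `union(i, j)` and `components()`
#'   (integer vector mapping element -> component representative).
#' @keywords internal
new_union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  components <- function() vapply(seq_len(n), find, integer(1))
  environment()
}

#' Strip the allele suffix from a V/J gene call
#' @param call gene call, e.g. `"IGHV3-23*01"`.
#' @return gene name without allele, e.g. `"IGHV3-23"`.
#' @export
strip_allele <- function(call) sub("\\*.*$", "", call)

#' Gene family of a V/J call (IMGT convention)
#'
#' The family is the text before the first hyphen of the allele-stripped
#' gene name: `IGHV3-23*01` -> `IGHV3`.
#'
#' @param call gene call(s).
#' @return character vector of family names.
#' @export
gene_family <- function(call) sub("-.*$", "", strip_allele(call))

#' Write a data.table as TSV with a provenance header
#'
#' @param dt data to write.
#' @param path output path.
#' @param provenance optional named character vector recorded as `# key=value`
#'   comment lines above the header.
#' @keywords internal
write_tsv_provenance <- function(dt, path, provenance = NULL) {
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), provenance), path)
    data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a provenance-headed TSV written by this package
#' @param path file path.
#' @return data.table (comment lines skipped).
#' @keywords internal
read_tsv_provenance <- function(path) {
  data.table::fread(path, sep = "\t", skip = "\t", header = TRUE)
}

# Internal: read a TSV tolerating '#' provenance lines at the top.
read_tsv_any <- function(path) {
  first <- readLines(path, n = 50L)
  nskip <- sum(cumprod(startsWith(first, "#")))
  data.table::fread(path, sep = "\t", skip = nskip, header = TRUE)
}

# Internal: validate a probability vector that must sum to 1.
check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s: probabilities must lie in [0, 1]", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("%s: frequencies must sum to 1 (got %.12f)", what, sum(p)),
         call. = FALSE)
  }
  invisible(TRUE)
}
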