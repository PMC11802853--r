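# Pegasos-style subgradient training of a binary linear SVM. The intercept
# is handled as an augmented constant feature (weakly regularised with the
# rest of w), and the iterate is averaged over the final epoch for
# stability. X: n x d matrix, y in {-1, +1}. Returns list(w, b).
train_linear_svm <- function(X, y, lambda = 0.01, epochs = 30L) {
  Xa <- cbind(X, 1)
  n <- nrow(Xa); d <- ncol(Xa)
  w <- numeric(d)
  t <- 0L
  wbar <- numeric(d); navg <- 0L
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1L
      eta <- 1 / (lambda * t)
      margin <- y[i] * sum(w * Xa[i, ])
      w <- (1 - eta * lambda) * w
      if (margin < 1) w <- w + eta * y[i] * Xa[i, ]
      if (e == epochs) {
        wbar <- wbar + w
        navg <- navg + 1L
      }
    }
  }
  wbar <- wbar / navg
  list(w = wbar[-d], b = wbar[d])
}

# One-vs-rest multi-class linear SVM; returns decision scores query x class.
ovr_svm_scores <- function(Xtrain, ytrain, Xquery, lambda, epochs) {
  classes <- sort(unique(ytrain))
  scores <- matrix(NA_real_, nrow(Xquery), length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    fit <- train_linear_svm(Xtrain, ifelse(ytrain == cl, 1, -1),
                            lambda = lambda, epochs = epochs)
    scores[, cl] <- Xquery %*% fit$w + fit$b
  }
  scores
}

#' SVM-based cell-type label transfer with class-balanced subsampling
#'
#' Over `reps` rounds, a multi-class linear SVM (one-vs-rest, trained by
#' subgradient descent) is fitted on a class-balanced subsample of the
#' reference embedding -- `cells_per_class` cells per class, drawn with
#' replacement for classes smaller than that -- and used to predict every
#' query cell. The final label is the majority vote across rounds and the
#' probability is the winning label's vote fraction, so annotation is
#' driven by expression geometry rather than class abundance.
#'
#' @param ref_embedding reference cells x dimensions numeric matrix (e.g. a
#'   batch-corrected reduced space shared with the query).
#' @param ref_labels character/factor label per reference cell.
#' @param query_embedding query cells x dimensions matrix (same
#'   dimensionality as the reference).
#' @param cells_per_class reference cells drawn per class per round
#'   (default 50).
#' @param reps training rounds (default 25).
#' @param seed integer seed.
#' @param lambda SVM regularisation strength (default 0.01).
#' @param epochs training epochs per round (default 30).
#' @return data.table `cell_id`, `label`, `probability`, with the full
#'   vote-fraction matrix in `attr(, "votes")`.
#' @export
svm_label_transfer <- function(ref_embedding, ref_labels, query_embedding,
                               cells_per_class = 50L, reps = 25L,
                               seed = 1L, lambda = 0.01, epochs = 30L) {
  ref <- as.matrix(ref_embedding)
  qry <- as.matrix(query_embedding)
  if (ncol(ref) != ncol(qry)) {
    stop("reference and query embeddings must share dimensionality (",
         ncol(ref), " vs ", ncol(qry), ")", call. = FALSE)
  }
  stopifnot(length(ref_labels) == nrow(ref))
  labels <- as.character(ref_labels)
  classes <- sort(unique(labels))
  # standardise on reference statistics for stable subgradient steps
  mu <- colMeans(ref)
  sdv <- apply(ref, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  refs <- sweep(sweep(ref, 2L, mu), 2L, sdv, "/")
  qrys <- sweep(sweep(qry, 2L, mu), 2L, sdv, "/")
  by_class <- split(seq_len(nrow(refs)), labels)
  votes <- matrix(0L, nrow(qrys), length(classes),
                  dimnames = list(NULL, classes))
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- unlist(lapply(by_class, function(ix) {
        if (length(ix) >= cells_per_class) sample(ix, cells_per_class)
        else sample(ix, cells_per_class, replace = TRUE)
      }))
      sc <- ovr_svm_scores(refs[idx, , drop = FALSE], labels[idx], qrys,
                           lambda = lambda, epochs = epochs)
      pick <- max.col(sc, ties.method = "first")
      votes[cbind(seq_len(nrow(qrys)), pick)] <-
        votes[cbind(seq_len(nrow(qrys)), pick)] + 1L
    }
  })
  frac <- votes / reps
  win <- max.col(frac, ties.method = "first")
  out <- data.table::data.table(
    cell_id = rownames(qry) %||% paste0("query", seq_len(nrow(qry))),
    label = classes[win],
    probability = frac[cbind(seq_len(nrow(qrys)), win)])
  data.table::setattr(out, "votes", frac)
  out[]
}
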