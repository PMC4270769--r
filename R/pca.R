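#' Principal components of a demeaned emotion matrix
#'
#' Decomposes the within-participant-centered trials x items matrix by
#' singular value decomposition, X = U D V'. The loadings V are orthonormal;
#' scores are X V; the explained-variance ratio of component k is
#' d_k^2 / sum(d^2). In food-evoked emotion data the first component
#' typically orders emotions from unpleasant to pleasant (valence) and the
#' second from calm to energetic (arousal).
#'
#' @param X a `centered_emotions` matrix from [demean_within_subject()], or
#'   any numeric matrix with (near) zero column means.
#' @param check_centering tolerance on column means; set `Inf` to disable.
#' @return An `emotion_pca` object: `rotation` (items x components,
#'   orthonormal), `scores` (trials x components), `sdev`,
#'   `explained_variance_ratio`, `orientation` (per-component sign applied
#'   by [orient_signs()], initially all +1), `emotion_names`, `row_keys`.
#' @export
fit_pca <- function(X, check_centering = 1e-8) {
  keys <- attr(X, "row_keys")
  M <- unclass(X)
  attributes(M)[setdiff(names(attributes(M)), c("dim", "dimnames"))] <- NULL
  if (nrow(M) < 2) stop("need at least 2 rows for PCA", call. = FALSE)
  cm <- colMeans(M)
  if (max(abs(cm)) > check_centering) {
    stop("matrix is not column-centered (max |column mean| = ",
         format(max(abs(cm))), "); demean first", call. = FALSE)
  }
  s <- svd(M)
  structure(list(rotation = s$v,
                 scores = M %*% s$v,
                 sdev = s$d / sqrt(max(1, nrow(M) - 1)),
                 explained_variance_ratio = s$d^2 / sum(s$d^2),
                 orientation = rep(1, ncol(s$v)),
                 emotion_names = colnames(M),
                 row_keys = keys),
            class = "emotion_pca")
}

#' @export
print.emotion_pca <- function(x, k = min(5, length(x$sdev)), ...) {
  cat(sprintf("PCA of %d trials x %d emotion items\n",
              nrow(x$scores), nrow(x$rotation)))
  evr <- x$explained_variance_ratio[seq_len(k)]
  cat("Explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * evr), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fix the signs of the principal components
#'
#' A singular value decomposition determines each component only up to sign.
#' To make the valence axis interpretable and its slope in the choice model
#' positive, PC1 is flipped when its scores correlate negatively with
#' liking; every other component is flipped so that its largest-magnitude
#' loading is positive. The applied signs are recorded in `orientation`.
#'
#' @param decomp an `emotion_pca` object.
#' @param liking per-trial liking vector aligned with the score rows.
#' @return The decomposition with deterministically oriented components.
#' @export
orient_signs <- function(decomp, liking) {
  stopifnot(inherits(decomp, "emotion_pca"))
  if (length(liking) != nrow(decomp$scores)) {
    stop("liking length does not match score rows", call. = FALSE)
  }
  if (stats::sd(liking) == 0) stop("liking has zero variance", call. = FALSE)
  k <- ncol(decomp$rotation)
  flip <- rep(1, k)
  r1 <- stats::cor(decomp$scores[, 1], liking)
  if (is.finite(r1) && r1 < 0) flip[1] <- -1
  if (k >= 2) {
    for (j in 2:k) {
      lead <- which.max(abs(decomp$rotation[, j]))
      if (decomp$rotation[lead, j] < 0) flip[j] <- -1
    }
  }
  decomp$rotation <- sweep(decomp$rotation, 2, flip, `*`)
  decomp$scores <- sweep(decomp$scores, 2, flip, `*`)
  decomp$orientation <- decomp$orientation * flip
  decomp
}

#' Project new demeaned rows onto a fitted rotation
#'
#' Applies the rotation learned from the training subjects to rows from a
#' held-out subject. The new rows must already be demeaned with the held-out
#' subject's own per-product means -- the rotation comes from the training
#' data, the centering from the subject.
#'
#' @param decomp an `emotion_pca` object.
#' @param new_rows numeric matrix with one column per emotion item.
#' @param k number of leading components to return (default: all).
#' @return Scores matrix `new_rows %*% rotation[, 1:k]`.
#' @export
project_scores <- function(decomp, new_rows, k = ncol(decomp$rotation)) {
  stopifnot(inherits(decomp, "emotion_pca"))
  if (is.null(dim(new_rows))) new_rows <- matrix(new_rows, nrow = 1)
  new_rows <- as.matrix(new_rows)
  if (ncol(new_rows) != nrow(decomp$rotation)) {
    stop("column count (", ncol(new_rows), ") does not match rotation (",
         nrow(decomp$rotation), " items)", call. = FALSE)
  }
  new_rows %*% decomp$rotation[, seq_len(k), drop = FALSE]
}

#' @rdname project_scores
#' @param object,newdata,... `predict()` method equivalents of
#'   `project_scores(decomp, new_rows, k)`.
#' @export
predict.emotion_pca <- function(object, newdata,
                                k = ncol(object$rotation), ...) {
  project_scores(object, newdata, k = k)
}

#' Stability of component loadings across cross-validation folds
#'
#' In the leave-one-out procedure the rotation is re-learned on every fold,
#' so the loadings of PC1/PC2 vary slightly from fold to fold. This
#' summarizes, per emotion item and component, the mean and standard
#' deviation of the loading over folds; small SDs relative to the mean
#' indicate a stable axis. All folds must be sign-oriented first, otherwise
#' sign flips masquerade as instability.
#'
#' @param fold_decomps list of `emotion_pca` objects, one per fold.
#' @param k number of leading components to summarize.
#' @return data.frame with `emotion`, and `PC<j>_mean` / `PC<j>_sd` columns.
#' @export
loading_stability <- function(fold_decomps, k = 2) {
  if (length(fold_decomps) < 2) stop("need at least 2 folds", call. = FALSE)
  stopifnot(all(vapply(fold_decomps, inherits, logical(1), "emotion_pca")))
  p <- nrow(fold_decomps[[1]]$rotation)
  out <- data.frame(emotion = fold_decomps[[1]]$emotion_names %||%
                      paste0("item", seq_len(p)))
  for (j in seq_len(k)) {
    L <- vapply(fold_decomps, function(d) d$rotation[, j], numeric(p))
    out[[sprintf("PC%d_mean", j)]] <- rowMeans(L)
    out[[sprintf("PC%d_sd", j)]] <- apply(L, 1, stats::sd)
  }
  out
}
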