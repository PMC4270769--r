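#' Remove each participant's mean emotion profile
#'
#' Subtracts, for every emotion item, the participant's own mean over the
#' product set from that participant's scores. This eliminates offset biases
#' between participants in how they use the response scale, so that all
#' remaining variation is within-participant variation across products --
#' the variation that can discriminate the products for that person.
#'
#' @param panel a validated [emotion_panel()].
#' @return A `centered_emotions` object: the trials x items demeaned matrix
#'   with attributes `row_keys` (subject/product data.frame aligned with the
#'   rows) and `subject_means` (subjects x items matrix of the removed
#'   means, kept so new data for a known subject can be centered
#'   identically).
#' @export
demean_within_subject <- function(panel) {
  validate_panel(panel)
  X <- emotion_matrix(panel)
  subj <- panel$subject
  n_alt <- length(alternatives(panel))
  counts <- table(subj)
  if (any(counts != n_alt)) {
    stop("subject(s) without exactly ", n_alt, " rows: ",
         paste(utils::head(names(counts)[counts != n_alt], 5),
               collapse = ", "), call. = FALSE)
  }
  means <- rowsum(X, subj, reorder = FALSE) / n_alt
  centered <- X - means[match(subj, rownames(means)), , drop = FALSE]
  structure(centered,
            row_keys = data.frame(subject = subj, product = panel$product,
                                  stringsAsFactors = FALSE),
            subject_means = means,
            class = c("centered_emotions", class(centered)))
}

#' Per-variable centering and scaling statistics
#'
#' Fits a mean/standard-deviation pair per column (denominator n - 1), so
#' predictors measured in different units (liking on 0--100, component
#' scores in item units) can be brought to a common standard-deviation-1
#' scale and their slope estimates compared. The fitted statistics can be
#' applied to new rows -- in cross-validation they are fit on the training
#' subjects only and applied to the held-out subject.
#'
#' @param x numeric vector or matrix/data.frame of columns to standardize.
#' @return A `scaling_stats` object with `center` and `scale` per column.
#' @export
fit_scaling <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit scaling", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    nm <- colnames(x) %||% as.character(seq_len(ncol(x)))
    stop("zero variance in variable(s): ", paste(nm[zero], collapse = ", "),
         call. = FALSE)
  }
  structure(list(center = ctr, scale = scl), class = "scaling_stats")
}

#' @rdname fit_scaling
#' @param stats a fitted `scaling_stats` object.
#' @return `apply_scaling()` returns `(x - center) / scale`, same shape as
#'   `x`.
#' @export
apply_scaling <- function(x, stats) {
  stopifnot(inherits(stats, "scaling_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$center)) {
    stop("column count does not match fitted scaling", call. = FALSE)
  }
  sweep(sweep(x, 2, stats$center), 2, stats$scale, `/`)
}
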