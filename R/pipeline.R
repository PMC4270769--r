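#' Assemble standardized choice-model predictors from emotion panels
#'
#' Runs the preprocessing chain once on the full sample: demean each
#' panel's emotion scores within participant, decompose by SVD, orient the
#' component signs against liking, and return a long predictor table with
#' one row per subject x product holding liking and the leading component
#' scores of each instrument, each centered and scaled to standard
#' deviation 1 so slope estimates are comparable.
#'
#' @param panels named list of validated [emotion_panel()]s sharing the
#'   same subjects and alternatives (e.g. `list(premo = ..., essense =
#'   ...)`); at least one must carry choice flags (see [merge_choice()]).
#' @param n_components leading components per instrument to expose, named
#'   `<instrument>_pc1 ...`.
#' @param standardize center/scale liking and scores to SD 1 (default).
#' @return data.frame with columns `subject`, `product`, `choice`,
#'   `liking`, and `<name>_pc<j>` per panel and component; the fitted
#'   `emotion_pca` objects are attached as attribute `"pca"` and the
#'   scaling as `"scaling"`.
#' @export
build_predictors <- function(panels, n_components = 2, standardize = TRUE) {
  if (inherits(panels, "emotion_panel")) panels <- list(panels)
  if (is.null(names(panels)) || any(names(panels) == "")) {
    names(panels) <- vapply(panels, function(p) attr(p, "instrument"),
                            character(1))
  }
  base <- panels[[1]]
  validate_panel(base)
  key <- paste(base$subject, base$product, sep = "\r")
  with_choice <- which(vapply(panels, function(p) "choice" %in% names(p),
                              logical(1)))
  if (!length(with_choice)) stop("no panel carries choice flags",
                                 call. = FALSE)
  ch_panel <- panels[[with_choice[1]]]
  out <- data.frame(subject = base$subject, product = base$product,
                    choice = ch_panel$choice[match(key,
                      paste(ch_panel$subject, ch_panel$product, sep = "\r"))],
                    liking = base$liking, stringsAsFactors = FALSE)
  pcas <- list()
  for (nm in names(panels)) {
    p <- panels[[nm]]
    validate_panel(p)
    k2 <- paste(p$subject, p$product, sep = "\r")
    if (!setequal(key, k2)) {
      stop("panel '", nm, "' does not share (subject, product) keys with '",
           names(panels)[1], "'", call. = FALSE)
    }
    pca <- orient_signs(fit_pca(demean_within_subject(p)), p$liking)
    pcas[[nm]] <- pca
    idx <- match(key, k2)
    for (j in seq_len(min(n_components, ncol(pca$rotation)))) {
      out[[sprintf("%s_pc%d", nm, j)]] <- pca$scores[idx, j]
    }
  }
  scl <- NULL
  if (standardize) {
    vars <- setdiff(names(out), c("subject", "product", "choice"))
    scl <- fit_scaling(out[vars])
    out[vars] <- apply_scaling(out[vars], scl)
  }
  structure(out, pca = pcas, scaling = scl)
}

ladder_formulas <- function(instruments) {
  i1 <- instruments[1]; i2 <- instruments[2]
  list(`1` = "choice ~ liking",
       `2` = sprintf("choice ~ %s_pc1", i1),
       `3` = sprintf("choice ~ %s_pc1", i2),
       `4` = sprintf("choice ~ liking + %s_pc1", i1),
       `5` = sprintf("choice ~ liking + %s_pc1", i2),
       `6` = sprintf("choice ~ liking + %s_pc1 + %s_pc2", i1, i1),
       `7` = sprintf("choice ~ liking + %s_pc1 + %s_pc2", i2, i2))
}

#' Fit and compare the seven-model choice ladder
#'
#' Fits the seven conditional logit models built from liking and the first
#' two emotion components of two instruments, and runs the forward
#' comparison sequence: liking-only vs each PC1-only model (replacement,
#' same parameter count, reported descriptively), PC1-only vs PC1+liking
#' (nested), the two combined models against each other (replacement), and
#' each combined model vs its PC2 extension (nested). The selected model is
#' the most complex one on either instrument branch whose nested addition
#' step is significant at `alpha`; replacement comparisons never drive
#' selection, but break the tie between branches by maximized
#' log-likelihood.
#'
#' @param predictors predictor table from [build_predictors()], with
#'   standardized columns `liking`, `<instr>_pc1`, `<instr>_pc2`.
#' @param instruments the two instrument prefixes, in Model-2/Model-3
#'   order; defaults to the order found in the table.
#' @param alpha forward-selection significance threshold.
#' @return A `choice_ladder` object: `fits` (models 1--7), `comparisons`
#'   (data.frame over the pairs 1v2, 1v3, 2v4, 3v5, 4v5, 4v6, 5v7),
#'   `fit_quality` (McFadden adjusted r2 per model), `best_model`.
#' @export
run_ladder <- function(predictors, instruments = NULL, alpha = 0.05) {
  if (is.null(instruments)) {
    instruments <- unique(sub("_pc[0-9]+$", "",
                              grep("_pc1$", names(predictors), value = TRUE)))
  }
  if (length(instruments) != 2) {
    stop("ladder needs exactly two instruments; found: ",
         paste(instruments, collapse = ", "), call. = FALSE)
  }
  forms <- ladder_formulas(instruments)
  fits <- lapply(forms, function(f)
    cond_logit(stats::as.formula(f), predictors))
  pairs <- list(c("1", "2"), c("1", "3"), c("2", "4"), c("3", "5"),
                c("4", "5"), c("4", "6"), c("5", "7"))
  cmps <- lapply(pairs, function(pr) lr_test(fits[[pr[1]]], fits[[pr[2]]]))
  comparisons <- data.frame(
    comparison = vapply(pairs, paste, character(1), collapse = "v"),
    chi2 = vapply(cmps, `[[`, numeric(1), "chi2"),
    df = vapply(cmps, `[[`, numeric(1), "df"),
    p = vapply(cmps, `[[`, numeric(1), "p"),
    nested = vapply(cmps, `[[`, logical(1), "nested"))
  p_of <- function(pair) comparisons$p[comparisons$comparison == pair]
  branch <- function(first, combined, extended, add1, add2) {
    head <- first
    if (p_of(add1) < alpha) head <- combined
    if (head == combined && p_of(add2) < alpha) head <- extended
    head
  }
  h1 <- branch("2", "4", "6", "2v4", "4v6")
  h2 <- branch("3", "5", "7", "3v5", "5v7")
  best <- if (fits[[h1]]$loglik >= fits[[h2]]$loglik) h1 else h2
  structure(list(fits = fits,
                 formulas = unlist(forms),
                 comparisons = comparisons,
                 fit_quality = vapply(fits, mcfadden_adj_r2, numeric(1)),
                 best_model = as.integer(best),
                 instruments = instruments,
                 alpha = alpha),
            class = "choice_ladder")
}

#' @export
print.choice_ladder <- function(x, ...) {
  cat("Conditional logit model ladder\n")
  for (id in names(x$fits)) {
    cat(sprintf("  Model %s: %-40s LL = %8.3f  adj r2 = %.3f\n", id,
                x$formulas[[id]], x$fits[[id]]$loglik, x$fit_quality[[id]]))
  }
  cat("\nComparisons:\n")
  print(transform(x$comparisons, chi2 = round(chi2, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("\nSelected model: %d (alpha = %g)\n", x$best_model, x$alpha))
  invisible(x)
}

#' Forward scan over higher-order principal components
#'
#' Starting from a base model (by default the ladder's selected model),
#' repeatedly adds the remaining components 2..k of one instrument, at each
#' step the component giving the largest likelihood-ratio improvement, and
#' reports every test in the order the components were added.
#'
#' @param predictors predictor table from [build_predictors()] built with
#'   `n_components >= max_components`.
#' @param instrument instrument prefix to scan.
#' @param max_components scan components 2..`max_components`.
#' @param base_formula starting model; default `choice ~ liking +
#'   <instrument>_pc1`.
#' @param alpha significance threshold recorded per step.
#' @return data.frame with one row per added component: `component`,
#'   `chi2`, `df`, `p`, `significant`. Empty for `max_components < 2`.
#' @export
extended_pc_scan <- function(predictors, instrument, max_components,
                             base_formula = NULL, alpha = 0.05) {
  cand <- sprintf("%s_pc%d", instrument,
                  seq(2, length.out = max(0, max_components - 1)))
  if (length(bad <- setdiff(cand, names(predictors)))) {
    stop("component column(s) not available: ", paste(bad, collapse = ", "),
         " (rebuild predictors with more components)", call. = FALSE)
  }
  if (is.null(base_formula)) {
    base_formula <- stats::as.formula(sprintf("choice ~ liking + %s_pc1",
                                              instrument))
  }
  fit <- cond_logit(base_formula, predictors)
  terms_now <- attr(stats::terms(base_formula), "term.labels")
  out <- data.frame(component = character(0), chi2 = numeric(0),
                    df = numeric(0), p = numeric(0),
                    significant = logical(0))
  while (length(cand)) {
    trial <- lapply(cand, function(v)
      cond_logit(stats::reformulate(c(terms_now, v), response = "choice"),
                 predictors))
    ll <- vapply(trial, `[[`, numeric(1), "loglik")
    pick <- which.max(ll)
    cmp <- lr_test(fit, trial[[pick]])
    out <- rbind(out, data.frame(component = cand[pick], chi2 = cmp$chi2,
                                 df = cmp$df, p = cmp$p,
                                 significant = cmp$p < alpha))
    terms_now <- c(terms_now, cand[pick])
    fit <- trial[[pick]]
    cand <- cand[-pick]
  }
  out
}

#' Pearson correlations among model predictors
#'
#' @param predictors predictor table (or any data.frame); non-numeric and
#'   id columns are dropped.
#' @param vars optional explicit column selection.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
predictor_correlations <- function(predictors, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(names(predictors)[vapply(predictors, is.numeric,
                                             logical(1))],
                    c("choice"))
  }
  X <- as.matrix(predictors[vars])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero variance in: ", paste(vars[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  stats::cor(X)
}
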