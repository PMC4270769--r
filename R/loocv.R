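#' Leave-one-out cross-validated choice prediction
#'
#' For each subject in turn: the emotion matrices are demeaned within
#' participant (each subject with their own product means, available before
#' any choice is made); the principal-component rotation is learned on the
#' remaining n-1 subjects' rows only, sign-oriented against the training
#' liking, and applied to the held-out subject's demeaned rows; the
#' predictor scaling is fit on the training rows (or once globally, by
#' option) and applied to the held-out subject; the conditional logit is
#' fit on the training subjects; and the held-out subject's seven choice
#' probabilities are predicted. The held-out subject's data never enter
#' that fold's rotation, scaling or fit. Probabilities are converted to
#' ranks 1 (most likely chosen) through J, ties broken by alternative
#' order.
#'
#' @param panels named list of [emotion_panel()]s as in
#'   [build_predictors()]; at least one with choice flags.
#' @param predictors character vector of predictor names drawn from
#'   `"liking"` and `"<instrument>_pc<j>"`.
#' @param scaling `"fold"` (fit standardization on the n-1 training
#'   subjects, the honest default) or `"global"` (fit once on all rows).
#' @param keep_rotations keep each fold's oriented `emotion_pca` objects
#'   for [loading_stability()] (per instrument).
#' @return A `loocv_result`: `predictions` data.frame (one row per subject:
#'   `subject`, `chosen`, `chosen_rank`, `prob_<alt>` and `rank_<alt>`
#'   columns), `probs` and `ranks` matrices, `fold_pcas`, `failures`,
#'   `alternatives`, `predictors`.
#' @export
loocv_predict <- function(panels, predictors = NULL,
                          scaling = c("fold", "global"),
                          keep_rotations = TRUE) {
  scaling <- match.arg(scaling)
  if (inherits(panels, "emotion_panel")) panels <- list(panels)
  if (is.null(names(panels)) || any(names(panels) == "")) {
    names(panels) <- vapply(panels, function(p) attr(p, "instrument"),
                            character(1))
  }
  if (is.null(predictors)) {
    predictors <- c("liking", paste0(names(panels)[1], "_pc1"))
  }
  base <- panels[[1]]
  validate_panel(base)
  alts <- alternatives(base)
  J <- length(alts)
  subj_ids <- subjects(base)
  n <- length(subj_ids)

  # which components of which instrument the spec needs
  pc_vars <- grep("_pc[0-9]+$", predictors, value = TRUE)
  instr_of <- sub("_pc[0-9]+$", "", pc_vars)
  comp_of <- as.integer(sub("^.*_pc", "", pc_vars))
  bad <- c(setdiff(setdiff(predictors, pc_vars), "liking"),
           setdiff(instr_of, names(panels)))
  if (length(bad)) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  need <- unique(instr_of)

  with_choice <- which(vapply(panels, function(p) "choice" %in% names(p),
                              logical(1)))
  if (!length(with_choice)) stop("no panel carries choice flags",
                                 call. = FALSE)
  ch_panel <- panels[[with_choice[1]]]

  key <- paste(base$subject, base$product, sep = "\r")
  centered <- list()
  for (nm in need) {
    p <- panels[[nm]]
    validate_panel(p)
    cm <- demean_within_subject(p)
    k2 <- paste(attr(cm, "row_keys")$subject, attr(cm, "row_keys")$product,
                sep = "\r")
    if (!setequal(key, k2)) {
      stop("panel '", nm, "' does not share keys with the first panel",
           call. = FALSE)
    }
    centered[[nm]] <- unclass(cm)[match(key, k2), , drop = FALSE]
  }
  liking <- base$liking
  choice <- ch_panel$choice[match(key, paste(ch_panel$subject,
                                             ch_panel$product, sep = "\r"))]
  subj <- base$subject
  prod <- base$product

  probs <- matrix(NA_real_, n, J, dimnames = list(subj_ids, alts))
  fold_pcas <- if (keep_rotations) stats::setNames(
    replicate(length(need), vector("list", n), simplify = FALSE), need)
  failures <- character(0)

  global_stats <- NULL
  if (scaling == "global") {
    full <- data.frame(liking = liking)
    for (i in seq_along(pc_vars)) {
      pca_full <- orient_signs(fit_pca(centered[[instr_of[i]]]), liking)
      full[[pc_vars[i]]] <- pca_full$scores[, comp_of[i]]
    }
    global_stats <- fit_scaling(full[predictors])
  }

  for (s in seq_len(n)) {
    sid <- subj_ids[s]
    is_test <- subj == sid
    res <- tryCatch({
      pred_tab <- data.frame(subject = subj, product = prod,
                             choice = choice, liking = liking,
                             stringsAsFactors = FALSE)
      for (nm in need) {
        pca <- fit_pca(centered[[nm]][!is_test, , drop = FALSE])
        pca <- orient_signs(pca, liking[!is_test])
        if (keep_rotations) fold_pcas[[nm]][[s]] <- pca
        sc <- matrix(NA_real_, length(subj), ncol(pca$rotation))
        sc[!is_test, ] <- pca$scores
        sc[is_test, ] <- project_scores(pca,
                                        centered[[nm]][is_test, ,
                                                       drop = FALSE])
        for (i in which(instr_of == nm)) {
          pred_tab[[pc_vars[i]]] <- sc[, comp_of[i]]
        }
      }
      stats_fold <- if (scaling == "fold") {
        fit_scaling(pred_tab[!is_test, predictors, drop = FALSE])
      } else global_stats
      pred_tab[predictors] <- apply_scaling(pred_tab[predictors],
                                            stats_fold)
      train <- pred_tab[!is_test, , drop = FALSE]
      test <- pred_tab[is_test, , drop = FALSE]
      fit <- cond_logit(stats::reformulate(predictors,
                                           response = "choice"),
                        train, alternatives = alts)
      test$choice <- NULL
      drop(predict(fit, newdata = test))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(sid, ": ", conditionMessage(res)))
    } else {
      probs[s, ] <- res
    }
  }

  ok <- !is.na(probs[, 1])
  ranks <- t(apply(probs[ok, , drop = FALSE], 1, probs_to_ranks))
  colnames(ranks) <- alts
  chosen_alt <- prod[choice == 1][match(subj_ids, subj[choice == 1])]
  chosen_rank <- rep(NA_integer_, n)
  chosen_rank[ok] <- ranks[cbind(seq_len(sum(ok)),
                                 match(chosen_alt[ok], alts))]
  predictions <- data.frame(subject = subj_ids, chosen = chosen_alt,
                            chosen_rank = chosen_rank,
                            stringsAsFactors = FALSE)
  pm <- as.data.frame(probs); names(pm) <- paste0("prob_", alts)
  rm_full <- matrix(NA_integer_, n, J, dimnames = list(subj_ids, alts))
  rm_full[ok, ] <- ranks
  rmd <- as.data.frame(rm_full); names(rmd) <- paste0("rank_", alts)
  predictions <- cbind(predictions, pm, rmd)
  rownames(predictions) <- NULL

  structure(list(predictions = predictions, probs = probs, ranks = rm_full,
                 fold_pcas = fold_pcas, failures = failures,
                 alternatives = alts, predictors = predictors,
                 scaling = scaling),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("Leave-one-out predictions for %d subjects (%s scaling)\n",
              nrow(x$predictions), x$scaling))
  cat("Predictors:", paste(x$predictors, collapse = " + "), "\n")
  if (length(x$failures)) {
    cat(length(x$failures), "fold failure(s)\n")
  }
  d <- rank_distribution(x)
  cat(sprintf("Chosen product at rank 1: %.1f%%, rank 2: %.1f%% (chance %.1f%%)\n",
              d$percent[1], d$percent[2], d$chance_level[1]))
  invisible(x)
}

#' Rank alternatives by predicted choice probability
#'
#' Rank 1 is the alternative with the highest predicted probability, rank J
#' the lowest; ties are broken by alternative order (earlier alternative
#' gets the better rank).
#'
#' @param probs probability vector over the alternatives.
#' @return Integer vector: the rank of each alternative, a permutation of
#'   `1:length(probs)`.
#' @export
probs_to_ranks <- function(probs) {
  if (any(!is.finite(probs))) stop("non-finite probabilities", call. = FALSE)
  ord <- order(-probs, seq_along(probs))
  ranks <- integer(length(probs))
  ranks[ord] <- seq_along(probs)
  ranks
}

#' Distribution of the chosen product's predicted rank
#'
#' Summarizes cross-validated predictions as the percentage of subjects
#' whose actually chosen product received each rank; perfect prediction
#' puts 100% at rank 1, chance puts 1/J everywhere.
#'
#' @param predictions a `loocv_result` or a vector of chosen ranks.
#' @param n_alternatives needed only when a bare rank vector is given.
#' @return data.frame with `rank`, `count`, `percent`, plus attribute-free
#'   column `chance_level` repeated for convenience.
#' @export
rank_distribution <- function(predictions, n_alternatives = NULL) {
  if (inherits(predictions, "loocv_result")) {
    ranks <- predictions$predictions$chosen_rank
    n_alternatives <- length(predictions$alternatives)
  } else {
    ranks <- predictions
    if (is.null(n_alternatives)) n_alternatives <- max(ranks)
  }
  ranks <- ranks[!is.na(ranks)]
  if (!length(ranks)) stop("no predictions", call. = FALSE)
  counts <- tabulate(ranks, nbins = n_alternatives)
  data.frame(rank = seq_len(n_alternatives), count = counts,
             percent = 100 * counts / sum(counts),
             chance_level = 100 / n_alternatives)
}
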