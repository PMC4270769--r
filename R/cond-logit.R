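#' Build a choice design from long-format data
#'
#' A choice design holds one chooser x alternative row block per chooser:
#' the alternative-varying covariates x_ij (liking, component scores, ...)
#' and, when fitting, a one-hot chosen indicator with exactly one chosen
#' alternative per chooser. Rows are ordered chooser-major with
#' alternatives in the fixed `alternatives` order; the first alternative is
#' the reference for the alternative-specific constants.
#'
#' @param data long data.frame, one row per chooser x alternative.
#' @param covariates character vector of covariate column names.
#' @param chooser,alternative,chosen column names; `chosen` may be `NULL`
#'   for prediction-only designs.
#' @param alternatives ordered alternative set; default sorted unique.
#' @return A `choice_design` object.
#' @export
choice_design <- function(data, covariates, chooser = "subject",
                          alternative = "product", chosen = "choice",
                          alternatives = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(chooser, alternative, covariates,
            if (!is.null(chosen) && chosen %in% names(data)) chosen)
  if (length(bad <- setdiff(c(chooser, alternative, covariates),
                            names(data)))) {
    stop("column(s) not in data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(data[[chooser]])
  alt <- as.character(data[[alternative]])
  if (is.null(alternatives)) alternatives <- sort(unique(alt))
  J <- length(alternatives)
  ord <- order(match(ids, unique(ids)), match(alt, alternatives))
  data <- data[ord, , drop = FALSE]
  ids <- ids[ord]; alt <- alt[ord]
  choosers <- unique(ids)
  n <- length(choosers)
  if (nrow(data) != n * J ||
      !all(alt == rep(alternatives, times = n)) ||
      !all(ids == rep(choosers, each = J))) {
    stop("design is not a complete chooser x alternative block", call. = FALSE)
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) {
    stop("covariates must be complete and numeric", call. = FALSE)
  }
  chosen_idx <- NULL
  if (!is.null(chosen) && chosen %in% names(data)) {
    y <- data[[chosen]]
    per <- rowsum(y, rep(seq_len(n), each = J))
    if (!all(y %in% c(0, 1)) || any(per != 1)) {
      stop("each chooser must have exactly one chosen alternative",
           call. = FALSE)
    }
    chosen_idx <- ((which(y == 1) - 1L) %% J) + 1L
  }
  structure(list(choosers = choosers, alternatives = alternatives,
                 covariates = covariates, X = X, chosen = chosen_idx,
                 n = n, J = J),
            class = "choice_design")
}

# full model matrix: covariates then ASC dummies for all non-reference
# alternatives, rows alt-fastest within chooser
design_Z <- function(design, include_asc = TRUE, reference = 1L) {
  J <- design$J
  Z <- design$X
  if (include_asc && J > 1) {
    D <- diag(J)[rep(seq_len(J), times = design$n), -reference, drop = FALSE]
    colnames(D) <- paste0("asc:", design$alternatives[-reference])
    Z <- cbind(Z, D)
  }
  Z
}

#' Conditional logit log-likelihood with analytic derivatives
#'
#' Utility of alternative j for chooser i is V_ij = alpha_j + x_ij' beta,
#' with the reference alternative's constant fixed at zero; the probability
#' of the chosen alternative is the softmax over the chooser's block, and
#' the log-likelihood sums the log chosen-probabilities. The log-sum-exp is
#' computed with the row maximum subtracted, so large utilities do not
#' overflow.
#'
#' @param params parameter vector: covariate slopes followed by the
#'   alternative-specific constants for the non-reference alternatives (the
#'   constants are absent when `include_asc = FALSE`).
#' @param design a [choice_design()] with chosen indicators.
#' @param include_asc include alternative-specific constants.
#' @param reference index of the reference alternative (constant = 0).
#' @param deriv 0, 1 or 2: attach `"gradient"` (and `"hessian"`) attributes.
#' @return Scalar log-likelihood, with derivative attributes as requested.
#' @export
clogit_loglik <- function(params, design, include_asc = TRUE,
                          reference = 1L, deriv = 2) {
  stopifnot(inherits(design, "choice_design"))
  if (is.null(design$chosen)) stop("design has no chosen indicators",
                                   call. = FALSE)
  Z <- design_Z(design, include_asc, reference)
  if (length(params) != ncol(Z)) {
    stop("params has length ", length(params), ", expected ", ncol(Z),
         call. = FALSE)
  }
  n <- design$n; J <- design$J
  V <- matrix(Z %*% params, nrow = n, ncol = J, byrow = TRUE)
  M <- apply(V, 1, max)
  E <- exp(V - M)
  denom <- rowSums(E)
  P <- E / denom
  picked <- cbind(seq_len(n), design$chosen)
  ll <- sum(V[picked] - M - log(denom))
  if (deriv >= 1) {
    y <- numeric(n * J)
    y[(seq_len(n) - 1L) * J + design$chosen] <- 1
    p_vec <- as.vector(t(P))
    g <- drop(crossprod(Z, y - p_vec))
    attr(ll, "gradient") <- g
    if (deriv >= 2) {
      PZ <- Z * p_vec
      A <- rowsum(PZ, rep(seq_len(n), each = J), reorder = FALSE)
      H <- -(crossprod(Z, PZ) - crossprod(A))
      attr(ll, "hessian") <- H
    }
  }
  ll
}

#' Fit a conditional (multinomial) logit choice model
#'
#' Estimates a McFadden conditional logit by Newton-Raphson on the concave
#' log-likelihood, from a cold start at zero, using the analytic gradient
#' and Hessian; convergence is declared when the gradient's maximum absolute
#' entry falls below `tol`. The covariance of the estimates is the inverse
#' observed information (negative Hessian) at the optimum.
#'
#' The formula interface names the chosen indicator on the left and the
#' alternative-varying covariates on the right, e.g.
#' `choice ~ liking + premo_pc1`; `data` is long format with one row per
#' chooser x alternative. Covariates are used as supplied -- standardize
#' them first (see [fit_scaling()]) if slopes are to be compared.
#'
#' @param formula chosen-indicator ~ covariates (use `~ 1` or
#'   `include_asc`-only designs for a constants-only model).
#' @param data long data.frame.
#' @param chooser,alternative id column names.
#' @param alternatives ordered alternative set; first not-`reference`
#'   handling see `reference`.
#' @param reference alternative id whose constant is fixed at 0; default
#'   the first of the alternative set.
#' @param include_asc include alternative-specific constants (default TRUE).
#' @param tol gradient convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @param start optional warm-start parameter vector (default zeros).
#' @return An object of class `cond_logit` with components `coefficients`
#'   (slopes then `asc:<alt>` constants), `beta`, `asc`, `loglik`, `vcov`,
#'   `n_params`, `converged`, `iterations`, `design`, `reference`.
#' @examples
#' d <- expand.grid(product = c("A", "B", "C"), subject = 1:50)
#' set.seed(1)
#' d$x <- rnorm(nrow(d))
#' u <- matrix(d$x, ncol = 3, byrow = TRUE)
#' pick <- apply(exp(u) / rowSums(exp(u)), 1, function(p) sample(3, 1, prob = p))
#' d$choice <- as.integer(rep(1:3, 50) == rep(pick, each = 3))
#' fit <- cond_logit(choice ~ x, d)
#' coef(fit)
#' @export
cond_logit <- function(formula, data, chooser = "subject",
                       alternative = "product", alternatives = NULL,
                       reference = NULL, include_asc = TRUE,
                       tol = 1e-8, max_iter = 100L, start = NULL) {
  vars <- all.vars(formula)
  chosen_col <- if (length(formula) == 3) all.vars(formula[[2]]) else
    stop("formula needs a left-hand side naming the chosen indicator",
         call. = FALSE)
  covariates <- setdiff(all.vars(formula[[3]]), ".")
  design <- choice_design(data, covariates, chooser = chooser,
                          alternative = alternative, chosen = chosen_col,
                          alternatives = alternatives)
  cond_logit_fit(design, reference = reference, include_asc = include_asc,
                 tol = tol, max_iter = max_iter, start = start,
                 call = match.call(), formula = formula)
}

#' @rdname cond_logit
#' @param design a [choice_design()] with chosen indicators (low-level
#'   interface used internally and by the cross-validation loop).
#' @param call,formula stored for printing.
#' @export
cond_logit_fit <- function(design, reference = NULL, include_asc = TRUE,
                           tol = 1e-8, max_iter = 100L, start = NULL,
                           call = NULL, formula = NULL) {
  stopifnot(inherits(design, "choice_design"))
  ref_idx <- if (is.null(reference)) 1L else {
    i <- match(as.character(reference), design$alternatives)
    if (is.na(i)) stop("reference alternative not in alternative set",
                       call. = FALSE)
    i
  }
  # covariates constant within every chooser block (e.g. identically 0)
  # carry no choice information: their slope is unidentified and is pinned
  # at 0 rather than estimated
  pinned <- vapply(seq_along(design$covariates), function(k) {
    M <- matrix(design$X[, k], nrow = design$J)
    all(M == rep(M[1, ], each = design$J))
  }, logical(1))
  fit_design <- design
  if (any(pinned)) {
    fit_design$X <- design$X[, !pinned, drop = FALSE]
    fit_design$covariates <- design$covariates[!pinned]
  }
  Z <- design_Z(fit_design, include_asc, ref_idx)
  K <- ncol(Z)
  theta <- if (is.null(start)) numeric(K) else {
    stopifnot(length(start) == K); as.numeric(start)
  }
  ll <- clogit_loglik(theta, fit_design, include_asc, ref_idx, deriv = 2)
  converged <- FALSE
  iter <- 0L
  if (K == 0L) converged <- TRUE
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    g <- attr(ll, "gradient")
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- attr(ll, "hessian")
    step <- tryCatch(solve(-H, g), error = function(e)
      stop("singular Hessian at iteration ", iter,
           ": predictors may be collinear", call. = FALSE))
    # concave LL: step-halve on the rare non-improving full step
    lam <- 1
    repeat {
      cand <- theta + lam * step
      ll_new <- clogit_loglik(cand, fit_design, include_asc, ref_idx, deriv = 2)
      if (as.numeric(ll_new) >= as.numeric(ll) - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- cand
    improving <- as.numeric(ll_new) > as.numeric(ll) + 1e-10
    ll <- ll_new
    if (sqrt(sum(theta^2)) > 50 && improving) {
      stop("apparent separation: parameter norm diverging while the ",
           "log-likelihood keeps improving", call. = FALSE)
    }
  }
  g <- attr(ll, "gradient")
  if (!converged && length(g) && max(abs(g)) < tol) converged <- TRUE
  if (!converged) {
    stop("Newton-Raphson did not converge in ", max_iter,
         " iterations (max |gradient| = ", format(max(abs(g))), ")",
         call. = FALSE)
  }
  H <- attr(ll, "hessian")
  vc <- tryCatch(solve(-H), error = function(e)
    stop("information matrix singular at the optimum; predictors may be ",
         "collinear", call. = FALSE))
  names(theta) <- colnames(Z)
  dimnames(vc) <- list(colnames(Z), colnames(Z))
  if (any(pinned)) {
    # re-insert pinned covariates with slope 0 and zero variance
    n_est_cov <- sum(!pinned)
    asc_names <- if (n_est_cov) names(theta)[-seq_len(n_est_cov)] else
      names(theta)
    full_names <- c(design$covariates, asc_names)
    theta_full <- stats::setNames(numeric(length(full_names)), full_names)
    theta_full[names(theta)] <- theta
    vc_full <- matrix(0, length(full_names), length(full_names),
                      dimnames = list(full_names, full_names))
    vc_full[names(theta), names(theta)] <- vc
    theta <- theta_full
    vc <- vc_full
  }
  n_cov <- length(design$covariates)
  structure(list(coefficients = theta,
                 beta = theta[seq_len(n_cov)],
                 asc = if (include_asc) theta[-seq_len(n_cov)] else NULL,
                 loglik = as.numeric(ll),
                 vcov = vc,
                 n_params = K,
                 converged = converged,
                 iterations = iter,
                 design = design,
                 include_asc = include_asc,
                 reference = design$alternatives[ref_idx],
                 call = call, formula = formula),
            class = "cond_logit")
}

#' @export
print.cond_logit <- function(x, ...) {
  cat("Conditional logit choice model\n")
  if (!is.null(x$formula)) cat("  ", deparse(x$formula), "\n")
  cat(sprintf("  %d choosers, %d alternatives (reference: %s)\n",
              x$design$n, x$design$J, x$reference))
  cat(sprintf("  log-likelihood %.4f, %d parameters, %d Newton iterations\n",
              x$loglik, x$n_params, x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.cond_logit <- function(object, ...) object$coefficients

#' @export
vcov.cond_logit <- function(object, ...) object$vcov

#' @export
logLik.cond_logit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$design$n,
            class = "logLik")
}

#' @export
nobs.cond_logit <- function(object, ...) object$design$n

#' @export
summary.cond_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  null <- null_fit(object)
  out <- list(coefficients = tab, loglik = object$loglik,
              loglik_null = null$loglik,
              mcfadden_r2 = 1 - object$loglik / null$loglik,
              mcfadden_adj_r2 = mcfadden_adj_r2(object, null),
              n = object$design$n, iterations = object$iterations,
              formula = object$formula)
  class(out) <- "summary.cond_logit"
  out
}

#' @export
print.summary.cond_logit <- function(x, ...) {
  cat("Conditional logit choice model\n")
  if (!is.null(x$formula)) cat("  ", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlog-likelihood: %.4f (constants-only: %.4f)\n",
              x$loglik, x$loglik_null))
  cat(sprintf("McFadden r2: %.4f   adjusted: %.4f   n = %d\n",
              x$mcfadden_r2, x$mcfadden_adj_r2, x$n))
  invisible(x)
}

#' Predicted choice probabilities
#'
#' @param object a fitted [cond_logit()] model.
#' @param newdata optional long data.frame or [choice_design()]; default
#'   the training design. Covariates must be on the training scale.
#' @param ... unused.
#' @return Choosers x alternatives matrix of probabilities; rows sum to 1.
#' @export
predict.cond_logit <- function(object, newdata = NULL, ...) {
  design <- object$design
  if (!is.null(newdata)) {
    design <- if (inherits(newdata, "choice_design")) newdata else
      choice_design(newdata, object$design$covariates,
                    chosen = NULL, alternatives = object$design$alternatives)
    if (!identical(design$alternatives, object$design$alternatives) ||
        !identical(design$covariates, object$design$covariates)) {
      stop("newdata alternatives/covariates do not match the fit",
           call. = FALSE)
    }
  }
  ref_idx <- match(object$reference, design$alternatives)
  Z <- design_Z(design, object$include_asc, ref_idx)
  V <- matrix(Z %*% object$coefficients, nrow = design$n, ncol = design$J,
              byrow = TRUE)
  E <- exp(V - apply(V, 1, max))
  P <- E / rowSums(E)
  dimnames(P) <- list(design$choosers, design$alternatives)
  P
}

#' @export
residuals.cond_logit <- function(object, ...) {
  P <- predict(object)
  Y <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  Y[cbind(seq_len(nrow(P)), object$design$chosen)] <- 1
  Y - P
}

#' @export
#' @importFrom stats simulate
simulate.cond_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- predict(object)
  out <- replicate(nsim, apply(P, 1, function(p)
    sample(object$design$alternatives, 1, prob = p)))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$design$choosers
  out
}

# constants-only fit on the same choosers (the null for McFadden's r2)
null_fit <- function(fit) {
  d <- fit$design
  d$X <- matrix(numeric(0), nrow = d$n * d$J, ncol = 0)
  d$covariates <- character(0)
  cond_logit_fit(d, reference = fit$reference,
                 include_asc = fit$include_asc)
}

#' Likelihood-ratio comparison of two conditional logit fits
#'
#' For nested fits on the same choosers, twice the log-likelihood gain is
#' chi-square distributed with degrees of freedom equal to the difference in
#' parameter count. Comparisons between models with the same parameter
#' count ("replacement" of one predictor by another) are not nested: the
#' statistic is still reported, but flagged and given no p-value unless a
#' df is forced explicitly.
#'
#' @param fit_restricted,fit_full fits on identical choosers, restricted
#'   first.
#' @param force_df optionally treat a non-nested (df = 0) comparison as
#'   chi-square with this df (compatibility with analyses that assign
#'   p-values to replacement comparisons).
#' @return A `model_comparison`: `chi2`, `df`, `p`, `nested`.
#' @export
lr_test <- function(fit_restricted, fit_full, force_df = NULL) {
  stopifnot(inherits(fit_restricted, "cond_logit"),
            inherits(fit_full, "cond_logit"))
  if (!identical(fit_restricted$design$choosers, fit_full$design$choosers)) {
    stop("fits are not on identical choosers", call. = FALSE)
  }
  chi2 <- 2 * (fit_full$loglik - fit_restricted$loglik)
  df <- fit_full$n_params - fit_restricted$n_params
  nested <- df > 0
  p <- if (nested) stats::pchisq(chi2, df, lower.tail = FALSE)
  else if (!is.null(force_df)) stats::pchisq(abs(chi2), force_df,
                                             lower.tail = FALSE)
  else NA_real_
  structure(list(chi2 = chi2, df = df, p = p, nested = nested),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  if (!is.null(x$removed)) {
    cat(sprintf("Hausman-McFadden IIA test (removed '%s', %d chooser(s) dropped):\n",
                x$removed, x$n_dropped))
    cat(sprintf("  q = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  } else {
    cat(sprintf("LR comparison: chi2 = %.4f, df = %d%s%s\n", x$chi2, x$df,
                if (is.na(x$p)) "" else sprintf(", p = %.4g", x$p),
                if (x$nested) "" else " (not nested)"))
  }
  invisible(x)
}

#' McFadden's adjusted pseudo r-squared
#'
#' `1 - (LL - K) / LL_0`, where `LL_0` is the log-likelihood of the null
#' model and `K` penalizes the estimated parameters. The default null is
#' the constants-only model on the same choosers and `K` counts every
#' estimated parameter; conventions differ across software, so `penalty`
#' can instead count slopes only, and `null` can be the equal-shares
#' (zero-parameter) model with `LL_0 = n log(1/J)`. Values of 0.2--0.4
#' indicate an excellent fit for discrete choice models.
#'
#' @param fit a [cond_logit()] fit.
#' @param null the constants-only fit on the same choosers (computed if
#'   `NULL`), or the string `"equal_shares"`.
#' @param penalty `"all"` (every estimated parameter) or `"slopes"`.
#' @param adjusted set `FALSE` for the unadjusted `1 - LL/LL_0`.
#' @return Scalar pseudo r-squared.
#' @export
mcfadden_adj_r2 <- function(fit, null = NULL, penalty = c("all", "slopes"),
                            adjusted = TRUE) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(fit, "cond_logit"))
  ll0 <- if (identical(null, "equal_shares")) {
    fit$design$n * log(1 / fit$design$J)
  } else {
    if (is.null(null)) null <- null_fit(fit)
    stopifnot(inherits(null, "cond_logit"))
    null$loglik
  }
  if (ll0 == 0) stop("null log-likelihood is zero", call. = FALSE)
  K <- if (!adjusted) 0
  else if (penalty == "all") fit$n_params
  else length(fit$beta)
  1 - (fit$loglik - K) / ll0
}

#' Hausman-McFadden test of independence of irrelevant alternatives
#'
#' Under IIA, removing one choice alternative (and the choosers who chose
#' it) should leave the remaining parameter estimates unchanged up to
#' sampling noise. The statistic is
#' `q = d' (V_r - V_f)^{-1} d` with `d` the difference between the
#' restricted and full estimates of the parameters common to both fits;
#' under the null q is chi-square with df = number of common parameters.
#' When the variance difference is not positive definite the Moore-Penrose
#' pseudo-inverse is used, with a warning.
#'
#' The reference alternative for both fits is the first alternative of the
#' set that is not the removed one, so the constants stay comparable.
#'
#' @param formula,data,chooser,alternative,alternatives as in
#'   [cond_logit()].
#' @param removed alternative id(s) to remove; default all alternatives in
#'   turn.
#' @return For a single removal, a `model_comparison` with elements
#'   `removed`, `chi2` (= q), `df`, `p`, `n_dropped` (choosers removed);
#'   for several, a data.frame with one row per removal.
#' @export
hausman_mcfadden <- function(formula, data, removed = NULL,
                             chooser = "subject", alternative = "product",
                             alternatives = NULL) {
  chosen_col <- all.vars(formula[[2]])
  covariates <- setdiff(all.vars(formula[[3]]), ".")
  design <- choice_design(data, covariates, chooser = chooser,
                          alternative = alternative, chosen = chosen_col,
                          alternatives = alternatives)
  alts <- design$alternatives
  if (is.null(removed)) removed <- alts
  if (length(removed) > 1) {
    rows <- lapply(removed, function(r)
      hausman_mcfadden(formula, data, removed = r, chooser = chooser,
                       alternative = alternative,
                       alternatives = alternatives))
    return(data.frame(removed = removed,
                      chi2 = vapply(rows, `[[`, numeric(1), "chi2"),
                      df = vapply(rows, `[[`, numeric(1), "df"),
                      p = vapply(rows, `[[`, numeric(1), "p"),
                      n_dropped = vapply(rows, `[[`, numeric(1),
                                         "n_dropped")))
  }
  removed <- as.character(removed)
  if (!removed %in% alts) stop("removed alternative not in set",
                               call. = FALSE)
  ref <- setdiff(alts, removed)[1]
  full <- cond_logit(formula, data, chooser = chooser,
                     alternative = alternative, alternatives = alternatives,
                     reference = ref)
  keep_alt <- data[[alternative]] != removed
  chose_removed <- unique(data[[chooser]][data[[alternative]] == removed &
                                            data[[chosen_col]] == 1])
  sub <- data[keep_alt & !(data[[chooser]] %in% chose_removed), ,
              drop = FALSE]
  n_kept <- length(unique(sub[[chooser]]))
  if (n_kept == 0) stop("all choosers chose the removed alternative",
                        call. = FALSE)
  if (n_kept < length(covariates) + length(alts) - 2 + 2) {
    stop("too few remaining choosers after removing '", removed, "'",
         call. = FALSE)
  }
  restricted <- cond_logit(formula, sub, chooser = chooser,
                           alternative = alternative,
                           alternatives = setdiff(alts, removed),
                           reference = ref)
  common <- intersect(names(restricted$coefficients),
                      names(full$coefficients))
  d <- restricted$coefficients[common] - full$coefficients[common]
  dV <- restricted$vcov[common, common] - full$vcov[common, common]
  ev <- eigen(dV, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    warning("V_restricted - V_full is not positive definite; ",
            "using the Moore-Penrose pseudo-inverse")
    q <- drop(t(d) %*% MASS::ginv(dV) %*% d)
  } else {
    q <- drop(t(d) %*% solve(dV, d))
  }
  df <- length(common)
  structure(list(removed = removed, chi2 = q, df = df,
                 p = stats::pchisq(q, df, lower.tail = FALSE),
                 n_dropped = full$design$n - n_kept, nested = FALSE),
            class = "model_comparison")
}
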