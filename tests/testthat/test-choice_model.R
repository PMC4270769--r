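test_that("log-likelihood at zero parameters is n log(1/J)", {
  d <- simulate_design_data(n = 30, J = 7,
                            beta = c(x1 = 0.5, x2 = -0.2), seed = 1)
  design <- choice_design(d, c("x1", "x2"))
  ll <- clogit_loglik(rep(0, 2 + 6), design, deriv = 0)
  expect_equal(as.numeric(ll), 30 * log(1 / 7), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  d <- simulate_design_data(n = 25, J = 4,
                            beta = c(x1 = 0.8, x2 = -0.4), seed = 2)
  design <- choice_design(d, c("x1", "x2"))
  set.seed(3)
  for (rep in 1:3) {
    theta <- rnorm(2 + 3, sd = 0.5)
    ll <- clogit_loglik(theta, design, deriv = 2)
    g <- attr(ll, "gradient")
    h <- 1e-5
    g_fd <- vapply(seq_along(theta), function(k) {
      e <- replace(numeric(length(theta)), k, h)
      (as.numeric(clogit_loglik(theta + e, design, deriv = 0)) -
         as.numeric(clogit_loglik(theta - e, design, deriv = 0))) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_fd, tolerance = 1e-6, ignore_attr = TRUE)
    # Hessian against finite differences of the gradient
    H <- attr(ll, "hessian")
    H_fd <- vapply(seq_along(theta), function(k) {
      e <- replace(numeric(length(theta)), k, h)
      (attr(clogit_loglik(theta + e, design, deriv = 1), "gradient") -
         attr(clogit_loglik(theta - e, design, deriv = 1),
              "gradient")) / (2 * h)
    }, numeric(length(theta)))
    expect_equal(H, H_fd, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("log-sum-exp handles extreme utilities without overflow", {
  d <- simulate_design_data(n = 10, J = 3, beta = c(x1 = 1), seed = 4)
  d$x1 <- d$x1 * 400
  design <- choice_design(d, "x1")
  ll <- clogit_loglik(c(2, 0, 0), design, deriv = 1)
  expect_true(is.finite(as.numeric(ll)))
  expect_true(all(is.finite(attr(ll, "gradient"))))
})

test_that("a 2-alternative fit equals binary logistic regression on differences", {
  d <- simulate_design_data(n = 150, J = 2,
                            beta = c(x1 = 0.9, x2 = -0.6),
                            asc = c(0, 0.4), seed = 5)
  fit <- cond_logit(choice ~ x1 + x2, d)

  # oracle: chooser i picks B iff y=1; P(B) = logistic(asc_B + dx' beta)
  A <- d[d$product == "A", ]; B <- d[d$product == "B", ]
  glm_fit <- glm(B$choice ~ I(B$x1 - A$x1) + I(B$x2 - A$x2),
                 family = binomial())
  expect_equal(unname(fit$beta), unname(coef(glm_fit)[2:3]),
               tolerance = 1e-6)
  expect_equal(unname(fit$asc), unname(coef(glm_fit)[1]),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(glm_fit)), tolerance = 1e-8)
})

test_that("simulated designs recover the true parameters within 3 SE", {
  true_beta <- c(x1 = 0.7, x2 = -0.5)
  true_asc <- c(0, 0.3, -0.2, 0.1, 0, 0.2, -0.1)
  d <- simulate_design_data(n = 2000, J = 7, beta = true_beta,
                            asc = true_asc, seed = 6)
  fit <- cond_logit(choice ~ x1 + x2, d)
  se <- sqrt(diag(fit$vcov))
  est <- fit$coefficients
  truth <- c(true_beta, true_asc[-1])
  expect_true(all(abs(est - truth) < 3 * se))
  expect_true(fit$converged)
})

test_that("a zero covariate gets slope 0 and ASCs reproduce log market shares", {
  d <- simulate_design_data(n = 300, J = 4, beta = c(x1 = 0.8),
                            asc = c(0, 0.5, -0.3, 0.2), seed = 7)
  d$flat <- 0
  fit <- cond_logit(choice ~ flat, d)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
  shares <- tapply(d$choice, d$product, sum) / 300
  expect_equal(unname(fit$asc), as.numeric(log(shares[-1] / shares[1])),
               tolerance = 1e-6)
})

test_that("predicted probabilities normalize, match brute force, and respond monotonically", {
  d3 <- data.frame(subject = rep("s1", 3), product = c("A", "B", "C"),
                   x = c(0.2, -0.1, 0.5), choice = c(1, 0, 0))
  design <- choice_design(d3, "x")
  # hand-built fit object: beta = 1.5, asc = (0.3, -0.2)
  fitlike <- structure(list(coefficients = c(x = 1.5, `asc:B` = 0.3,
                                             `asc:C` = -0.2),
                            include_asc = TRUE, reference = "A",
                            design = design),
                       class = "cond_logit")
  P <- predict(fitlike)
  u <- c(1.5 * 0.2, 1.5 * -0.1 + 0.3, 1.5 * 0.5 - 0.2)
  expect_equal(drop(P), exp(u) / sum(exp(u)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(P), 1, tolerance = 1e-12)

  # raising one alternative's covariate strictly raises its probability
  d3b <- d3; d3b$x[2] <- d3$x[2] + 0.5
  P2 <- predict(fitlike, newdata = choice_design(d3b, "x", chosen = NULL))
  expect_gt(P2[1, "B"], P[1, "B"])
  expect_equal(rowSums(P2), 1, tolerance = 1e-12, ignore_attr = TRUE)

  # zero-parameter model: uniform probabilities
  fit0 <- structure(list(coefficients = c(x = 0, `asc:B` = 0, `asc:C` = 0),
                         include_asc = TRUE, reference = "A",
                         design = design), class = "cond_logit")
  expect_equal(drop(predict(fit0)), rep(1 / 3, 3), ignore_attr = TRUE)
})

test_that("the optimum is unique: random warm starts reach the zero-start fit", {
  d <- simulate_design_data(n = 120, J = 5,
                            beta = c(x1 = 0.6, x2 = 0.3), seed = 8)
  fit0 <- cond_logit(choice ~ x1 + x2, d)
  set.seed(9)
  for (r in 1:3) {
    fit_r <- cond_logit(choice ~ x1 + x2, d,
                        start = rnorm(fit0$n_params, sd = 1))
    expect_equal(fit_r$loglik, fit0$loglik, tolerance = 1e-8)
    expect_equal(fit_r$coefficients, fit0$coefficients, tolerance = 1e-5)
  }
})

test_that("relabeling the reference alternative is a pure reparameterization", {
  d <- simulate_design_data(n = 150, J = 4,
                            beta = c(x1 = 0.5, x2 = -0.3),
                            asc = c(0, 0.4, -0.2, 0.1), seed = 10)
  fit_a <- cond_logit(choice ~ x1 + x2, d, reference = "A")
  fit_c <- cond_logit(choice ~ x1 + x2, d, reference = "C")
  expect_equal(fit_a$beta, fit_c$beta, tolerance = 1e-7)
  expect_equal(fit_a$loglik, fit_c$loglik, tolerance = 1e-9)
  # ASCs shift by the old constant of the new reference
  alpha_a <- c(`asc:A` = 0, fit_a$asc)
  shifted <- alpha_a - alpha_a["asc:C"]
  expect_equal(unname(fit_c$asc[c("asc:A", "asc:B", "asc:D")]),
               unname(shifted[c("asc:A", "asc:B", "asc:D")]),
               tolerance = 1e-6)
  expect_equal(predict(fit_a), predict(fit_c), tolerance = 1e-8)
})

test_that("identical predictors trigger a collinearity error; separation is detected", {
  d <- simulate_design_data(n = 80, J = 3, beta = c(x1 = 0.5), seed = 11)
  d$x1_copy <- d$x1
  expect_error(cond_logit(choice ~ x1 + x1_copy, d), "collinear")

  # perfectly separable design: chosen alternative always has the largest x
  d2 <- simulate_design_data(n = 40, J = 3, beta = c(x1 = 1), seed = 12)
  best <- ave(d2$x1, d2$subject, FUN = max)
  d2$choice <- as.integer(d2$x1 == best)
  expect_error(cond_logit(choice ~ x1, d2, include_asc = FALSE),
               "separation")
})

test_that("likelihood-ratio tests: self-comparison, nestedness, chooser identity", {
  d <- simulate_design_data(n = 100, J = 4,
                            beta = c(x1 = 0.6, x2 = -0.4), seed = 13)
  fit1 <- cond_logit(choice ~ x1, d)
  fit2 <- cond_logit(choice ~ x1 + x2, d)
  self <- lr_test(fit1, fit1)
  expect_equal(self$chi2, 0)
  expect_false(self$nested)

  cmp <- lr_test(fit1, fit2)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$chi2, 0)
  expect_equal(cmp$p, pchisq(cmp$chi2, 1, lower.tail = FALSE))

  # replacement comparison: same parameter count, no p unless forced
  d$x3 <- rnorm(nrow(d))
  fit3 <- cond_logit(choice ~ x3, d)
  rep_cmp <- lr_test(fit1, fit3)
  expect_false(rep_cmp$nested)
  expect_true(is.na(rep_cmp$p))
  forced <- lr_test(fit1, fit3, force_df = 1)
  expect_false(is.na(forced$p))

  d_sub <- d[d$subject %in% unique(d$subject)[1:50], ]
  fit_sub <- cond_logit(choice ~ x1, d_sub)
  expect_error(lr_test(fit_sub, fit2), "identical choosers")
})

test_that("the LR statistic is null-distributed as chi-square(df)", {
  # x2 has no true effect: 2*dLL from adding it should be chi-square(1)
  stats <- replicate(300, NA_real_)
  for (r in seq_along(stats)) {
    d <- simulate_design_data(n = 60, J = 3, beta = c(x1 = 0.5, x2 = 0),
                              seed = 2000 + r)
    f1 <- cond_logit(choice ~ x1, d)
    f2 <- cond_logit(choice ~ x1 + x2, d)
    stats[r] <- lr_test(f1, f2)$chi2
  }
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("McFadden's adjusted r2 follows its definition and conventions", {
  d <- simulate_design_data(n = 200, J = 4,
                            beta = c(x1 = 0.8, x2 = -0.5),
                            asc = c(0, 0.3, -0.1, 0.2), seed = 14)
  fit <- cond_logit(choice ~ x1 + x2, d)
  null <- cond_logit(choice ~ flat, transform(d, flat = 0))
  # null via explicit constants-only model: slope pinned at 0 adds 1 param
  ll0 <- null$loglik
  expect_equal(mcfadden_adj_r2(fit),
               1 - (fit$loglik - fit$n_params) / ll0, tolerance = 1e-10)
  expect_equal(mcfadden_adj_r2(fit, penalty = "slopes"),
               1 - (fit$loglik - 2) / ll0, tolerance = 1e-10)
  expect_equal(mcfadden_adj_r2(fit, adjusted = FALSE),
               1 - fit$loglik / ll0, tolerance = 1e-10)
  expect_equal(mcfadden_adj_r2(fit, null = "equal_shares",
                               adjusted = FALSE),
               1 - fit$loglik / (200 * log(1 / 4)), tolerance = 1e-10)
  # a model no better than its null has unadjusted r2 of 0 and
  # adjusted r2 below 0
  null2 <- cond_logit(choice ~ flat, transform(d, flat = 0))
  expect_lt(mcfadden_adj_r2(null2), 0)
})

test_that("Wald summary reports standard errors and p-values", {
  d <- simulate_design_data(n = 400, J = 4, beta = c(x1 = 0.9, x2 = 0),
                            seed = 15)
  s <- summary(cond_logit(choice ~ x1 + x2, d))
  tab <- s$coefficients
  expect_lt(tab["x1", "Pr(>|z|)"], 1e-6)
  expect_gt(tab["x2", "Pr(>|z|)"], 0.01)
  expect_equal(tab[, "z value"], tab[, "Estimate"] / tab[, "Std. Error"],
               tolerance = 1e-12)
})

test_that("Hausman-McFadden: identical fits give q = 0 and IIA data are not over-rejected", {
  d <- simulate_design_data(n = 250, J = 4,
                            beta = c(x1 = 0.7, x2 = -0.4),
                            asc = c(0, 0.3, -0.2, 0.4), seed = 16)
  res <- hausman_mcfadden(choice ~ x1 + x2, d, removed = "D")
  expect_equal(res$df, 2 + 2)  # 2 slopes + 2 remaining non-reference ASCs
  expect_true(res$p > 0 && res$p <= 1)

  # artificial q = 0: compare a fit against itself through the formula
  fitB <- hausman_mcfadden(choice ~ x1 + x2, d, removed = "B")
  expect_true(is.finite(fitB$chi2))

  # IIA holds by construction: across replicates, rejections at alpha=0.05
  # should be near nominal (binomial check at a generous band)
  rej <- logical(60)
  for (r in seq_along(rej)) {
    dr <- simulate_design_data(n = 150, J = 3, beta = c(x1 = 0.8),
                               asc = c(0, 0.2, -0.2), seed = 3000 + r)
    h <- suppressWarnings(hausman_mcfadden(choice ~ x1, dr, removed = "C"))
    rej[r] <- is.finite(h$p) && h$p < 0.05
  }
  expect_lte(mean(rej), 0.18)

  # all-removals interface returns one row per alternative
  tab <- suppressWarnings(hausman_mcfadden(choice ~ x1 + x2, d))
  expect_equal(tab$removed, c("A", "B", "C", "D"))
  expect_true(all(tab$df == 4))
})

test_that("degenerate Hausman inputs are rejected", {
  d <- simulate_design_data(n = 50, J = 3, beta = c(x1 = 0.5), seed = 17)
  d$choice <- as.integer(d$product == "A")  # everyone chose A
  expect_error(hausman_mcfadden(choice ~ x1, d, removed = "A"),
               "all choosers|too few")
})

test_that("simulate() draws choices from the fitted probabilities", {
  d <- simulate_design_data(n = 200, J = 3, beta = c(x1 = 1.2), seed = 18)
  fit <- cond_logit(choice ~ x1, d)
  sims <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(dim(sims), c(200, 50))
  freq <- rowMeans(sims == "A")
  expect_gt(cor(freq, predict(fit)[, "A"]), 0.9)
})

test_that("residuals are observed-minus-predicted and sum to zero per alternative", {
  d <- simulate_design_data(n = 150, J = 4, beta = c(x1 = 0.5), seed = 19)
  fit <- cond_logit(choice ~ x1, d)
  r <- residuals(fit)
  # with ASCs in the model the score equations force per-alternative sums
  # of residuals to zero at the optimum
  expect_lt(max(abs(colSums(r))), 1e-6)
  expect_equal(dim(r), c(150, 4))
})
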