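# Small hand-built panels used across the suite.

# complete-block panel with explicit cell values: n_subjects x n_alts,
# n_em emotion items filled from a deterministic pattern unless given
toy_panel <- function(n_subjects = 2, n_alts = 7, n_em = 3,
                      emotions = NULL, liking = NULL, choice = NULL,
                      instrument = "toy") {
  alts <- LETTERS[seq_len(n_alts)]
  df <- expand.grid(product = alts,
                    subject = sprintf("P%02d", seq_len(n_subjects)),
                    stringsAsFactors = FALSE)[, c("subject", "product")]
  n <- nrow(df)
  df$liking <- if (is.null(liking)) seq(10, 90, length.out = n) else liking
  if (is.null(choice)) {
    choice <- rep(0L, n)
    choice[seq(1, n, by = n_alts)] <- 1L   # everyone chooses alternative A
  }
  df$choice <- choice
  E <- if (is.null(emotions)) {
    matrix(((seq_len(n * n_em) * 7) %% 5), n, n_em)
  } else emotions
  colnames(E) <- sprintf("e%02d", seq_len(n_em))
  emotion_panel(cbind(df, as.data.frame(E)), instrument = instrument)
}

# long-format choice data simulated from known conditional-logit truth
simulate_design_data <- function(n = 200, J = 3, beta = c(x1 = 1, x2 = -0.5),
                                 asc = rep(0, J), seed = 42) {
  set.seed(seed)
  alts <- LETTERS[seq_len(J)]
  df <- expand.grid(product = alts, subject = sprintf("C%04d", seq_len(n)),
                    stringsAsFactors = FALSE)[, c("subject", "product")]
  K <- length(beta)
  X <- matrix(rnorm(n * J * K), ncol = K,
              dimnames = list(NULL, names(beta)))
  U <- matrix(drop(X %*% beta) + rep(asc, times = n), n, J, byrow = TRUE)
  P <- exp(U - apply(U, 1, max)); P <- P / rowSums(P)
  pick <- vapply(seq_len(n), function(i) sample.int(J, 1, prob = P[i, ]),
                 integer(1))
  df$choice <- as.integer(rep(seq_len(J), n) == rep(pick, each = J))
  cbind(df, as.data.frame(X))
}
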