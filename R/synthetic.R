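#' Configuration for the synthetic emotion-and-choice generator
#'
#' The generator emulates the structure of a breakfast-drink emotion study:
#' each subject tastes every product and rates a set of emotion items on a
#' 0--4 scale plus liking on a 0--100 scale; a week later each subject
#' chooses exactly one product. Two latent affect dimensions drive the
#' data: per subject x product, valence and arousal are the product's mean
#' level plus a subject-level offset plus trial noise; emotion items load
#' on the two latents through a loading matrix and get item noise, then are
#' clipped and (optionally) rounded to the 0--4 ordinal support; liking is
#' affine in valence with its own noise, clipped to 0--100; the single
#' choice is drawn from a conditional logit whose utilities combine the
#' true constants with the true slopes on (standardized) liking, valence
#' and arousal.
#'
#' The default product valence profile is calibrated so that two products
#' dominate choice (roughly 40% and 30% of subjects), putting the
#' alternative-specific constants in the regime the models must handle.
#'
#' @param n_subjects,n_alternatives,n_emotions design dimensions; defaults
#'   123 subjects x 7 products, 12 items (a PrEmo-like instrument; use 39
#'   for an EsSense-like one).
#' @param loadings optional n_emotions x 2 loading matrix; by default a
#'   balanced-valence matrix is generated (half the items load positively
#'   on valence, half negatively, arousal loadings alternate in sign) with
#'   deterministic small jitter.
#' @param product_valence,product_arousal per-alternative latent means.
#' @param subject_sd SD of the subject-level offset on each latent (an
#'   offset bias, removed by within-participant demeaning).
#' @param latent_sd SD of the trial-level latent noise.
#' @param item_sd SD of the per-item measurement noise.
#' @param item_baseline mean item response placing scores inside 0--4.
#' @param liking_intercept,liking_slope,liking_sd liking = intercept +
#'   slope * valence + N(0, sd), clipped to 0--100.
#' @param beta true utility slopes, named `liking`, `valence`, `arousal`;
#'   the liking term enters as `(liking - intercept) / 20` so all three
#'   slopes live on a comparable scale.
#' @param asc true alternative-specific constants (length
#'   `n_alternatives`, first is the reference and conventionally 0).
#' @param discretize round emotion scores to the 0--4 integer support.
#' @param seed RNG seed used by [generate_panel()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 123, n_alternatives = 7,
                         n_emotions = 12, loadings = NULL,
                         product_valence = NULL, product_arousal = NULL,
                         subject_sd = 0.3, latent_sd = 0.45,
                         item_sd = 0.45, item_baseline = 2,
                         liking_intercept = 52, liking_slope = 14,
                         liking_sd = 12,
                         beta = c(liking = 0.6, valence = 1.1,
                                  arousal = 0),
                         asc = rep(0, n_alternatives),
                         discretize = TRUE, seed = 1L) {
  if (is.null(product_valence)) {
    base_v <- c(-0.15, -0.65, -0.7, -0.5, -0.1, 1.15, 0.95)
    product_valence <- rep_len(base_v, n_alternatives)
  }
  if (is.null(product_arousal)) {
    base_a <- c(0.3, -0.4, 0.1, -0.2, 0.45, -0.1, -0.35)
    product_arousal <- rep_len(base_a, n_alternatives)
  }
  cfg <- list(n_subjects = n_subjects, n_alternatives = n_alternatives,
              n_emotions = n_emotions, loadings = loadings,
              product_valence = product_valence,
              product_arousal = product_arousal,
              subject_sd = subject_sd, latent_sd = latent_sd,
              item_sd = item_sd, item_baseline = item_baseline,
              liking_intercept = liking_intercept,
              liking_slope = liking_slope, liking_sd = liking_sd,
              beta = beta, asc = asc, discretize = discretize,
              seed = seed)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_subjects >= 2, n_alternatives >= 2, n_emotions >= 2,
              length(product_valence) == n_alternatives,
              length(product_arousal) == n_alternatives,
              length(asc) == n_alternatives,
              all(c("liking", "valence", "arousal") %in% names(beta)))
    if (any(c(subject_sd, latent_sd, item_sd, liking_sd) < 0)) {
      stop("noise SDs must be >= 0", call. = FALSE)
    }
    if (!is.null(loadings) &&
        (nrow(loadings) != n_emotions || ncol(loadings) != 2)) {
      stop("loadings must be n_emotions x 2", call. = FALSE)
    }
  })
  invisible(cfg)
}

default_loadings <- function(n_emotions) {
  i <- seq_len(n_emotions)
  if (n_emotions <= 20) {
    # compact non-verbal instrument: balanced valence signs (half
    # positive, half negative items), clearly identifiable arousal axis
    v <- rep(c(1, -1), length.out = n_emotions) * (0.75 + 0.1 * sin(i))
    a <- rep(c(0.4, 0.32, -0.4, -0.32), length.out = n_emotions) *
      (1 + 0.2 * cos(i))
  } else {
    # large verbal instrument: mostly mildly positive terms, few negative,
    # a block of uncategorized terms dominated by arousal -- valence
    # captures a much smaller variance share than in the compact case
    n_neg <- 3
    n_unc <- max(0, round(n_emotions * 11 / 39))
    n_pos <- n_emotions - n_neg - n_unc
    v <- c(0.56 + 0.08 * sin(seq_len(n_pos)),
           rep(-0.6, n_neg),
           0.05 * cos(seq_len(n_unc)))
    a <- c(rep(c(0.25, 0.2, -0.25, -0.2), length.out = n_pos),
           rep(0.15, n_neg),
           rep(c(0.55, -0.45), length.out = n_unc))
  }
  cbind(valence = v, arousal = a)
}

#' Generate a synthetic emotion panel with known ground truth
#'
#' @param config a [synth_config()].
#' @return A validated [emotion_panel()] (instrument `"synthetic"`, with
#'   choice flags) carrying a `"ground_truth"` attribute: the latent
#'   valence/arousal per trial, the loading matrix, true utilities and
#'   choice probabilities, and the configuration. Byte-reproducible from
#'   `config$seed`.
#' @export
generate_panel <- function(config = synth_config()) {
  validate_synth_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects; J <- cfg$n_alternatives; p <- cfg$n_emotions
  L <- cfg$loadings %||% default_loadings(p)
  subj_ids <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
  alts <- LETTERS[seq_len(J)]

  subj_v <- stats::rnorm(n, 0, cfg$subject_sd)
  subj_a <- stats::rnorm(n, 0, cfg$subject_sd)
  valence <- rep(cfg$product_valence, times = n) + rep(subj_v, each = J) +
    stats::rnorm(n * J, 0, cfg$latent_sd)
  arousal <- rep(cfg$product_arousal, times = n) + rep(subj_a, each = J) +
    stats::rnorm(n * J, 0, cfg$latent_sd)

  E <- cbind(valence, arousal) %*% t(L) + cfg$item_baseline +
    matrix(stats::rnorm(n * J * p, 0, cfg$item_sd), n * J, p)
  E <- pmin(pmax(E, 0), 4)
  if (cfg$discretize) E <- round(E)
  colnames(E) <- sprintf("e%02d", seq_len(p))

  liking <- cfg$liking_intercept + cfg$liking_slope * valence +
    stats::rnorm(n * J, 0, cfg$liking_sd)
  liking <- pmin(pmax(liking, 0), 100)

  U <- rep(cfg$asc, times = n) +
    cfg$beta[["liking"]] * (liking - cfg$liking_intercept) / 20 +
    cfg$beta[["valence"]] * valence +
    cfg$beta[["arousal"]] * arousal
  Um <- matrix(U, nrow = n, ncol = J, byrow = TRUE)
  P <- exp(Um - apply(Um, 1, max))
  P <- P / rowSums(P)
  pick <- vapply(seq_len(n), function(i) sample.int(J, 1, prob = P[i, ]),
                 integer(1))
  choice <- as.integer(rep(seq_len(J), times = n) == rep(pick, each = J))

  df <- data.frame(subject = rep(subj_ids, each = J),
                   product = rep(alts, times = n),
                   liking = liking, choice = choice,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(E))
  panel <- emotion_panel(df, instrument = "synthetic",
                         emotion_names = colnames(E), alternatives = alts)
  attr(panel, "ground_truth") <- list(valence = valence, arousal = arousal,
                                      loadings = L, utilities = Um,
                                      choice_probs = P, chosen = pick,
                                      config = cfg)
  panel
}

#' @rdname generate_panel
#' @param panel a generated panel.
#' @return `ground_truth()` returns the generator's ground-truth record.
#' @export
ground_truth <- function(panel) attr(panel, "ground_truth")

#' Generate a second instrument's view of the same tasting sessions
#'
#' Produces a companion panel measuring the same subject x product latent
#' valence/arousal states as `panel` through a different emotion
#' instrument: a fresh loading matrix of the requested size plus fresh item
#' noise, with liking and choice copied from the original sessions. This
#' mirrors a study design where participants rate every product on two
#' instruments in the same sitting.
#'
#' @param panel a panel from [generate_panel()] (must carry ground truth).
#' @param n_emotions item count of the companion instrument.
#' @param item_sd item noise SD; defaults to the original configuration's.
#' @param instrument label for the new panel.
#' @param seed RNG seed for the new instrument's item noise.
#' @return A validated [emotion_panel()] sharing subjects, products,
#'   liking and choice with `panel`, with its own `"ground_truth"`.
#' @export
generate_instrument_view <- function(panel, n_emotions = 39,
                                     item_sd = NULL,
                                     instrument = "synthetic2",
                                     seed = 1L) {
  gt <- ground_truth(panel)
  if (is.null(gt)) stop("panel carries no ground truth", call. = FALSE)
  cfg <- gt$config
  if (is.null(item_sd)) item_sd <- cfg$item_sd
  set.seed(seed)
  L <- default_loadings(n_emotions)
  m <- nrow(panel)
  E <- cbind(gt$valence, gt$arousal) %*% t(L) + cfg$item_baseline +
    matrix(stats::rnorm(m * n_emotions, 0, item_sd), m, n_emotions)
  E <- pmin(pmax(E, 0), 4)
  if (cfg$discretize) E <- round(E)
  colnames(E) <- sprintf("e%02d", seq_len(n_emotions))
  df <- data.frame(subject = panel$subject, product = panel$product,
                   liking = panel$liking, choice = panel$choice,
                   stringsAsFactors = FALSE)
  out <- emotion_panel(cbind(df, as.data.frame(E)),
                       instrument = instrument,
                       emotion_names = colnames(E),
                       alternatives = alternatives(panel))
  gt$loadings <- L
  attr(out, "ground_truth") <- gt
  out
}
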