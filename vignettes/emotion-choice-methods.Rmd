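---
title: "Predicting individual food choice from liking and food-evoked emotions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual food choice from liking and food-evoked emotions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emochoice)
```

# The problem

Sensory and consumer science increasingly measures *food-evoked emotions* —
what tasting a product makes a consumer feel — alongside the classic
hedonic liking rating, on the hypothesis that emotion profiles carry
information about subsequent choice behaviour that liking alone does not.
`emochoice` implements a complete pipeline for testing that hypothesis on
panel data in which every participant tastes every product, rates liking
(0–100 visual analogue scale) and a battery of emotion items (ordinal 0–4),
and later chooses exactly one product to consume.

The pipeline has four stages, each exposed as ordinary functions:

1. **Within-participant demeaning** (`demean_within_subject`). Participants
   use response scales idiosyncratically; subtracting each participant's own
   mean per emotion item removes these offset biases, leaving only the
   within-participant variation across products — the variation that can
   discriminate products *for that person*. Demeaning is a linear
   projection, so it is idempotent and invariant to any per-participant
   constant shift of the raw scores (both properties are asserted in the
   test suite).

2. **Valence/arousal extraction** (`fit_pca`, `orient_signs`,
   `project_scores`). The demeaned trials × items matrix is decomposed by
   singular value decomposition. In emotion data of this kind the first
   component orders emotions from unpleasant to pleasant (valence) and the
   second from calm to energetic (arousal). Items are *not* variance-scaled
   before the SVD: all items share the same 0–4 response scale, and only
   mean removal is part of the procedure. Because an SVD determines each
   axis only up to sign, `orient_signs` fixes PC1 so its scores correlate
   positively with liking (making its choice-model slope positive and
   interpretable) and every further component so its largest-magnitude
   loading is positive.

3. **Conditional logit choice models** (`cond_logit`). The probability that
   chooser $i$ picks alternative $j$ among $J$ is
   $$P_{ij} = \frac{\exp(\alpha_j + x_{ij}^\top \beta)}{\sum_k \exp(\alpha_k + x_{ik}^\top \beta)},$$
   with alternative-varying covariates $x_{ij}$ (standardized liking and
   component scores) and alternative-specific constants (ASCs) $\alpha_j$,
   the first alternative fixed at $\alpha = 0$ as reference. Covariates are
   centered and scaled to standard deviation 1 (n−1 denominator) before
   fitting so slopes are comparable across predictors measured in different
   units. Model quality is compared with likelihood-ratio tests,
   McFadden's adjusted pseudo-$r^2$, and the Hausman–McFadden test of the
   independence-of-irrelevant-alternatives (IIA) assumption.

4. **Leave-one-out cross-validation** (`loocv_predict`). Choice prediction
   is evaluated per person: for each subject in turn the PCA rotation, the
   predictor scaling and the logit fit are re-learned on the other $n-1$
   subjects, the held-out subject's demeaned rows are projected through the
   training rotation, and the subject's $J$ choice probabilities are
   predicted and converted to ranks (1 = most likely). The headline summary
   is the share of subjects whose actually chosen product was ranked 1
   (chance: $1/J$, i.e. 14.3% for 7 products).

# The model ladder

`run_ladder` fits seven models built from liking and the first two
components of two instruments (a compact non-verbal one and a large verbal
one, called `premo` and `essense` throughout):

| id | predictors |
|----|-----------------------------------|
| 1  | liking |
| 2  | premo PC1 |
| 3  | essense PC1 |
| 4  | liking + premo PC1 |
| 5  | liking + essense PC1 |
| 6  | liking + premo PC1 + premo PC2 |
| 7  | liking + essense PC1 + essense PC2 |

and runs the comparison sequence 1v2, 1v3, 2v4, 3v5, 4v5, 4v6, 5v7.
Three of these (1v2, 1v3, 4v5) *replace* one predictor by another: the
models have equal parameter counts and are not nested, so twice the
log-likelihood difference is not $\chi^2$ distributed. These comparisons
are reported descriptively (statistic, no p-value; `lr_test(force_df=)`
exists as an explicit compatibility switch for analyses that nonetheless
assign them p-values). Selection uses only the nested addition steps
(2v4, 3v5, 4v6, 5v7) at $\alpha = 0.05$; when both instrument branches
survive, the branch with the higher maximized log-likelihood wins. This
keeps the selection statistically defensible while still producing every
statistic of the published sequence.

Design choices worth recording:

* **ASCs are always included.** The data regime this package targets has
  strongly unequal market shares (two products chosen by ~70% of subjects
  combined); without ASCs the slope estimates would absorb baseline
  popularity. The Hausman test's degrees of freedom (7 = 2 slopes + 5
  remaining ASCs for the combined model on 7 alternatives) only make sense
  with constants present.
* **Reference alternative** is the first of the lexicographically ordered
  alternative set (product A) everywhere; estimates are invariant to this
  choice up to reparameterization (tested).
* **McFadden's adjusted $r^2$** defaults to $1-(LL-K)/LL_0$ with the
  constants-only model as null and $K$ counting every estimated parameter.
  Conventions differ across software, so `mcfadden_adj_r2` also offers
  slope-only penalties and the equal-shares null; the acceptance check for
  the published value searches the documented conventions and records
  which one matches.
* **Hausman–McFadden removals.** The removed alternative is configurable
  and defaults to all alternatives in turn, since analyses rarely state
  which alternative was dropped. When the removed alternative is the
  reference, both fits are re-parameterized against the first remaining
  alternative so constants stay comparable. The variance difference
  $V_r - V_f$ is frequently indefinite in well-behaved data; a
  Moore–Penrose pseudo-inverse is then used with a warning (negative
  statistics are reported as computed — they indicate no evidence against
  IIA).

# Numerical choices

* Estimation is Newton–Raphson on the analytic gradient and Hessian from a
  cold start at zero, with step-halving as a safeguard; the log-likelihood
  is globally concave, so the optimum is unique (verified by random warm
  starts). Convergence is declared at max $|$gradient$| < 10^{-8}$, capped
  at 100 iterations.
* The log-sum-exp is computed with the row maximum subtracted, so extreme
  utilities cannot overflow.
* Apparent separation (parameter norm diverging while the likelihood still
  improves) and singular information (collinear predictors) raise explicit
  errors rather than returning garbage.
* A covariate with no within-chooser variation (e.g. identically zero)
  carries no choice information; its slope is pinned at 0 with zero
  variance instead of crashing the solver.
* Rank ties in predicted probabilities are broken by alternative order
  (A before B); ties are measure-zero in real data but the synthetic tests
  hit them deliberately.
* Missing cells, incomplete blocks, and out-of-range scores are hard
  errors at the I/O boundary — no imputation anywhere.

# Cross-validation details

Two points in the leave-one-out scheme are genuinely open and are resolved
as follows:

* **Centering of the held-out subject.** The rotation comes from the
  training subjects, but each subject's demeaning uses their *own* seven
  product means. A subject's own means are available before any choice is
  made, so this does not leak outcome information, and it is the only
  centering consistent with the demeaning stage.
* **Predictor scaling per fold or globally.** `loocv_predict` defaults to
  fitting the standardization on the n−1 training subjects and applying it
  to the held-out subject (`scaling = "fold"`, the honest choice); a
  `"global"` option standardizes once on the full sample. On synthetic
  data the two agree closely (tested) but not exactly.

The left-out subject's data never enter their fold's rotation, scaling or
fit. The suite asserts this by reassigning a subject's choice flag — which
is training-side-only information for their own fold — and checking their
predicted probabilities are bit-identical.

# The synthetic-data generator

`generate_panel` emulates the structure the analysis assumes, with known
ground truth, so every stage is testable without any proprietary data:

* 123 subjects × 7 products by default (the canonical study size for this
  design), with emotion instruments of 12 items (compact, balanced
  positive/negative) or 39 items (large, mostly mildly positive terms plus
  an arousal-dominated block — which is why its PC1 captures a much
  smaller variance share).
* Latent valence and arousal per subject × product: product mean + subject
  offset (SD 0.3) + trial noise (SD 0.45), in latent units. The product
  valence profile is calibrated so two products dominate choice (roughly
  40% and 30% in expectation), exercising the ASC-relevant regime.
* Emotion items: loadings × latents + item noise (SD 0.45), shifted to a
  baseline of 2 and clipped/rounded to the ordinal 0–4 support.
* Liking: $52 + 14 \cdot \text{valence} + N(0, 12)$, clipped to 0–100.
* Choice: exactly one per subject, drawn from a conditional logit on the
  true utilities with slopes (liking 0.6, valence 1.1, arousal 0) — the
  zero arousal slope reproduces the characteristic finding that arousal
  does not predict choice at the group level.
* `generate_instrument_view` produces a second instrument's measurement of
  the *same* sessions (same latents, liking, choice; fresh loadings and
  item noise), mirroring a within-session two-instrument protocol.

What the generator does **not** emulate: hedonic-asymmetry semantics of
individual emotion terms, test-order and fatigue effects, individual
differences in optimal arousal, and any dependence between instruments'
item noise. Passing tests therefore demonstrate correctness of the
machinery and recoverability under the stated statistical structure — not
that real instruments behave this way.

# Problem sizes

The test suite runs the full pipeline at the canonical 123 × 7 size and
smaller; distributional checks use 300–400 replicates of 50–60 choosers;
parameter recovery uses 500 replicates at 500 choosers × 7 alternatives
(bias and Wald coverage of the slopes); `scripts/acceptance.R` runs the
complete two-instrument pipeline, ladder, IIA battery and two
cross-validations at 123 × 7. Everything is deterministic given the seed.

# Known limitations

* Only complete blocks are supported; unbalanced designs are rejected, not
  handled.
* No mixed or nested logit, no random coefficients, no chooser-level
  covariates: relative odds obey IIA by construction, which is why the
  Hausman–McFadden diagnostic is part of the standard output.
* The higher-component scan (`extended_pc_scan`) is a generic forward
  selection over components 2..k; components beyond the second are
  typically unstable across folds (quantify with `loading_stability`) and
  should be interpreted with caution.
* Wald p-values use the normal approximation from the inverse observed
  information; at small n the LR test is the more reliable comparison.
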