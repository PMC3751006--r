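## Decision-tree module: baseline assignment of latent glucose state,
## diagnosis and intervention status for each strategy.
##
## The latent state distribution is common to all arms (arms differ only in
## diagnosis, intervention and screening cost), which enables common-random-
## number comparisons: with the same uniform draw a subject occupies the same
## latent state in every arm.

#' Baseline assignment distribution for a strategy
#'
#' Implements the screening decision tree.  The latent state probabilities
#' come from the screening cascade: a fraction `1 - neg_rate_2hpg` of the
#' population is 2-h plasma glucose positive; of those, `ogtt_positive_rate`
#' are OGTT positive; of the OGTT positives, `igt_fraction_of_positive` are
#' IGT and the rest have undiagnosed diabetes.  Screen-negatives are
#' assigned normal glucose tolerance.  In screening arms each subject
#' attends screening with probability `compliance` (incurring the screening
#' cost); attending IGT subjects are detected with probability
#' `detection_level` and, in the diet/exercise/duo arms, detected IGT
#' subjects receive the lifestyle intervention.  Non-attending and
#' undetected subjects follow the control arm's fate (but remain in their
#' strategy's cohort).  The control arm uses the same latent distribution
#' with no diagnosis and no cost.
#'
#' @param strategy a strategy list from `params$strategies`, or a strategy
#'   id string.
#' @param params a `dm_parameters` object.
#' @return a data.frame (canonically ordered for inverse-CDF sampling) with
#'   columns `state` (`"normal"`, `"igt"`, `"onset_dm"`), `diagnosed`,
#'   `receives_intervention`, `screening_cost` and `prob`; probabilities
#'   sum to 1.
#' @export
#' @examples
#' d <- initial_distribution("diet", default_parameters())
#' sum(d$prob)
#' # probability of entering the model as diagnosed, intervened IGT:
#' sum(d$prob[d$receives_intervention])  # 0.04 * 0.305 * 0.478
initial_distribution <- function(strategy, params) {
  if (is.character(strategy)) {
    strategy <- params$strategies[[match.arg(strategy, names(params$strategies))]]
  }
  sc <- params$screening
  p_pos <- 1 - sc$neg_rate_2hpg
  p_igt <- p_pos * sc$ogtt_positive_rate * sc$igt_fraction_of_positive
  p_dm  <- p_pos * sc$ogtt_positive_rate * (1 - sc$igt_fraction_of_positive)
  p_norm <- 1 - p_igt - p_dm

  row <- function(state, diagnosed, ri, cost, prob)
    data.frame(state = state, diagnosed = diagnosed,
               receives_intervention = ri, screening_cost = cost,
               prob = prob, stringsAsFactors = FALSE)

  if (!isTRUE(strategy$has_screening)) {
    out <- rbind(row("normal",   FALSE, FALSE, 0, p_norm),
                 row("igt",      FALSE, FALSE, 0, p_igt),
                 row("onset_dm", FALSE, FALSE, 0, p_dm))
  } else {
    cpl <- sc$compliance
    det <- sc$detection_level
    cost <- params$costs$screening
    intervenes <- strategy$id %in% c("diet", "exercise", "duo")
    ## within each latent-state block the sub-branch ordering is fixed
    ## (attended & detected, attended & undetected, unattended) so the same
    ## uniform draw yields the same attendance decision in every arm
    out <- rbind(
      row("normal", FALSE, FALSE, cost, p_norm * cpl),
      row("normal", FALSE, FALSE, 0,    p_norm * (1 - cpl)),
      row("igt",    TRUE,  intervenes, cost, p_igt * cpl * det),
      row("igt",    FALSE, FALSE, cost, p_igt * cpl * (1 - det)),
      row("igt",    FALSE, FALSE, 0,    p_igt * (1 - cpl)),
      row("onset_dm", TRUE,  FALSE, cost, p_dm * cpl),
      row("onset_dm", FALSE, FALSE, 0,    p_dm * (1 - cpl)))
  }
  out <- out[out$prob > 0, , drop = FALSE]   # zero-mass branches drop out
  tot <- sum(out$prob)
  if (abs(tot - 1) > 1e-12)
    stop("internal error: initial distribution sums to ", format(tot))
  out$prob <- out$prob / tot   # normalisation guard against rounding
  rownames(out) <- NULL
  out
}

#' Sample a baseline cohort from an assignment distribution
#'
#' Inverse-CDF sampling over the canonical row ordering of
#' [initial_distribution()], using a single uniform draw per subject.
#' Because the latent-state blocks are aligned across strategies, calling
#' this with the same seed for every arm gives each subject the same latent
#' state (and the same screening-attendance decision) in every arm --
#' the common-random-number design used for paired comparisons.
#'
#' @param dist distribution data.frame from [initial_distribution()].
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @return a data.frame with one row per subject: `subject`, `state`,
#'   `diagnosed`, `receives_intervention`, `screening_cost`.
#' @export
sample_cohort <- function(dist, n, seed) {
  if (!is.numeric(n) || n < 1) stop("'n' must be a positive count")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  u <- runif(n)
  idx <- findInterval(u, cumsum(dist$prob), left.open = TRUE) + 1L
  idx[idx > nrow(dist)] <- nrow(dist)   # guard the u ~ 1 edge
  out <- dist[idx, c("state", "diagnosed", "receives_intervention",
                     "screening_cost")]
  rownames(out) <- NULL
  cbind(subject = seq_len(n), out)
}
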