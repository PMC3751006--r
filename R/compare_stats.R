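## Nonparametric between-arm comparisons: two-sided Wilcoxon rank-sum
## (Mann-Whitney) test with midranks for ties, exact enumeration of the
## rank-sum distribution for small untied samples and a tie-corrected,
## continuity-corrected normal approximation otherwise.

## internal: exact null distribution of the rank sum W of the first sample
## (size m) when m + n untied ranks are split at random: enumerates, by a
## subset-sum dynamic programme, how many of the choose(m+n, m) splits give
## each possible rank sum.  counts[w + 1] = #splits with W = w (w = 0..mN
## for convenience; impossible sums have count 0).
exact_w_counts <- function(m, n) {
  N <- m + n
  maxs <- sum((n + 1):N)                 # largest possible rank sum
  dp <- matrix(0, m + 1, maxs + 1)       # dp[j+1, s+1]: j ranks summing to s
  dp[1, 1] <- 1
  for (k in seq_len(N)) {
    for (j in rev(seq_len(min(k, m)))) {
      shifted <- c(numeric(k), dp[j, seq_len(maxs + 1 - k)])
      dp[j + 1, ] <- dp[j + 1, ] + shifted
    }
  }
  dp[m + 1, ]
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum comparison of two samples of
#' a continuous outcome, as used for all between-strategy comparisons.
#' Ties receive midranks.  When both samples have at most `exact_limit`
#' observations and there are no ties, the p-value is computed by exact
#' enumeration of the rank-sum distribution; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param sample_a,sample_b numeric vectors (nonempty).
#' @param alpha significance level (default 0.05).
#' @param exact_limit largest per-sample size for which the exact
#'   distribution is enumerated (default 20).
#' @return an object of class `dm_ranksum`: list with `statistic` (the
#'   rank sum of `sample_a`), `u` (the Mann-Whitney U of `sample_a`),
#'   `p_value`, `significant`, `method` and `degenerate` (all values tied
#'   across both samples, in which case p = 1).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 (exact)
rank_sum_test <- function(sample_a, sample_b, alpha = 0.05,
                          exact_limit = 20L) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be nonempty")
  m <- length(sample_a); n <- length(sample_b); N <- m + n
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                      # midranks for ties
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  ties <- table(pooled)
  degenerate <- length(ties) == 1L

  if (degenerate) {
    p <- 1
    method <- "degenerate"
  } else if (m <= exact_limit && n <= exact_limit && all(ties == 1L)) {
    counts <- exact_w_counts(m, n)
    total <- sum(counts)
    lo <- sum(counts[seq_len(W + 1)]) / total         # P(W' <= W)
    hi <- sum(counts[(W + 1):length(counts)]) / total # P(W' >= W)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      method <- "degenerate"
      degenerate <- TRUE
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
      method <- "normal"
    }
  }
  structure(list(statistic = W, u = U, p_value = p,
                 significant = p < alpha, method = method,
                 degenerate = degenerate,
                 n_a = m, n_b = n),
            class = "dm_ranksum")
}

#' @export
print.dm_ranksum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, p = %.4g%s\n",
              x$method, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise strategy comparisons of subject-level outcomes
#'
#' Wilcoxon rank-sum tests for every strategy pair at each initiation age,
#' for QALYs and survival years over the diabetes/IGT subgroup and for
#' costs over the configured cost-averaging population.
#'
#' @param run a `dm_run` from [run_model()].
#' @param outcomes outcomes to compare.
#' @return data.frame: `initiation_age`, `outcome`, `arm_a`, `arm_b`,
#'   `statistic`, `p_value`, `significant`.
#' @export
compare_arms <- function(run,
                         outcomes = c("qalys", "survival_years", "cost")) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  pop <- run$params$settings$cost_population
  rows <- list()
  for (age in names(run$subjects)) {
    by_arm <- run$subjects[[age]]
    arms <- names(by_arm)
    for (i in seq_along(arms)) for (j in seq_along(arms)) {
      if (i >= j) next
      for (oc in outcomes) {
        pick <- function(df) {
          if (oc == "cost" && pop == "all") df$cost
          else df[df$eligible, oc]
        }
        rt <- rank_sum_test(pick(by_arm[[i]]), pick(by_arm[[j]]))
        rows[[length(rows) + 1L]] <- data.frame(
          initiation_age = as.integer(age), outcome = oc,
          arm_a = arms[i], arm_b = arms[j],
          statistic = rt$statistic, p_value = rt$p_value,
          significant = rt$significant)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
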