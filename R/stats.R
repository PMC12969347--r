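#' @include utils.R
NULL

#' Two-sided permutation test on the difference of group means
#'
#' Statistic: absolute difference of group means.  The null distribution
#' is obtained by permuting group labels: exactly (full enumeration of
#' group-A index sets) when the number of distinct assignments is at most
#' 20,000, otherwise by Monte Carlo with \code{(1 + #exceedances) /
#' (1 + nPerm)} smoothing so p > 0.  A bootstrap confidence interval
#' (percentile, 2000 resamples) on the group difference is reported
#' alongside; the p-value itself comes from the permutation test only.
#'
#' @param valuesA,valuesB numeric group values (>= 2 each).
#' @param nPerm Monte Carlo permutations (default 2000).
#' @param seed RNG seed for Monte Carlo permutation and bootstrap.
#' @param nBoot bootstrap resamples for the CI.
#' @return List with \code{p}, \code{observed} (mean(A) - mean(B)),
#'   \code{exact} (enumeration used?), \code{nPerm}, \code{ci}
#'   (bootstrap 95% CI on the difference), and \code{seed}.
#' @export
permTest <- function(valuesA, valuesB, nPerm = 2000L, seed = 1L,
                     nBoot = 2000L) {
  .stop_if(length(valuesA) < 2L || length(valuesB) < 2L,
           "each group needs at least 2 values")
  nA <- length(valuesA)
  pooled <- c(valuesA, valuesB)
  n <- length(pooled)
  obs_diff <- mean(valuesA) - mean(valuesB)
  obs <- abs(obs_diff)
  total <- choose(n, nA)
  tol <- 1e-12 * max(1, obs)
  if (total <= 20000) {
    idx <- utils::combn(n, nA)
    stats_null <- abs(colMeans(matrix(pooled[idx], nrow = nA)) -
                      (sum(pooled) - colSums(matrix(pooled[idx],
                                                    nrow = nA))) /
                      (n - nA))
    p <- sum(stats_null >= obs - tol) / total
    exact <- TRUE
    nPerm_used <- total
  } else {
    stats_null <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
      ia <- sample.int(n, nA)
      abs(mean(pooled[ia]) - mean(pooled[-ia]))
    }, numeric(1)))
    p <- (1 + sum(stats_null >= obs - tol)) / (1 + nPerm)
    exact <- FALSE
    nPerm_used <- nPerm
  }
  ci <- withSeed(deriveSeed(seed, 1L), {
    boots <- vapply(seq_len(nBoot), function(i)
      mean(sample(valuesA, nA, replace = TRUE)) -
      mean(sample(valuesB, n - nA, replace = TRUE)), numeric(1))
    stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  })
  list(p = p, observed = obs_diff, exact = exact, nPerm = nPerm_used,
       ci = ci, seed = as.integer(seed))
}

#' Bonferroni significance flags for HMM parameter families
#'
#' Applies the family-specific Bonferroni factor — 4 for state occupancies
#' and rates, 16 for the transition probabilities of a 4-state model —
#' and flags significance at the 0.05 / 0.01 / 0.001 tiers.
#'
#' @param pValues raw p-values in (0, 1].
#' @param family \code{"occupancy_lambda"} (factor 4) or
#'   \code{"transitions"} (factor 16); alternatively supply
#'   \code{factor} directly.
#' @param factor explicit correction factor (overrides \code{family}).
#' @return data.frame with columns \code{p}, \code{pCorrected},
#'   \code{stars} ("", "*", "**", "***") and \code{significant}
#'   (at 0.05).
#' @export
bonferroniFlags <- function(pValues,
                            family = c("occupancy_lambda", "transitions"),
                            factor = NULL) {
  .stop_if(any(pValues <= 0) || any(pValues > 1),
           "p-values must lie in (0, 1]")
  if (is.null(factor)) {
    family <- match.arg(family)
    factor <- c(occupancy_lambda = 4, transitions = 16)[[family]]
  }
  pc <- pmin(pValues * factor, 1)
  stars <- ifelse(pc < 0.001, "***",
           ifelse(pc < 0.01, "**", ifelse(pc < 0.05, "*", "")))
  data.frame(p = pValues, pCorrected = pc, stars = stars,
             significant = pc < 0.05)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), via
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pValues raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(pValues) {
  .stop_if(any(pValues <= 0) || any(pValues > 1),
           "p-values must lie in (0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Paired Wilcoxon signed-rank test (day vs night)
#'
#' Two-sided signed-rank test on paired per-fish values; zero differences
#' are dropped.  Exact for 25 or fewer non-zero differences (without
#' ties), normal approximation above.
#'
#' @param dayValues,nightValues paired numeric vectors (one pair per
#'   fish).
#' @return List with \code{statistic} (V), \code{p}, \code{n} (non-zero
#'   pairs).
#' @export
pairedWilcoxon <- function(dayValues, nightValues) {
  .stop_if(length(dayValues) != length(nightValues),
           "values must be paired per fish")
  d <- dayValues - nightValues
  keep <- d != 0
  if (!any(keep)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n = 0L))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(dayValues[keep], nightValues[keep],
                       paired = TRUE, exact = sum(keep) <= 25,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = sum(keep))
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test on group values.  Degenerate input
#' (zero variance in both groups with equal means) returns p = 1.
#'
#' @param valuesA,valuesB numeric group values (>= 2 each).
#' @return List with \code{statistic}, \code{p}, \code{df}.
#' @export
groupTtest <- function(valuesA, valuesB) {
  .stop_if(length(valuesA) < 2L || length(valuesB) < 2L,
           "each group needs at least 2 values")
  if (stats::sd(valuesA) == 0 && stats::sd(valuesB) == 0) {
    if (mean(valuesA) == mean(valuesB))
      return(list(statistic = 0, p = 1, df = NA_real_))
    return(list(statistic = Inf * sign(mean(valuesA) - mean(valuesB)),
                p = 0, df = NA_real_))
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Arcsine square-root transform of a fraction
#'
#' Variance-stabilizing transform \code{asin(sqrt(f))} for response
#' fractions.
#'
#' @param f fraction(s) in [0, 1].
#' @return Transformed value(s) in [0, pi/2].
#' @export
arcsineFraction <- function(f) {
  .stop_if(any(f < 0) || any(f > 1), "fractions must lie in [0, 1]")
  asin(sqrt(f))
}

#' Pearson correlation and fit to the identity line
#'
#' Pearson r and p for paired values, plus the mean signed deviation
#' \code{y - x} summarizing departure from the line y = x.
#'
#' @param x,y paired numeric vectors (>= 3 points).
#' @return List with \code{r}, \code{p}, \code{meanDeviation}; \code{r}
#'   and \code{p} are NA when either vector is constant.
#' @export
pearsonIdentityFit <- function(x, y) {
  .stop_if(length(x) != length(y), "x and y must be paired")
  .stop_if(length(x) < 3L, "need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_,
                meanDeviation = mean(y - x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       meanDeviation = mean(y - x))
}
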