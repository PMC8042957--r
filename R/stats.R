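# Modality-agreement statistics: two-sided paired t-tests and Pearson
# correlations, computable either from raw paired BIC values or directly
# from printed summary statistics (mean difference with SD, or r with n),
# so published tables can be reproduced without the raw specimen data.
# Table-style rounding is half-away-from-zero to 2 decimals; full-precision
# values are always retained alongside.

#' Two-sided p-value for a Pearson coefficient via the t transform
#'
#' Computes \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} and the two-sided
#' tail probability of Student's t with \code{n - 2} degrees of freedom --
#' the standard significance test for a Pearson correlation, usable from a
#' printed (r, n) pair alone.
#'
#' @param r Pearson coefficient with |r| <= 1. For |r| = 1 the limiting
#'   p-value 0 is returned with a warning.
#' @param n Sample size (>= 3).
#' @return Named list: \code{r}, \code{n}, \code{df}, \code{t_stat},
#'   \code{p_value}, \code{p_value_2dp} (half-away-from-zero rounding).
#' @examples
#' pearsonPFromR(0.74, 6)$p_value_2dp  # 0.09
#' pearsonPFromR(0.84, 6)$p_value_2dp  # 0.04
#' @export
pearsonPFromR <- function(r, n) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1) {
    stop("r must be a single value with |r| <= 1")
  }
  if (n < 3) stop("n must be >= 3 for a correlation test")
  df <- n - 2
  if (abs(r) == 1) {
    warning("|r| = 1: reporting the limiting p-value 0")
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, n = n, df = df, t_stat = t, p_value = p,
       p_value_2dp = .roundHalfAway(p, 2L))
}

#' Pearson correlation of paired measurements
#'
#' Sample Pearson coefficient from the covariance/variance definition,
#' with its two-sided p-value via \code{\link{pearsonPFromR}} and a
#' strength label via \code{\link{classifyStrength}}.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return Named list: \code{n}, \code{r}, \code{t_stat}, \code{p_value},
#'   \code{p_value_2dp}, \code{strength}.
#' @examples
#' pearsonFromPairs(1:6, c(2, 4, 5, 8, 9, 12))
#' @export
pearsonFromPairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) {
    stop("undefined correlation: zero variance in one of the variables")
  }
  r <- sum((x - mx) * (y - my)) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  pr <- pearsonPFromR(r, n)
  c(list(n = n), pr[c("r", "t_stat", "p_value", "p_value_2dp")],
    list(strength = classifyStrength(r)))
}

#' Paired t-test from paired-difference summary statistics
#'
#' The paired t statistic from the printed mean and SD of the paired
#' differences: \code{t = mean_diff / (sd_diff / sqrt(n))}, with the
#' two-sided tail of Student's t on \code{n - 1} degrees of freedom.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample SD (n - 1 denominator) of the differences; > 0.
#' @param n Number of pairs (>= 2).
#' @return Named list: \code{n}, \code{mean_diff}, \code{sd_diff},
#'   \code{t_stat}, \code{p_value}, \code{p_value_2dp}.
#' @examples
#' pairedTFromSummary(5.07, 9.44, 6)$p_value_2dp  # 0.25
#' @export
pairedTFromSummary <- function(mean_diff, sd_diff, n) {
  if (n < 2) stop("n must be >= 2")
  if (!is.numeric(sd_diff) || sd_diff <= 0) {
    stop("sd_diff must be positive (zero-variance differences are degenerate)")
  }
  t <- mean_diff / (sd_diff / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  list(n = n, mean_diff = mean_diff, sd_diff = sd_diff, t_stat = t,
       p_value = p, p_value_2dp = .roundHalfAway(p, 2L))
}

#' Paired t-test from raw paired measurements
#'
#' Forms the differences \code{x - y} and delegates to
#' \code{\link{pairedTFromSummary}}; also reports the per-method means and
#' SDs (sample SD, n - 1 denominator).
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return As \code{\link{pairedTFromSummary}}, plus \code{mean_a},
#'   \code{sd_a}, \code{mean_b}, \code{sd_b}.
#' @export
pairedTFromPairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need n >= 2 pairs")
  d <- x - y
  out <- if (stats::sd(d) == 0 && mean(d) == 0) {
    # identical pairs: every difference is zero, no evidence of a shift
    list(n = n, mean_diff = 0, sd_diff = 0, t_stat = 0, p_value = 1,
         p_value_2dp = 1)
  } else {
    pairedTFromSummary(mean(d), stats::sd(d), n)
  }
  c(out, list(mean_a = mean(x), sd_a = stats::sd(x),
              mean_b = mean(y), sd_b = stats::sd(y)))
}

#' Label the strength of a correlation coefficient
#'
#' Coefficients are labeled by magnitude: |r| < 0.40 weak,
#' 0.40 <= |r| < 0.70 moderate, |r| >= 0.70 strong. These cut-offs are
#' consistent with the conventional strong/moderate/weak wording for
#' r = 0.74/0.84/0.81/0.71 (strong), 0.46/0.41 (moderate) and 0.30 (weak).
#'
#' @param r Coefficient with |r| <= 1.
#' @return "weak", "moderate" or "strong".
#' @examples
#' classifyStrength(0.46)
#' @export
classifyStrength <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1) {
    stop("r must be a single value with |r| <= 1")
  }
  a <- abs(r)
  if (a < 0.40) "weak" else if (a < 0.70) "moderate" else "strong"
}

#' Build a per-group modality-agreement table
#'
#' For each named group of paired BIC values (e.g. histology vs micro-CT
#' per specimen), computes n, per-method mean and SD, mean and SD of the
#' paired differences, the Pearson correlation with its two-sided p, and
#' the paired t-test p -- one row per group, in the layout of a published
#' method-comparison table.
#'
#' @param groups Named list; each element a list (or data.frame) with
#'   numeric components \code{a} (reference method, e.g. histology) and
#'   \code{b} (comparison method, e.g. micro-CT) of equal length.
#' @return data.frame with one row per group: group, n, mean_a, sd_a,
#'   mean_b, sd_b, mean_diff, sd_diff, r, r_p, r_p_2dp, strength, t_p,
#'   t_p_2dp.
#' @examples
#' g <- list(ideal = list(a = c(60, 65, 70, 62, 68, 64),
#'                        b = c(60, 65, 70, 62, 68, 64)))
#' buildAgreementTable(g)
#' @export
buildAgreementTable <- function(groups) {
  if (!length(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a non-empty named list")
  }
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    a <- g$a; b <- g$b
    if (length(a) != length(b)) {
      stop("group '", nm, "': paired value lists differ in length")
    }
    tt <- pairedTFromPairs(a, b)
    rr <- tryCatch(pearsonFromPairs(a, b), error = function(e) {
      stop("group '", nm, "': ", conditionMessage(e))
    })
    data.frame(group = nm, n = tt$n,
               mean_a = tt$mean_a, sd_a = tt$sd_a,
               mean_b = tt$mean_b, sd_b = tt$sd_b,
               mean_diff = tt$mean_diff, sd_diff = tt$sd_diff,
               r = rr$r, r_p = rr$p_value, r_p_2dp = rr$p_value_2dp,
               strength = rr$strength,
               t_p = tt$p_value, t_p_2dp = tt$p_value_2dp)
  })
  do.call(rbind, rows)
}
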