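# Angle-level statistics on pair databases: descriptive summaries per
# position x sensor x snapshot role, and a paired Wilcoxon signed-rank test
# per sensor on the guided-minus-unguided angle differences. The signed-rank
# test is implemented with an exact small-sample path (distribution of the
# positive-rank sum over all sign assignments, computed by convolution, which
# stays exact in the presence of tied |differences| through midranks) and a
# tie- and continuity-corrected normal approximation for larger samples.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of zero median for paired differences. Zero differences are
#' discarded (the classical signed-rank treatment); `|differences|` are
#' midranked; the statistic is `W`, the sum of ranks of positive differences.
#' For `n_eff <= exact_limit` the p-value is exact: the null distribution of
#' `W` over all `2^n_eff` equiprobable sign assignments is computed by
#' convolving the rank generating polynomial (midranks are half-integers, so
#' doubled ranks are convolved on an integer grid). Larger samples use the
#' normal approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x Numeric vector of differences, or first member of the pairs.
#' @param y Optional second member; when given the test uses `x - y`.
#' @param exact_limit Largest effective sample size for the exact path
#'   (default 25).
#' @param zero_method Only `"discard"` is implemented; the argument exists so
#'   a Pratt-style treatment can slot in.
#' @return List of class `wilcoxon_sr`: `statistic` (W), `p_value`, `n_eff`
#'   (non-zero differences), `method` (`"exact"` or `"normal"`), `ties`.
#'   If all differences are zero the test is degenerate: `p_value = 1` with a
#'   warning.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L,
                                 zero_method = c("discard")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (!all(is.finite(d))) stop("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; test is degenerate")
    return(structure(list(statistic = 0, p_value = 1, n_eff = 0L,
                          method = "degenerate", ties = FALSE),
                     class = "wilcoxon_sr"))
  }
  r <- rank(abs(d))                      # midranks
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= exact_limit) {
    probs <- signed_rank_null(r)         # P(W2 = w), w on doubled-rank grid
    w2 <- round(2 * W)
    lower <- sum(probs[seq_len(w2 + 1L)])            # P(W <= w)
    upper <- sum(probs[(w2 + 1L):length(probs)])     # P(W >= w)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)          # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(statistic = W, p_value = p, n_eff = n, method = method,
                 ties = ties),
            class = "wilcoxon_sr")
}

# Exact null pmf of 2*W (doubled positive-rank sum) for midranks r: the
# coefficients of prod_i (1 + x^(2 r_i)) / 2^n, by iterated convolution.
signed_rank_null <- function(r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  probs <- numeric(total + 1L)
  probs[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), probs[seq_len(total + 1L - ri)])
    probs <- (probs + shifted) / 2
  }
  probs
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n_eff = %d, p = %s\n",
              x$method, x$statistic, x$n_eff, format_p(x$p_value)))
  invisible(x)
}

# reporting convention: very small p-values are displayed as "< 1e-06";
# display only, the numeric p is never truncated
format_p <- function(p, eps = 1e-6) {
  ifelse(p < eps, paste0("< ", format(eps)), format(p, digits = 3))
}

#' Descriptive angle statistics per position, sensor and snapshot role
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum, maximum,
#' median and interquartile range of the tilt angles, split by position,
#' sensor (1 = lowest) and snapshot role (`t0` unguided / `t1` guided).
#' Quartiles use linear interpolation between closest order statistics
#' (type 7), matching the percentile convention used for cluster bundles.
#'
#' @param pairs A `posture_pairs` data.frame.
#' @return `data.frame`: `position`, `sensor`, `role`, `mean`, `sd`, `min`,
#'   `max`, `median`, `iqr` (degrees, full precision; round for display).
#' @export
descriptive_table <- function(pairs) {
  rows <- list()
  for (pos in intersect(POSITIONS, unique(as.character(pairs$position)))) {
    p <- pairs[pairs$position == pos, , drop = FALSE]
    for (sensor in 1:5) for (role in c("t0", "t1")) {
      a <- p[[paste0(role, "_angle_", sensor)]]
      q <- stats::quantile(a, c(0.25, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, sensor = sensor, role = role,
        mean = mean(a), sd = stats::sd(a), min = min(a), max = max(a),
        median = stats::median(a), iqr = q[2] - q[1])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sensor paired Wilcoxon tests on a pair database
#'
#' For each position present and each of the five sensors, tests whether the
#' median guided-minus-unguided angle change differs from zero
#' ([wilcoxon_signed_rank()], two-sided). No multiple-testing correction is
#' applied across sensors or positions; each test is reported marginally.
#'
#' @param pairs A `posture_pairs` data.frame.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param exact_limit Passed to [wilcoxon_signed_rank()].
#' @return `data.frame`: `position`, `sensor`, `n_eff`, `statistic`,
#'   `p_value`, `p_display` (truncated at the `1e-6` reporting threshold),
#'   `significant`.
#' @export
wilcoxon_per_sensor <- function(pairs, alpha = 0.05, exact_limit = 25L) {
  rows <- list()
  for (pos in intersect(POSITIONS, unique(as.character(pairs$position)))) {
    p <- pairs[pairs$position == pos, , drop = FALSE]
    for (sensor in 1:5) {
      d <- p[[paste0("t1_angle_", sensor)]] - p[[paste0("t0_angle_", sensor)]]
      wt <- if (all(d == 0)) {
        suppressWarnings(wilcoxon_signed_rank(d, exact_limit = exact_limit))
      } else wilcoxon_signed_rank(d, exact_limit = exact_limit)
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, sensor = sensor, n_eff = wt$n_eff,
        statistic = wt$statistic, p_value = wt$p_value,
        p_display = format_p(wt$p_value), significant = wt$p_value < alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
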