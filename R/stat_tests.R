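#' Two-sample Kolmogorov-Smirnov statistic and p-value
#'
#' Computes the exact supremum distance `D` between the empirical cumulative
#' distribution functions of the two groups, evaluated at every jump point of
#' the pooled sample, and a two-sided p-value from the asymptotic Kolmogorov
#' distribution
#' \deqn{p = 2 \sum_{j \ge 1} (-1)^{j-1} e^{-2 j^2 \lambda^2}.}
#' Because `D` lives on a finite lattice, evaluating the asymptotic
#' distribution exactly at the achieved `D` is systematically conservative at
#' finite sample sizes; by default a continuity correction of a quarter of the
#' combined lattice step is applied,
#' \eqn{\lambda = (D + (1/m + 1/n)/4)\sqrt{mn/(m+n)}}, which restores
#' near-uniform null p-values at per-position coverages typical of this
#' application. `correction = FALSE` uses the plain
#' \eqn{\lambda = D \sqrt{mn/(m+n)}}. The p-value is also returned on the log
#' scale so that extremely significant sites remain ordered after the double
#' underflows.
#'
#' @param x,y Numeric vectors of (normalized) signals for the two groups.
#' @param correction Apply the continuity correction (default TRUE).
#' @return List with `statistic` (D), `p.value`, `log.p.value`, `m`, `n`.
#' @examples
#' ks_statistic(c(1, 2, 3), c(1.5, 2.5))$statistic # 1/3
#' @export
ks_statistic <- function(x, y, correction = TRUE) {
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) abort("undefined test: both groups must be non-empty")
  D <- ks_D(x, y)
  lp <- ks_log_p(D, m, n, correction = correction)
  list(statistic = D, p.value = exp(lp), log.p.value = lp, m = m, n = n)
}

ks_D <- function(x, y) {
  m <- length(x); n <- length(y)
  w <- c(x, y)
  o <- order(w)
  # integer arithmetic: m*n*(F1 - F2) steps by +n for group-1 points and -m
  # for group-2 points, so D is exact
  z <- cumsum(ifelse(o <= m, n, -m))
  ws <- w[o]
  # the sup of |F1 - F2| over step functions is attained immediately after a
  # jump; with ties, only the state after processing all tied values counts
  keep <- c(diff(ws) != 0, TRUE)
  max(abs(z[keep])) / (m * n)
}

ks_log_p <- function(D, m, n, correction = TRUE) {
  ne <- sqrt(m * n / (m + n))
  lam <- if (correction) (D + 0.25 * (1 / m + 1 / n)) * ne else D * ne
  if (lam < 1e-3) return(0) # p = 1
  if (lam > 3) {
    # one-term tail; the next term is exp(-16 lam^2) relative, negligible
    return(log(2) - 2 * lam^2)
  }
  j <- 1:200
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  p <- min(max(p, 1e-300), 1)
  log(p)
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided rank-sum test with tie correction and continuity correction,
#' matching `stats::wilcox.test(exact = FALSE, correct = TRUE)`, with the
#' p-value additionally returned on the log scale.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `statistic` (W, as in `wilcox.test`), `p.value`,
#'   `log.p.value`.
#' @export
u_test <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) abort("undefined test: both groups must be non-empty")
  w <- c(x, y)
  r <- rank(w)
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  nt <- rle(sort(w))$lengths # tie group sizes
  sigma2 <- (m * n / 12) * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
  if (sigma2 <= 0) {
    warn("all values tied in u_test; p = 1")
    return(list(statistic = W, p.value = 1, log.p.value = 0))
  }
  z <- W - m * n / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  lp <- min(log(2) + pnorm(-abs(z), log.p = TRUE), 0)
  list(statistic = W, p.value = exp(lp), log.p.value = lp)
}

#' Student's t test (pooled variance)
#'
#' Two-sided equal-variance t test, matching
#' `stats::t.test(var.equal = TRUE)`, with the p-value additionally returned
#' on the log scale. A zero pooled variance yields p = 1 with a warning.
#'
#' @param x,y Numeric vectors for the two groups (each length >= 2).
#' @return List with `statistic` (t), `df`, `p.value`, `log.p.value`.
#' @export
t_test <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) abort("t test needs at least 2 values per group")
  sp2 <- ((m - 1) * stats::var(x) + (n - 1) * stats::var(y)) / (m + n - 2)
  df <- m + n - 2
  if (sp2 <= 0) {
    warn("zero pooled variance in t_test; p = 1")
    return(list(statistic = 0, df = df, p.value = 1, log.p.value = 0))
  }
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / m + 1 / n))
  lp <- min(log(2) + pt(-abs(tt), df, log.p = TRUE), 0)
  list(statistic = tt, df = df, p.value = exp(lp), log.p.value = lp)
}

#' Score pooled positions with a per-base two-group test
#'
#' Adds per-position single-base test results to a pooled site table:
#' `D` (KS statistic, `NA` for other tests), `p_single` and `log_p_single`.
#'
#' @param sites Pooled (and typically coverage-filtered) site table from
#'   [pool_position_signals()].
#' @param test `"ks"` (default), `"u"` or `"t"`.
#' @param ks_correction Apply the lattice continuity correction in the KS p-value.
#' @return `sites` with scoring columns added.
#' @export
score_sites <- function(sites, test = c("ks", "u", "t"), ks_correction = TRUE) {
  test <- match.arg(test)
  ns <- nrow(sites)
  D <- rep(NA_real_, ns)
  lp <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    x <- sites$signals1[[i]]; y <- sites$signals2[[i]]
    if (length(x) == 0L || length(y) == 0L) next
    if (test == "ks") {
      D[i] <- ks_D(x, y)
      lp[i] <- ks_log_p(D[i], length(x), length(y), correction = ks_correction)
    } else if (test == "u") {
      lp[i] <- u_test(x, y)$log.p.value
    } else {
      lp[i] <- if (length(x) > 1L && length(y) > 1L) t_test(x, y)$log.p.value else NA_real_
    }
  }
  sites$D <- D
  sites$log_p_single <- lp
  sites$p_single <- exp(lp)
  sites
}
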