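#' Weighted Stouffer combination of a window of p-values
#'
#' Combines the p-values of a center position and its neighbors into
#' \deqn{Z = \frac{\sum_i w_i \Phi^{-1}(1 - p_i)}{\sqrt{\sum_i w_i^2}}}
#' with the combined p-value the upper-tail standard normal probability of
#' `Z`. Z is invariant to positive rescaling of the weights. Input p-values of
#' exactly 0 or 1 are clamped into the open unit interval with a warning
#' (lower bound 1e-300); pass log-scale p-values via `log.p = TRUE` to retain
#' resolution far beyond double underflow.
#'
#' @param p Numeric vector of p-values for the window (center plus neighbors),
#'   or their logarithms when `log.p = TRUE`.
#' @param weights Positive weights, one per entry of `p` (default: equal).
#' @param log.p Are `p` given on the log scale?
#' @return List with `Z`, `p.value`, `log.p.value`.
#' @examples
#' combine_stouffer(c(0.5, 0.5, 0.01, 0.5, 0.5),
#'                  weights = c(0.25, 0.5, 1, 0.5, 0.25))
#' @export
combine_stouffer <- function(p, weights = NULL, log.p = FALSE) {
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p)) abort("`weights` must match `p` in length")
  if (any(weights <= 0)) abort("`weights` must be positive")
  lp <- clamp_log_p(p, log.p)
  zq <- -qnorm(lp, log.p = TRUE) # Phi^{-1}(1 - p)
  Z <- sum(weights * zq) / sqrt(sum(weights^2))
  lpc <- pnorm(Z, lower.tail = FALSE, log.p = TRUE)
  list(Z = Z, p.value = exp(lpc), log.p.value = lpc)
}

#' Fisher combination of a window of p-values
#'
#' Combines p-values via \eqn{\chi^2 = -2 \sum_i \ln p_i} on `2 k` degrees of
#' freedom, where `k` is the window size.
#'
#' @inheritParams combine_stouffer
#' @return List with `statistic` (chi-squared), `df`, `p.value`,
#'   `log.p.value`.
#' @export
combine_fisher <- function(p, log.p = FALSE) {
  lp <- clamp_log_p(p, log.p)
  X <- -2 * sum(lp)
  df <- 2 * length(lp)
  lpc <- pchisq(X, df = df, lower.tail = FALSE, log.p = TRUE)
  list(statistic = X, df = df, p.value = exp(lpc), log.p.value = lpc)
}

clamp_log_p <- function(p, log.p) {
  eps <- 1e-300
  if (log.p) {
    if (any(p > 0, na.rm = TRUE)) abort("log p-values must be <= 0")
    return(pmax(pmin(p, log(1 - 1e-16)), log(eps)))
  }
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p <= 0 | p >= 1)) {
    warn("p-values of 0 or 1 clamped into the open unit interval")
    p <- pmin(pmax(p, eps), 1 - 1e-16)
  }
  log(p)
}

neighbor_weight <- function(offset, scheme = c("exp2", "linear", "uniform")) {
  scheme <- match.arg(scheme)
  d <- abs(offset)
  switch(scheme,
    exp2 = 1 / 2^d,
    linear = 1 / (d + 1),
    uniform = rep(1, length(d))
  )
}

#' Combine single-base p-values over neighboring positions
#'
#' For every scored position, combines its p-value with those of the scored
#' positions within `k` bases on each side (the window is truncated at
#' sequence ends or at filtered-out positions). Stouffer weights decay with
#' distance from the center according to `weight_scheme`: `"exp2"` (default)
#' uses \eqn{w = 1/2^{|d|}}, `"linear"` uses \eqn{w = 1/(|d|+1)}, `"uniform"`
#' uses equal weights. Combination is done on the log scale throughout.
#'
#' @param scored Site table from [score_sites()].
#' @param method `"stouffer"` (default), `"fisher"` or `"none"` (the combined
#'   p-value is the single-base p-value).
#' @param k Neighbor half-window in bases (default 2).
#' @param weight_scheme Weight decay for Stouffer (ignored otherwise).
#' @return `scored` with columns `Z`, `p_combined`, `log_p_combined` added.
#' @export
combine_neighbor_pvalues <- function(scored,
                                     method = c("stouffer", "fisher", "none"),
                                     k = 2,
                                     weight_scheme = c("exp2", "linear", "uniform")) {
  method <- match.arg(method)
  weight_scheme <- match.arg(weight_scheme)
  lp <- pmax(pmin(scored$log_p_single, log(1 - 1e-16)), log(1e-300))

  if (method == "none") {
    scored$Z <- NA_real_
    scored$log_p_combined <- scored$log_p_single
    scored$p_combined <- scored$p_single
    return(scored)
  }

  pos <- scored$ref_position
  ns <- length(pos)
  if (method == "stouffer") {
    zq <- -qnorm(lp, log.p = TRUE)
    num <- rep(0, ns); den <- rep(0, ns)
    for (off in seq(-k, k)) {
      w <- neighbor_weight(off, weight_scheme)
      idx <- match(pos + off, pos)
      ok <- !is.na(idx) & !is.na(zq[ifelse(is.na(idx), 1L, idx)])
      num[ok] <- num[ok] + w * zq[idx[ok]]
      den[ok] <- den[ok] + w^2
    }
    Z <- num / sqrt(den)
    scored$Z <- Z
    scored$log_p_combined <- pnorm(Z, lower.tail = FALSE, log.p = TRUE)
  } else {
    X <- rep(0, ns); df <- rep(0L, ns)
    for (off in seq(-k, k)) {
      idx <- match(pos + off, pos)
      ok <- !is.na(idx) & !is.na(lp[ifelse(is.na(idx), 1L, idx)])
      X[ok] <- X[ok] - 2 * lp[idx[ok]]
      df[ok] <- df[ok] + 2L
    }
    scored$Z <- NA_real_
    scored$log_p_combined <- pchisq(X, df = df, lower.tail = FALSE, log.p = TRUE)
  }
  scored$p_combined <- exp(scored$log_p_combined)
  scored
}
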