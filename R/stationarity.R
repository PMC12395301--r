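## Augmented Dickey-Fuller unit-root test with a constant term, used to
## verify that an RMSD series has reached a stationary state. The null
## hypothesis is a unit root (non-stationary); small p-values reject it.
## P-values are interpolated from the standard finite-sample quantile table
## of the tau_mu statistic (constant, no trend).

# rows: sample sizes; columns: P(tau <= cv) = 0.01,...,0.99
adf_tau_mu_table <- local({
  tab <- rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60))
  rownames(tab) <- c(25, 50, 100, 250, 500, 1e5)
  colnames(tab) <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  tab
})

#' Augmented Dickey-Fuller stationarity test
#'
#' Fits \code{diff(y)_t = a + rho * y_(t-1) + sum phi_i diff(y)_(t-i)} and
#' tests \code{rho = 0} (unit root) against \code{rho < 0} (stationary
#' around a constant). The p-value is interpolated from the tau_mu quantile
#' table at the series' sample size; \code{stationary} is \code{p < 0.05}.
#' A constant series is reported as stationary with \code{degenerate = TRUE}.
#'
#' @param series Numeric series of length >= 20.
#' @param lags Number of augmenting lag differences; default
#'   \code{trunc((length - 1)^(1/3))}.
#' @return List: \code{statistic}, \code{p_value}, \code{stationary},
#'   \code{lags}, \code{degenerate}.
#' @export
stationarity_test <- function(series, lags = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 20) stop("series must have at least 20 observations", call. = FALSE)
  if (stats::sd(series) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, stationary = TRUE,
                lags = 0L, degenerate = TRUE))
  }
  if (is.null(lags)) lags <- trunc((n - 1)^(1 / 3))
  lags <- as.integer(lags)
  dy <- diff(series)
  k <- lags + 1L
  m <- length(dy)
  yl <- series[k:(n - 1L)]            # y_{t-1}
  dyt <- dy[k:m]                      # response
  if (lags > 0) {
    Xlag <- sapply(seq_len(lags), function(i) dy[(k - i):(m - i)])
    fit <- stats::lm(dyt ~ yl + Xlag)
  } else {
    fit <- stats::lm(dyt ~ yl)
  }
  stat <- stats::coef(summary(fit))["yl", "t value"]
  tab <- adf_tau_mu_table
  sizes <- as.numeric(rownames(tab))
  probs <- as.numeric(colnames(tab))
  cv <- vapply(seq_along(probs), function(jc)
    stats::approx(sizes, tab[, jc], xout = n, rule = 2)$y, numeric(1))
  p <- stats::approx(cv, probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, stationary = p < 0.05,
       lags = lags, degenerate = FALSE)
}
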