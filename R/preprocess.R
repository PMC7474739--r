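#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), so the filter's group delay cancels and phase
#' relations between nodes — which the causality estimator depends on — are
#' not distorted in a direction-dependent way. Output length is preserved.
#'
#' @param ts A `source_ts` (nodes x samples) or plain matrix.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs Sampling rate; taken from the `source_ts` attribute if absent.
#' @return Filtered object of the same shape and class.
#' @export
bandpass_filter <- function(ts, low = 1, high = 60, fs = attr(ts, "sampling_rate")) {
  if (is.null(fs)) stop("sampling rate not supplied and not an attribute of `ts`")
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("band upper edge must be below the Nyquist frequency fs/2")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(ts, 1L, function(row) signal::filtfilt(bf, row)))
  attributes(out) <- attributes(ts)
  out
}

#' Baseline correction
#'
#' Subtracts, per node, the mean over the baseline window (by default the
#' first `baseline_n` samples of the trial) so that each node's baseline
#' mean is zero afterwards. Idempotent.
#'
#' @param ts A `source_ts` or nodes x samples matrix.
#' @param baseline_n Number of leading samples forming the baseline window;
#'   defaults to the `source_ts` attribute.
#' @return Corrected object of the same shape and class.
#' @export
baseline_correct <- function(ts, baseline_n = attr(ts, "baseline_n")) {
  if (is.null(baseline_n) || baseline_n < 1 || baseline_n > ncol(ts)) {
    stop("baseline window must be a non-empty leading segment of the trial")
  }
  mu <- rowMeans(ts[, seq_len(baseline_n), drop = FALSE])
  out <- ts - mu
  attributes(out) <- attributes(ts)
  out
}

#' Remove per-node linear trend and mean from a window
#'
#' Least-squares removal of an intercept-plus-slope fit from each column.
#' Applying it twice equals applying it once (projection).
#'
#' @param w Window matrix, samples x nodes, at least 3 rows.
#' @return Detrended matrix of the same dimensions.
#' @export
detrend_demean <- function(w) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (n < 3L) stop("window must have at least 3 samples")
  t0 <- seq_len(n) - (n + 1) / 2               # centered time, orthogonal to intercept
  slope <- crossprod(t0, w) / sum(t0 * t0)
  out <- sweep(w, 2L, colMeans(w)) - outer(t0, drop(slope))
  dimnames(out) <- dimnames(w)
  out
}

## --- unit-root / stationarity tests -------------------------------------
## No unit-root testing package is available in this toolchain, so both
## tests are implemented directly from their defining regressions, with the
## standard published critical values at the 5% level.

## 5% critical values of the Dickey-Fuller tau statistic (constant, no
## trend), interpolated in 1/n between tabulated sample sizes.
adf_cv_5pct <- function(n) {
  ns <- c(25, 50, 100, 250, 500, 1e9)
  cv <- c(-3.00, -2.93, -2.89, -2.88, -2.87, -2.86)
  stats::approx(1 / ns, cv, xout = 1 / max(n, 25), rule = 2)$y
}

#' Augmented Dickey-Fuller test (constant, fixed lag)
#'
#' Regresses the first difference on a constant, the lagged level, and
#' `lags` lagged differences; the t-statistic of the lagged level is
#' compared with the 5% Dickey-Fuller critical value. Rejection means
#' evidence *against* a unit root. A short fixed lag (default 1) is used
#' because automatic lag selection is unstable on 50-sample windows.
#'
#' @param y Numeric series.
#' @param lags Number of lagged differences in the test regression.
#' @return List with `statistic`, `cv` (5% critical value), `reject`, `n`.
#' @export
adf_test <- function(y, lags = 1L) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < lags + 10L) stop("series too short for the ADF regression")
  if (!all(is.finite(y))) stop("non-finite values in input")
  dy <- diff(y)
  idx <- (lags + 1L):(n - 1L)                  # rows of the test regression
  X <- cbind(1, y[idx])
  for (k in seq_len(lags)) X <- cbind(X, dy[idx - k])
  yy <- dy[idx]
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    return(list(statistic = 0, cv = adf_cv_5pct(n), reject = FALSE, n = n))
  }
  b <- solve(XtX, crossprod(X, yy))
  e <- yy - X %*% b
  s2 <- sum(e^2) / (length(yy) - ncol(X))
  se <- sqrt(s2 * solve(XtX)[2, 2])
  stat <- b[2] / se
  cv <- adf_cv_5pct(n)
  list(statistic = as.numeric(stat), cv = cv, reject = stat < cv, n = n)
}

#' KPSS test for level stationarity
#'
#' Computes the KPSS eta statistic from the partial sums of the demeaned
#' series with a Bartlett-window long-run variance (bandwidth
#' `floor(4 * (n/100)^(1/4))`), compared with the 5% critical value 0.463.
#' Rejection means evidence *against* stationarity.
#'
#' @param y Numeric series.
#' @return List with `statistic`, `cv`, `reject`, `n`, `bandwidth`.
#' @export
kpss_test <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10L) stop("series too short for the KPSS statistic")
  if (!all(is.finite(y))) stop("non-finite values in input")
  e <- y - mean(y)
  S <- cumsum(e)
  l <- floor(4 * (n / 100)^0.25)
  g0 <- sum(e^2) / n
  lrv <- g0
  for (j in seq_len(l)) {
    w <- 1 - j / (l + 1)
    lrv <- lrv + 2 * w * sum(e[(j + 1):n] * e[1:(n - j)]) / n
  }
  if (lrv <= 0) lrv <- g0
  stat <- if (lrv == 0) 0 else sum(S^2) / (n^2 * lrv)
  list(statistic = stat, cv = 0.463, reject = stat > 0.463, n = n, bandwidth = l)
}

#' Stationarity gate for an analysis window
#'
#' Each node passes when the ADF test rejects a unit root *and* the KPSS
#' test does not reject stationarity (`rule = "both"`, the conservative
#' conjunction of the two complementary nulls; `rule = "either"` accepts a
#' node when either test is favorable). The window passes overall only if
#' every node passes; failing windows are flagged for first-order
#' differencing. Windows shorter than 20 samples are reported as
#' insufficient and treated as non-stationary.
#'
#' @param w Window matrix, samples x nodes.
#' @param rule `"both"` (default) or `"either"`.
#' @return An object of class `stationarity_report`: per-node decisions,
#'   the overall `pass` flag, and `insufficient`.
#' @export
stationarity_gate <- function(w, rule = c("both", "either")) {
  rule <- match.arg(rule)
  w <- as.matrix(w)
  if (!all(is.finite(w))) stop("non-finite values in window")
  n <- nrow(w)
  nodes <- colnames(w) %||% paste0("node", seq_len(ncol(w)))
  if (n < 20L) {
    tab <- data.frame(node = nodes, adf_stat = NA_real_, adf_reject = FALSE,
                      kpss_stat = NA_real_, kpss_reject = TRUE, pass = FALSE)
    return(structure(list(table = tab, pass = FALSE, insufficient = TRUE,
                          rule = rule), class = "stationarity_report"))
  }
  rows <- lapply(seq_len(ncol(w)), function(j) {
    y <- w[, j]
    if (stats::sd(y) < 1e-12) {
      ## degenerate constant series: fails the gate by definition
      return(data.frame(node = nodes[j], adf_stat = 0, adf_reject = FALSE,
                        kpss_stat = 0, kpss_reject = TRUE, pass = FALSE))
    }
    a <- adf_test(y)
    k <- kpss_test(y)
    pass <- if (rule == "both") a$reject && !k$reject else a$reject || !k$reject
    data.frame(node = nodes[j], adf_stat = a$statistic, adf_reject = a$reject,
               kpss_stat = k$statistic, kpss_reject = k$reject, pass = pass)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, pass = all(tab$pass), insufficient = FALSE,
                 rule = rule), class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat(sprintf("<stationarity_report> overall %s (rule = %s)%s\n",
              if (x$pass) "PASS" else "FAIL", x$rule,
              if (x$insufficient) " [insufficient samples]" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' First-order difference of a window
#'
#' `out[t, ] = w[t + 1, ] - w[t, ]`; one sample shorter. Applied at most
#' once per window, only when the stationarity gate fails.
#'
#' @param w Window matrix, samples x nodes, at least 2 rows.
#' @return Differenced matrix with `nrow(w) - 1` rows.
#' @export
difference_once <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) < 2L) stop("window must have at least 2 samples to difference")
  diff(w)
}

#' Condition one analysis window for VAR fitting
#'
#' The fixed per-window protocol: detrend/demean, gate; if the gate fails,
#' difference once, detrend/demean again and re-gate. Windows that remain
#' non-stationary after one difference are retained with a warning flag;
#' windows that are degenerate (zero variance after conditioning) are
#' marked unusable.
#'
#' @param w Window matrix, samples x nodes.
#' @param rule Gate rule passed to [stationarity_gate()].
#' @return List: `window` (conditioned matrix), `differenced`,
#'   `nonstationary` (still failing after differencing), `usable`,
#'   `report` (the final gate report).
#' @export
preprocess_window <- function(w, rule = "both") {
  w <- detrend_demean(w)
  rep1 <- stationarity_gate(w, rule = rule)
  differenced <- FALSE
  nonstationary <- FALSE
  report <- rep1
  if (!rep1$pass) {
    w <- detrend_demean(difference_once(w))
    differenced <- TRUE
    report <- stationarity_gate(w, rule = rule)
    nonstationary <- !report$pass
  }
  usable <- all(apply(w, 2L, stats::sd) > 1e-12)
  list(window = w, differenced = differenced, nonstationary = nonstationary,
       usable = usable, report = report)
}
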