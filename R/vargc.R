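#' Canonical EEG frequency bands
#'
#' Conventional band edges, with the gamma band capped at 60 Hz to match
#' the 1-60 Hz analysis bandpass. Band membership downstream is
#' half-open: a grid frequency belongs to a band when `low <= f < high`.
#'
#' @param theta,alpha,beta,gamma Numeric `c(low, high)` pairs in Hz.
#' @return Data frame with columns `band`, `low`, `high`; bands must be
#'   non-overlapping and ordered.
#' @export
frequency_bands <- function(theta = c(4, 8), alpha = c(8, 13),
                            beta = c(13, 30), gamma = c(30, 60)) {
  tab <- data.frame(band = c("theta", "alpha", "beta", "gamma"),
                    low = c(theta[1], alpha[1], beta[1], gamma[1]),
                    high = c(theta[2], alpha[2], beta[2], gamma[2]))
  if (any(tab$low >= tab$high)) stop("each band needs low < high")
  if (any(diff(as.vector(t(tab[, c("low", "high")]))) < 0)) {
    stop("bands must be ordered and non-overlapping")
  }
  tab
}

#' Default frequency grid
#'
#' `n` equally spaced frequencies in `(0, fs/2]` (the Nyquist interval),
#' on which transfer functions, spectra and causality are evaluated.
#'
#' @param fs Sampling rate in Hz.
#' @param n Number of grid points (default 128).
#' @return Numeric vector of frequencies in Hz.
#' @export
default_grid <- function(fs, n = 128L) {
  seq_len(n) * (fs / 2) / n
}

## lagged design matrix for a VAR(p): rows t = p+1..n, columns stacked by lag
lag_matrix <- function(w, p, from = p + 1L) {
  n <- nrow(w)
  X <- matrix(0, n - from + 1L, ncol(w) * p)
  for (k in seq_len(p)) {
    X[, (k - 1L) * ncol(w) + seq_len(ncol(w))] <- w[(from - k):(n - k), , drop = FALSE]
  }
  X
}

#' Fit a VAR(p) by least squares
#'
#' Multivariate regression of `x_t` on its `p` lags (no intercept; windows
#' are demeaned by the conditioning protocol). The residual covariance uses
#' the effective sample count minus the number of regressors per equation.
#'
#' @param w Window matrix, samples x nodes, conditioned (stationary, zero
#'   mean).
#' @param p Model order, `>= 1`.
#' @return An object of class `var_model`: coefficient array `A`
#'   (nodes x nodes x p, `A[i, j, k]` the effect of node j's k-th lag on
#'   node i), residual covariance `Sigma`, its ML variant `Sigma_ml`,
#'   `bic`, `loglik`, `spectral_radius`, `nobs`.
#' @export
fit_var <- function(w, p) {
  w <- as.matrix(w)
  d <- ncol(w)
  n <- nrow(w)
  stopifnot(p >= 1)
  N <- n - p
  k <- d * p
  if (N <= k) stop("insufficient samples for a VAR(", p, ") on ", d, " nodes")
  Y <- w[(p + 1L):n, , drop = FALSE]
  X <- lag_matrix(w, p)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    stop("singular regressor moment matrix; window is degenerate")
  }
  B <- solve(XtX, crossprod(X, Y))        # k x d
  E <- Y - X %*% B
  Sigma_ml <- crossprod(E) / N
  Sigma <- crossprod(E) / (N - k)
  A <- array(0, dim = c(d, d, p), dimnames = list(colnames(w), colnames(w), NULL))
  for (kk in seq_len(p)) A[, , kk] <- t(B[(kk - 1L) * d + seq_len(d), , drop = FALSE])
  det_s <- det(Sigma_ml)
  loglik <- -N / 2 * (d * log(2 * pi) + log(max(det_s, .Machine$double.xmin)) + d)
  bic <- log(max(det_s, .Machine$double.xmin)) + log(N) / N * (p * d^2)
  structure(list(p = as.integer(p), A = A, Sigma = Sigma, Sigma_ml = Sigma_ml,
                 nobs = N, loglik = loglik, bic = bic,
                 spectral_radius = companion_spectral_radius(A)),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> order %d, %d nodes, %d obs, BIC %.4f, spectral radius %.3f\n",
              x$p, dim(x$A)[1], x$nobs, x$bic, x$spectral_radius))
  invisible(x)
}

#' Select the VAR order by BIC
#'
#' Fits orders 1..`p_max` on the common sample (the window minus its first
#' `p_max` rows, so all candidates see the same observations) and returns
#' the BIC minimizer, with ties broken toward the smaller order. If the
#' window is too short for `p_max`, the candidate range is lowered with a
#' warning; if even order 1 cannot be fitted, `NA` is returned and the
#' window should be marked unusable.
#'
#' @param w Conditioned window matrix, samples x nodes.
#' @param p_max Largest candidate order.
#' @return Integer order, with the candidate BIC values as attribute
#'   `"bic"`; `NA_integer_` when no order is estimable.
#' @export
select_order_bic <- function(w, p_max = 3L) {
  w <- as.matrix(w)
  d <- ncol(w)
  n <- nrow(w)
  while (p_max >= 1L && (n - p_max) <= d * p_max + 1L) {
    p_max <- p_max - 1L
  }
  if (p_max < 1L) {
    warning("window too short for any VAR order; marking unusable")
    return(NA_integer_)
  }
  bics <- vapply(seq_len(p_max), function(p) {
    Y <- w[(p_max + 1L):n, , drop = FALSE]
    X <- lag_matrix(w, p, from = p_max + 1L)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) return(Inf)
    B <- solve(XtX, crossprod(X, Y))
    E <- Y - X %*% B
    N <- nrow(Y)
    log(max(det(crossprod(E) / N), .Machine$double.xmin)) + log(N) / N * (p * d^2)
  }, numeric(1))
  if (all(!is.finite(bics))) {
    warning("all candidate orders degenerate; marking window unusable")
    return(NA_integer_)
  }
  p <- which.min(bics)                 # which.min takes the first (smallest p) on ties
  attr(p, "bic") <- bics
  p
}

#' VAR transfer function on a frequency grid
#'
#' `H(omega) = (I - sum_k A_k exp(-i k omega))^(-1)`, the inverse of the
#' Fourier transform of the regression coefficients, evaluated at
#' `omega = 2 pi f / fs` for each grid frequency. Grid points where the
#' characteristic matrix is numerically singular are masked with a warning.
#'
#' @param model A [fit_var()] model.
#' @param freq_hz Frequency grid in Hz (default [default_grid()]).
#' @param fs Sampling rate in Hz.
#' @return An object of class `spectral_matrices` holding `H`
#'   (nodes x nodes x frequencies, complex), the grid, and a `masked` flag
#'   per frequency.
#' @export
transfer_function <- function(model, fs, freq_hz = default_grid(fs)) {
  stopifnot(inherits(model, "var_model"))
  d <- dim(model$A)[1]
  omega <- 2 * pi * freq_hz / fs
  nf <- length(omega)
  H <- array(NA_complex_, dim = c(d, d, nf))
  masked <- logical(nf)
  I <- diag(d)
  for (f in seq_len(nf)) {
    Af <- I + 0i
    for (k in seq_len(model$p)) {
      Af <- Af - model$A[, , k] * exp(-1i * k * omega[f])
    }
    if (rcond(Af) < 1e-12) {
      masked[f] <- TRUE
      next
    }
    H[, , f] <- solve(Af)
  }
  if (any(masked)) {
    warning(sum(masked), " grid frequencies masked (near-singular characteristic matrix)")
  }
  structure(list(freq_hz = freq_hz, omega = omega, H = H, S = NULL,
                 masked = masked, fs = fs),
            class = "spectral_matrices")
}

#' Cross-power spectral density from a VAR model
#'
#' `S(omega) = H(omega) Sigma H*(omega)`, the unique spectral factorization
#' implied by the VAR; Hermitian with a real nonnegative diagonal.
#'
#' @param model A [fit_var()] model.
#' @param fs Sampling rate in Hz.
#' @param freq_hz Frequency grid in Hz.
#' @param tf Optionally, a precomputed [transfer_function()] result.
#' @return The `spectral_matrices` object with the `S` slot filled.
#' @export
cpsd <- function(model, fs, freq_hz = default_grid(fs), tf = NULL) {
  if (is.null(tf)) tf <- transfer_function(model, fs, freq_hz)
  d <- dim(tf$H)[1]
  nf <- length(tf$freq_hz)
  S <- array(NA_complex_, dim = c(d, d, nf))
  for (f in seq_len(nf)) {
    if (tf$masked[f]) next
    Hf <- tf$H[, , f]
    Sf <- Hf %*% model$Sigma %*% Conj(t(Hf))
    S[, , f] <- (Sf + Conj(t(Sf))) / 2       # enforce Hermitian symmetry
  }
  tf$S <- S
  tf
}

## Core bivariate spectral GC evaluation at arbitrary omega (radians/sample).
## Columns of the model are (1, 2); returns f for both directions.
spectral_gc_core <- function(A, Sigma, omega) {
  p <- dim(A)[3]
  nf <- length(omega)
  ## closed-form 2x2 inversion vectorized over the grid
  a11 <- 1 - vapply(seq_len(nf), function(f) sum(A[1, 1, ] * exp(-1i * seq_len(p) * omega[f])), complex(1))
  a12 <- -vapply(seq_len(nf), function(f) sum(A[1, 2, ] * exp(-1i * seq_len(p) * omega[f])), complex(1))
  a21 <- -vapply(seq_len(nf), function(f) sum(A[2, 1, ] * exp(-1i * seq_len(p) * omega[f])), complex(1))
  a22 <- 1 - vapply(seq_len(nf), function(f) sum(A[2, 2, ] * exp(-1i * seq_len(p) * omega[f])), complex(1))
  det <- a11 * a22 - a12 * a21
  masked <- Mod(det) < 1e-12
  H11 <- a22 / det; H12 <- -a12 / det
  H21 <- -a21 / det; H22 <- a11 / det
  s11 <- Sigma[1, 1]; s22 <- Sigma[2, 2]; s12 <- Sigma[1, 2]
  ## partial covariances (instantaneous correlation removed)
  sig2_g1 <- s22 - s12^2 / s11      # var of node 2's innovation given node 1's
  sig1_g2 <- s11 - s12^2 / s22
  S11 <- Re(H11 * s11 * Conj(H11) + H11 * s12 * Conj(H12) +
              H12 * s12 * Conj(H11) + H12 * s22 * Conj(H12))
  S22 <- Re(H21 * s11 * Conj(H21) + H21 * s12 * Conj(H22) +
              H22 * s12 * Conj(H21) + H22 * s22 * Conj(H22))
  f21 <- -log(1 - sig2_g1 * Mod(H12)^2 / S11)   # node 2 -> node 1
  f12 <- -log(1 - sig1_g2 * Mod(H21)^2 / S22)   # node 1 -> node 2
  bad <- masked | S11 <= 0 | S22 <= 0
  f21[bad] <- NA_real_
  f12[bad] <- NA_real_
  list(f21 = f21, f12 = f12, masked = bad,
       partial = c(sig2_g1 = sig2_g1, sig1_g2 = sig1_g2))
}

clip_nonneg <- function(f, tol = 1e-10) {
  clipped <- sum(f < -tol, na.rm = TRUE)
  f[!is.na(f) & f < 0] <- 0
  list(f = f, clipped = clipped)
}

#' Spectral (Geweke) Granger causality for a node pair
#'
#' For a bivariate VAR model of the pair (X = column 1, Y = column 2),
#' computes the frequency-domain causality
#' `f_{Y->X}(omega) = -ln(1 - Sigma_{Y|X} |H_XY(omega)|^2 / S_XX(omega))`
#' with the partial covariance
#' `Sigma_{Y|X} = Sigma_YY - Sigma_YX Sigma_XX^{-1} Sigma_XY`, and likewise
#' for the reverse direction. Values below zero by no more than a 1e-10
#' tolerance are clipped to zero (finite-sample estimates can dip below 0);
#' clip counts are recorded. Grid points with a nonpositive spectrum or a
#' singular characteristic matrix are masked.
#'
#' @param model A bivariate [fit_var()] model.
#' @param fs Sampling rate in Hz.
#' @param freq_hz Frequency grid in Hz.
#' @return An object of class `spectral_gc`: the grid, a two-column matrix
#'   `f` (direction `2->1` then `1->2`, in nats), the partial covariances,
#'   masked flags and clip counts. `usable` is `FALSE` if every grid point
#'   is masked.
#' @export
spectral_gc_pair <- function(model, fs, freq_hz = default_grid(fs)) {
  stopifnot(inherits(model, "var_model"))
  if (dim(model$A)[1] != 2L) stop("spectral_gc_pair expects a bivariate model")
  omega <- 2 * pi * freq_hz / fs
  core <- spectral_gc_core(model$A, model$Sigma, omega)
  c21 <- clip_nonneg(core$f21)
  c12 <- clip_nonneg(core$f12)
  nodes <- dimnames(model$A)[[1]] %||% c("1", "2")
  f <- cbind(c21$f, c12$f)
  colnames(f) <- c(paste0(nodes[2], "->", nodes[1]), paste0(nodes[1], "->", nodes[2]))
  structure(list(freq_hz = freq_hz, omega = omega, f = f,
                 nodes = nodes, partial = core$partial,
                 masked = core$masked,
                 clipped = c(c21$clipped, c12$clipped),
                 usable = !all(core$masked)),
            class = "spectral_gc")
}

#' @export
print.spectral_gc <- function(x, ...) {
  cat(sprintf("<spectral_gc> pair (%s, %s), %d grid frequencies\n",
              x$nodes[1], x$nodes[2], length(x$freq_hz)))
  for (j in 1:2) {
    cat(sprintf("  %s: mean %.4f nats, max %.4f\n", colnames(x$f)[j],
                mean(x$f[, j], na.rm = TRUE), max(x$f[, j], na.rm = TRUE)))
  }
  invisible(x)
}

#' Band average of a spectral causality
#'
#' Arithmetic mean of `f` over grid frequencies in `[low, high)` Hz.
#'
#' @param sgc A [spectral_gc_pair()] result.
#' @param band Either a band name from [frequency_bands()] or a
#'   `c(low, high)` pair in Hz.
#' @param direction 1 for `2->1` (column order of `sgc$f`), 2 for `1->2`,
#'   or `NULL` for both.
#' @return Named numeric vector of band-averaged causality in nats.
#' @export
band_average <- function(sgc, band, direction = NULL) {
  stopifnot(inherits(sgc, "spectral_gc"))
  if (is.character(band)) {
    tab <- frequency_bands()
    row <- tab[tab$band == band, ]
    if (!nrow(row)) stop("unknown band name: ", band)
    band <- c(row$low, row$high)
  }
  sel <- sgc$freq_hz >= band[1] & sgc$freq_hz < band[2]
  if (!any(sel)) stop("frequency grid has no points in the requested band")
  cols <- direction %||% 1:2
  out <- colMeans(sgc$f[sel, cols, drop = FALSE], na.rm = TRUE)
  out
}

#' Time-domain Granger causality (restricted vs. full regression)
#'
#' The log ratio of the target's residual variance in a restricted model
#' (omitting the source's lags) over the full model. With
#' `conditional = TRUE` both models include the lags of every other column
#' of `w`, giving the conditional time-domain measure; otherwise the models
#' are bivariate in (target, source). Serves as the integral oracle for the
#' spectral measure: the mean of `f` over the full frequency grid matches
#' this value for a well-specified model.
#'
#' @param w Conditioned window matrix, samples x nodes, with named columns
#'   (or numeric indices used for `source`/`target`).
#' @param source,target Column names or indices.
#' @param p Full-model order.
#' @param p_restricted Order of the restricted model (defaults to `p`).
#' @param conditional Condition on the remaining columns of `w`.
#' @return Causality in nats (nonnegative up to sampling noise).
#' @export
time_domain_gc <- function(w, source, target, p, p_restricted = p,
                           conditional = FALSE) {
  w <- as.matrix(w)
  if (is.character(source)) source <- match(source, colnames(w))
  if (is.character(target)) target <- match(target, colnames(w))
  stopifnot(!is.na(source), !is.na(target), source != target)
  cols_full <- if (conditional) seq_len(ncol(w)) else c(target, source)
  wf <- w[, cols_full, drop = FALSE]
  tgt_pos <- match(target, cols_full)
  src_pos <- match(source, cols_full)
  n <- nrow(wf)
  from <- max(p, p_restricted) + 1L          # common estimation sample
  resid_var <- function(p_use, drop_source) {
    X <- lag_matrix(wf, p_use, from = from)
    if (drop_source) {
      drop_cols <- src_pos + (seq_len(p_use) - 1L) * ncol(wf)
      X <- X[, -drop_cols, drop = FALSE]
    }
    y <- wf[from:n, tgt_pos]
    keep <- col_vars(X) > 1e-24              # drop degenerate (constant-zero) regressors
    X <- X[, keep, drop = FALSE]
    if (!ncol(X)) return(stats::var(y) * (length(y) - 1) / length(y))
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) stop("singular regressor moment matrix; window is degenerate")
    b <- solve(XtX, crossprod(X, y))
    e <- y - X %*% b
    sum(e^2) / length(y)                     # ML variance on the common sample
  }
  log(resid_var(p_restricted, TRUE) / resid_var(p, FALSE))
}
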