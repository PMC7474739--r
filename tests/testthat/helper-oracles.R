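## independent oracles and small fixture builders used across the suite

## amplitude of a sinusoid at frequency f recovered by least squares
fit_sine_amplitude <- function(x, f, fs) {
  t <- seq_along(x) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

rand_digraph <- function(n, p) {
  adj <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(adj) <- 0L
  adj
}

## two-node montage used in many tests
pair_design2 <- function() trial_design(frontal = "F1", parietal = "P1")

## stationary bivariate series from an explicit coefficient array
simulate_var_local <- function(A, n, burn = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gcnet:::simulate_var(A, n, burn)
}

## canonical coupled VAR(1): x driven by y, unit innovations
coupled_var1 <- function() {
  A <- array(0, dim = c(2, 2, 1))
  A[1, 1, 1] <- 0.5
  A[1, 2, 1] <- 0.4
  A[2, 2, 1] <- 0.7
  A
}
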