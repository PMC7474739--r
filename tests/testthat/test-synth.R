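test_that("trial design enforces its structural invariants", {
  d <- trial_design()
  expect_equal(d$n_nodes, 13L)
  expect_equal(d$baseline_n + d$task_n, d$total_n)
  expect_equal(d$total_n, 5000L)
  expect_error(trial_design(frontal = c("A", "B"), parietal = c("B", "C")),
               "disjoint")
  expect_error(trial_design(phase_boundaries_ms = c(6000, 3000)),
               "strictly increasing")
  expect_error(trial_design(phase_boundaries_ms = c(3000, 9000)),
               "strictly increasing")
})

test_that("coefficient schedule places couplings exactly and only in their interval", {
  d <- pair_design2()
  ## no couplings: off-diagonals identically zero in every segment
  sch0 <- build_tv_var(d, coupling_scenario())
  for (seg in sch0$segments) {
    for (k in 1:2) {
      offd <- seg$A[, , k]
      diag(offd) <- 0
      expect_true(all(offd == 0))
    }
  }
  ## one coupling: entry is 0.4 inside [3000, 6000) ms of the task, 0 outside
  sch <- build_tv_var(d, coupling_scenario(
    coupling("F1", "P1", "theta", 3000, 6000, 0.4)))
  on_samples <- d$baseline_n + (3000 * 500 / 1000 + 1):(6000 * 500 / 1000)
  for (seg in sch$segments) {
    inside <- seg$from >= min(on_samples) && seg$to <= max(on_samples)
    expect_equal(seg$A["P1", "F1", 1], if (inside) 0.4 else 0)
    expect_equal(seg$A["P1", "F1", 2], 0)
    expect_equal(seg$A["F1", "P1", 1], 0)
  }
  ## segments tile the full trial
  froms <- vapply(sch$segments, `[[`, integer(1), "from")
  tos <- vapply(sch$segments, `[[`, integer(1), "to")
  expect_equal(min(froms), 1L)
  expect_equal(max(tos), d$total_n)
  expect_true(all(froms[-1] == tos[-length(tos)] + 1L))
})

test_that("oscillator blocks resonate at the scenario's center frequencies", {
  for (f0 in c(6, 40)) {
    ar <- oscillator_ar2(f0, 500, r = 0.9)
    comp <- rbind(ar, c(1, 0))
    ev <- eigen(comp, only.values = TRUE)$values
    ## oracle: eigendecomposition of the companion matrix
    expect_lt(abs(max(Arg(ev)) - 2 * pi * f0 / 500) / (2 * pi * f0 / 500), 0.05)
    expect_equal(max(Mod(ev)), 0.9, tolerance = 1e-10)
  }
})

test_that("unstable composite dynamics are rejected with an interval diagnostic", {
  d <- pair_design2()
  scen <- coupling_scenario(list(
    coupling("F1", "P1", "theta", 1000, 5000, 2.0),
    coupling("P1", "F1", "theta", 1000, 5000, 2.0)))
  expect_error(build_tv_var(d, scen), "unstable.*interval", ignore.case = TRUE)
  expect_error(build_tv_var(d, coupling_scenario(
    coupling("F1", "XX", "theta", 0, 1000, 0.1))), "unknown node")
})

test_that("trial simulation is seed-deterministic and handles degenerate noise", {
  d <- pair_design2()
  sch <- build_tv_var(d, coupling_scenario())
  t1 <- simulate_trial(sch, seed = 7)
  t2 <- simulate_trial(sch, seed = 7)
  expect_identical(unclass(t1), unclass(t2))
  t3 <- simulate_trial(sch, seed = 8)
  expect_false(identical(unclass(t1), unclass(t3)))
  expect_equal(dim(t1), c(2L, d$total_n))
  ## homogeneous system: zero innovations give the all-zero trial
  sch0 <- build_tv_var(d, coupling_scenario(noise_sd = 0))
  expect_true(all(simulate_trial(sch0, seed = 1) == 0))
})

test_that("narrowband tuning yields a theta spectral peak", {
  ## high-Q tuning: a genuine interior spectral maximum needs a pole
  ## modulus near 1; the peak is located on a trial-averaged periodogram
  d <- pair_design2()
  sch <- build_tv_var(d, coupling_scenario(osc_r = 0.96))
  spec_sum <- NULL
  for (i in 1:20) {
    tr <- simulate_trial(sch, seed = 4000 + i)
    sp <- stats::spec.pgram(stats::ts(as.numeric(tr[1, ]), frequency = 500),
                            taper = 0.1, plot = FALSE)
    spec_sum <- if (is.null(spec_sum)) sp$spec else spec_sum + sp$spec
  }
  peak_hz <- sp$freq[which.max(spec_sum)]
  expect_gte(peak_hz, 4)
  expect_lt(peak_hz, 8)
})

test_that("default cohort counts reproduce the retained-trial structure", {
  d <- trial_design(baseline_ms = 200, task_ms = 600,
                    phase_boundaries_ms = c(200, 400),
                    frontal = "F1", parietal = "P1")
  scen <- coupling_scenario()
  cohort <- generate_cohort(d, list(gifted = scen, control = scen),
                            master_seed = 1)
  expect_equal(cohort_trial_counts(cohort),
               c(gifted = 400L, control = 380L))
  expect_equal(length(cohort$groups$gifted$subjects), 20L)
  expect_equal(length(cohort$groups$control$subjects), 18L)
})

test_that("cohorts are reproducible from the master seed and reject bad counts", {
  d <- pair_design2()
  scen <- coupling_scenario()
  counts <- list(g = list(n_subjects = 2L, trials_per_subject = 2L))
  c1 <- generate_cohort(d, list(g = scen), counts, master_seed = 5)
  c2 <- generate_cohort(d, list(g = scen), counts, master_seed = 5)
  expect_identical(unclass(c1$groups$g$subjects$S01$trials[[1]]),
                   unclass(c2$groups$g$subjects$S01$trials[[1]]))
  expect_identical(unclass(c1$groups$g$subjects$S02$trials[[2]]),
                   unclass(c2$groups$g$subjects$S02$trials[[2]]))
  expect_error(generate_cohort(d, list(g = scen),
                               list(g = list(n_subjects = 0L, trials_per_subject = 2L))),
               "positive")
  expect_error(generate_cohort(d, list(g = scen),
                               list(g = list(n_subjects = 2L, trials_per_subject = -1))),
               "positive")
})

test_that("designed causality is recoverable and absent under the null", {
  d <- pair_design2()
  sch_c <- build_tv_var(d, coupling_scenario(
    coupling("F1", "P1", "theta", 0, 9000, 0.4)))
  sch_0 <- build_tv_var(d, coupling_scenario())
  fwd <- rev <- nfwd <- nrev <- numeric(100)
  for (i in 1:100) {
    tr <- simulate_trial(sch_c, seed = 900 + i)
    seg <- t(tr[, 1001:2000])          # 2 s stationary coupled segment
    seg <- sweep(seg, 2, colMeans(seg))
    fwd[i] <- time_domain_gc(seg, source = 1, target = 2, p = 2)
    rev[i] <- time_domain_gc(seg, source = 2, target = 1, p = 2)
    tr0 <- simulate_trial(sch_0, seed = 900 + i)
    seg0 <- sweep(t(tr0[, 1001:2000]), 2, colMeans(t(tr0[, 1001:2000])))
    nfwd[i] <- time_domain_gc(seg0, source = 1, target = 2, p = 2)
    nrev[i] <- time_domain_gc(seg0, source = 2, target = 1, p = 2)
  }
  expect_gte(mean(fwd > rev), 0.95)
  ## null fidelity: the two directions are exchangeable without coupling
  expect_gt(stats::wilcox.test(nfwd, nrev)$p.value, 0.01)
})

test_that("simulated trials are variance-stationary within phases", {
  d <- pair_design2()
  sch <- build_tv_var(d, coupling_scenario())
  tr <- simulate_trial(sch, seed = 77)
  task <- tr[1, (d$baseline_n + 1):d$total_n]
  bins <- split(task, rep(1:10, each = length(task) / 10))
  v <- vapply(bins, stats::var, numeric(1))
  expect_lt(max(v) / min(v), 3)
})

test_that("cohort round-trips through the on-disk format", {
  d <- pair_design2()
  scen <- coupling_scenario()
  cohort <- generate_cohort(d, list(g = scen),
                            list(g = list(n_subjects = 2L, trials_per_subject = 2L)),
                            master_seed = 3)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir, force = TRUE)
  back <- read_cohort(dir)
  expect_equal(cohort_trial_counts(back), cohort_trial_counts(cohort))
  expect_equal(as.vector(unclass(back$groups$g$subjects$S01$trials[[1]])),
               as.vector(unclass(cohort$groups$g$subjects$S01$trials[[1]])))
  unlink(dir, recursive = TRUE)
})
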