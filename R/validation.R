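## Simulation studies that probe the estimator and the detection pipeline
## under designed ground truth. These encapsulate the package's standard
## validation conditions; the defaults are the conditions themselves and
## are not meant to be tuned per run.

#' Group-effect scenarios for a two-group cohort
#'
#' The designed group contrast of the synthetic study: the `gifted` group
#' carries stronger theta-band frontal-to-parietal coupling during premise
#' integration and the early conclusion phase, and weaker coupling late in
#' the conclusion phase; the `control` group is the mirror image. Every
#' frontal node drives every parietal node (couplings are unidirectional
#' frontal-to-parietal, which keeps the composite VAR stable by
#' construction).
#'
#' @param design A [trial_design()].
#' @param integration_ms,late_ms Active intervals (ms, task time) of the
#'   two effects.
#' @param strong,weak Coupling strengths in the integration/early window
#'   for the gifted and control groups. The defaults (0.3 vs. 0.05) sit in
#'   the sensitive range of the short-window causality estimator, whose
#'   response to coupling strength saturates above roughly 0.2.
#' @param late_strong,late_weak Strengths in the late-conclusion window
#'   for the control and gifted groups.
#' @param ... Passed to [coupling_scenario()] (noise scale etc.).
#' @return Named list of two [coupling_scenario()]s (`gifted`, `control`).
#' @export
group_effect_scenarios <- function(design,
                                   integration_ms = c(3000, 6500),
                                   late_ms = c(7500, 9000),
                                   strong = 0.3, weak = 0.05,
                                   late_strong = 0.3, late_weak = 0.05,
                                   ...) {
  make <- function(mid_strength, late_strength) {
    cps <- list()
    for (f in design$frontal) {
      for (p in design$parietal) {
        cps[[length(cps) + 1L]] <- coupling(f, p, "theta",
                                            integration_ms[1], integration_ms[2],
                                            mid_strength)
        cps[[length(cps) + 1L]] <- coupling(f, p, "theta",
                                            late_ms[1], late_ms[2],
                                            late_strength)
      }
    }
    coupling_scenario(cps, ...)
  }
  list(gifted = make(strong, late_weak),
       control = make(weak, late_strong))
}

## random stable bivariate VAR(2) with identity innovations and
## substantive bidirectional coupling (lag-1 cross coefficients of
## magnitude 0.3-0.6), so that relative-error comparisons are made on
## causality values bounded away from zero; rejection sampling keeps the
## companion spectral radius below 0.9
sample_stable_var2 <- function() {
  repeat {
    A <- array(0, dim = c(2, 2, 2))
    A[, , 1] <- diag(stats::runif(2, 0.2, 0.6) * sample(c(-1, 1), 2, TRUE))
    A[1, 2, 1] <- stats::runif(1, 0.3, 0.6) * sample(c(-1, 1), 1)
    A[2, 1, 1] <- stats::runif(1, 0.3, 0.6) * sample(c(-1, 1), 1)
    A[, , 2] <- diag(stats::runif(2, -0.3, 0.2))
    if (companion_spectral_radius(A) < 0.9) return(A)
  }
}

simulate_var <- function(A, n, burn = 500L) {
  p <- dim(A)[3]
  d <- dim(A)[1]
  x <- matrix(0, n + burn + p, d)
  e <- matrix(stats::rnorm((n + burn + p) * d), ncol = d)
  for (t in (p + 1):nrow(x)) {
    acc <- e[t, ]
    for (k in seq_len(p)) acc <- acc + A[, , k] %*% x[t - k, ]
    x[t, ] <- acc
  }
  x[(burn + p + 1):nrow(x), , drop = FALSE]
}

#' Spectral-temporal consistency of the causality estimator
#'
#' For random stable bivariate VAR(2) processes, the mean of the spectral
#' causality over the full frequency grid must match the time-domain
#' restricted-vs-full log variance ratio (the integral identity of the
#' frequency decomposition). The restricted regression uses three times
#' the full-model order: the implied marginal process of a VAR carries a
#' moving-average part, and a handful of extra autoregressive lags absorb
#' it without paying a meaningful variance price at this sample size.
#'
#' @param n_models Number of random processes.
#' @param n_samples Series length per process.
#' @param n_grid Frequency-grid size for the quadrature.
#' @param p_restricted Restricted-model order for the time-domain side.
#' @param seed Seed.
#' @return Data frame with per-model, per-direction `spectral_mean`,
#'   `time_domain` and `rel_err`; max relative error as attribute
#'   `"max_rel_err"`.
#' @export
gc_consistency_study <- function(n_models = 20L, n_samples = 5000L,
                                 n_grid = 512L, p_restricted = 6L,
                                 seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_models), function(i) {
      A <- sample_stable_var2()
      x <- simulate_var(A, n_samples)
      x <- sweep(x, 2L, colMeans(x))
      model <- fit_var(x, 2L)
      fs <- 2 * pi                       # grid in raw radians: Hz == rad/sample
      sgc <- spectral_gc_pair(model, fs = fs, freq_hz = default_grid(fs, n_grid))
      sm <- colMeans(sgc$f, na.rm = TRUE)
      td <- c(time_domain_gc(x, source = 2, target = 1, p = 2,
                             p_restricted = p_restricted),
              time_domain_gc(x, source = 1, target = 2, p = 2,
                             p_restricted = p_restricted))
      data.frame(model = i, direction = c("2->1", "1->2"),
                 spectral_mean = as.numeric(sm), time_domain = td,
                 rel_err = abs(as.numeric(sm) - td) / pmax(abs(td), 1e-12))
    })
    out <- do.call(rbind, rows)
    attr(out, "max_rel_err") <- max(out$rel_err)
    out
  })
}

## shared small montage for the edge-detection studies: one frontal and
## one parietal theta-tuned node
pair_design <- function(fs = 500) {
  trial_design(sampling_rate = fs, frontal = "F1", parietal = "P1")
}

pair_counts <- function(n_trials, groups) {
  stats::setNames(rep(list(list(n_subjects = 4L,
                                trials_per_subject = rep(n_trials / 4L, 4L))),
                      length(groups)), groups)
}

#' Null calibration of the edge-detection procedure
#'
#' Repeatedly generates no-coupling cohorts, runs the full causality and
#' binarization pipeline on the theta band, and reports the overall edge
#' rate — the fraction of (window, pair, group) entries set to 1 — which
#' must stay near the nominal level of the cluster test.
#'
#' @param n_reps Number of seeded repetitions.
#' @param trials_per_group Trials per group per repetition.
#' @param n_perm,alpha Cluster-test parameters.
#' @param seed Seed.
#' @return List: `edge_rate`, per-repetition rates, `n_reps`.
#' @export
null_edge_rate_study <- function(n_reps = 200L, trials_per_group = 20L,
                                 n_perm = 200L, alpha = 0.05, seed = 1L) {
  design <- pair_design()
  scen <- coupling_scenario()            # no couplings
  groups <- c("gifted", "control")
  seeds <- derive_seeds(seed, n_reps)
  bands <- frequency_bands()[1, , drop = FALSE]
  pairs2 <- data.frame(source = c("F1", "P1"), target = c("P1", "F1"))
  rates <- vapply(seq_len(n_reps), function(i) {
    cohort <- generate_cohort(design,
                              scenarios = list(gifted = scen, control = scen),
                              counts = pair_counts(trials_per_group, groups),
                              master_seed = seeds[i])
    tab <- window_gc_table(cohort, bands = bands,
                           pairs = data.frame(source = "F1", target = "P1"))
    nets <- binarize_networks(tab, pairs = pairs2, n_perm = n_perm,
                              alpha = alpha, seed = seeds[i])
    mean(vapply(nets$adjacency, function(gl)
      mean(vapply(gl, mean, numeric(1))), numeric(1)))
  }, numeric(1))
  list(edge_rate = mean(rates), per_rep = rates, n_reps = n_reps)
}

#' Direction recovery of a designed coupling
#'
#' A single-group cohort carries one theta-band frontal-to-parietal
#' coupling active in a known task interval. The study reports the
#' fraction of active windows in which the true directed edge is detected
#' and the edge rate of the reverse direction (the negative control),
#' which should stay at the null level.
#'
#' @param trials Number of trials.
#' @param strength Coupling strength (lag-1 AR coefficient).
#' @param active_ms Active interval in task time.
#' @param n_perm,alpha Cluster-test parameters.
#' @param seed Seed.
#' @return List: `detection_rate` (active windows), `reverse_rate` (all
#'   windows, reverse direction), `active_windows`.
#' @export
direction_recovery_study <- function(trials = 20L, strength = 0.4,
                                     active_ms = c(3000, 6000),
                                     n_perm = 200L, alpha = 0.05, seed = 1L,
                                     osc_r = 0.7) {
  design <- pair_design()
  scen <- coupling_scenario(coupling("F1", "P1", "theta",
                                     active_ms[1], active_ms[2], strength),
                            osc_r = osc_r)
  cohort <- generate_cohort(design, scenarios = list(coupled = scen),
                            counts = pair_counts(trials, "coupled"),
                            master_seed = seed)
  bands <- frequency_bands()[1, , drop = FALSE]
  tab <- window_gc_table(cohort, bands = bands,
                         pairs = data.frame(source = "F1", target = "P1"))
  pairs2 <- data.frame(source = c("F1", "P1"), target = c("P1", "F1"))
  nets <- binarize_networks(tab, pairs = pairs2, n_perm = n_perm,
                            alpha = alpha, seed = seed)
  grid <- attr(tab, "grid")
  win_on <- (seq_len(grid$n_task) - 1L) * grid$window_ms
  active <- which(win_on >= active_ms[1] & win_on < active_ms[2])
  adj <- nets$adjacency$coupled$theta
  list(detection_rate = mean(adj[active, "F1->P1"]),
       reverse_rate = mean(adj[, "P1->F1"]),
       active_windows = active)
}

#' Graph-metric oracle equivalence
#'
#' Checks the production shortest-path implementation against a
#' brute-force all-pairs computation on random digraphs, and two exact
#' closed-form cases: the 3-node directed cycle's characteristic path
#' length and the causal density of a single nonzero entry.
#'
#' @param n_graphs Number of random digraphs.
#' @param n_nodes Nodes per digraph.
#' @param edge_prob Edge probability.
#' @param seed Seed.
#' @return List: `mismatches` (count of graphs where BFS and the
#'   brute-force distances differ), `cycle3_L`, `single_edge_cd`.
#' @export
graph_metric_oracle_study <- function(n_graphs = 100L, n_nodes = 10L,
                                      edge_prob = 0.2, seed = 1L) {
  mism <- with_seed(seed, {
    sum(vapply(seq_len(n_graphs), function(i) {
      adj <- matrix(as.integer(stats::runif(n_nodes^2) < edge_prob),
                    n_nodes, n_nodes)
      diag(adj) <- 0L
      !identical(shortest_path_matrix(adj), floyd_warshall_distances(adj))
    }, logical(1)))
  })
  cyc <- matrix(0L, 3, 3)
  cyc[cbind(1:3, c(2, 3, 1))] <- 1L
  cycle3 <- characteristic_path_length(shortest_path_matrix(cyc))$L
  gm <- matrix(0, 3, 3)
  gm[1, 2] <- 0.6
  list(mismatches = mism, cycle3_L = cycle3,
       single_edge_cd = causal_density(gm)$cd)
}

#' Recovery of a designed group effect by the per-window ANOVA
#'
#' Generates two-group cohorts with the [group_effect_scenarios()]
#' contrast on a compact montage, computes subject-level theta-band causal
#' density per window, runs the per-window ANOVA, and measures how much of
#' the designed effect windows the significant spans cover.
#'
#' @param n_cohorts Number of seeded cohorts.
#' @param n_subjects Per-group subject counts.
#' @param trials_per_subject Trials per subject.
#' @param integration_ms,late_ms Designed effect intervals (task ms).
#' @param alpha ANOVA significance level.
#' @param seed Seed.
#' @return List: `success_rate` (fraction of cohorts with overlap >= 0.7),
#'   per-cohort `overlap`, `designed_windows`.
#' @export
group_effect_recovery_study <- function(n_cohorts = 20L,
                                        n_subjects = c(gifted = 20L, control = 18L),
                                        trials_per_subject = 6L,
                                        integration_ms = c(3000, 6500),
                                        late_ms = c(7500, 9000),
                                        alpha = 0.05, seed = 1L) {
  design <- trial_design(frontal = c("F1", "F2"), parietal = c("P1", "P2"))
  scens <- group_effect_scenarios(design, integration_ms = integration_ms,
                                  late_ms = late_ms)
  counts <- list(
    gifted = list(n_subjects = n_subjects[["gifted"]],
                  trials_per_subject = rep(trials_per_subject, n_subjects[["gifted"]])),
    control = list(n_subjects = n_subjects[["control"]],
                   trials_per_subject = rep(trials_per_subject, n_subjects[["control"]])))
  bands <- frequency_bands()[1, , drop = FALSE]
  grid <- window_grid(design)
  win_on <- (seq_len(grid$n_task) - 1L) * grid$window_ms
  designed <- which((win_on >= integration_ms[1] & win_on < integration_ms[2]) |
                      (win_on >= late_ms[1] & win_on < late_ms[2]))
  seeds <- derive_seeds(seed, n_cohorts)
  overlap <- vapply(seq_len(n_cohorts), function(i) {
    cohort <- generate_cohort(design, scens, counts, master_seed = seeds[i])
    tab <- window_gc_table(cohort, bands = bands, pairs = roi_pairs(design))
    cd <- subject_cd_series(tab)
    wc <- per_window_anova(cd[cd$band == "theta", ], alpha = alpha)
    sig <- unlist(lapply(seq_len(nrow(wc$spans)), function(k)
      wc$spans$start[k]:wc$spans$end[k]))
    length(intersect(sig, designed)) / length(designed)
  }, numeric(1))
  list(success_rate = mean(overlap >= 0.7), overlap = overlap,
       designed_windows = designed)
}

#' Type-I error of the per-window ANOVA
#'
#' Null replicates draw subject-level metric values for two groups from
#' the same Gaussian distribution; the study reports the fraction of
#' windows declared significant, which must sit at the nominal level.
#'
#' @param n_reps Number of replicates.
#' @param n_subjects Per-group subject counts.
#' @param n_windows Windows per replicate.
#' @param alpha Significance level.
#' @param seed Seed.
#' @return List: `fp_rate`, `n_tests`.
#' @export
anova_type1_study <- function(n_reps = 200L,
                              n_subjects = c(20L, 18L), n_windows = 90L,
                              alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    hits <- 0L
    total <- 0L
    for (i in seq_len(n_reps)) {
      df <- data.frame(
        group = rep(c("a", "b"), times = n_subjects * n_windows),
        window = c(rep(seq_len(n_windows), each = n_subjects[1]),
                   rep(seq_len(n_windows), each = n_subjects[2])),
        value = stats::rnorm(sum(n_subjects) * n_windows))
      wc <- per_window_anova(df, alpha = alpha, min_span = 1L)
      hits <- hits + sum(wc$table$significant)
      total <- total + nrow(wc$table)
    }
    list(fp_rate = hits / total, n_tests = total)
  })
}
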