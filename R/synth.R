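#' Trial layout for a three-phase reasoning task
#'
#' Describes the temporal structure of one trial — a pre-stimulus baseline
#' followed by a task period split into sequential phases (premise coding,
#' premise integration, conclusion) — together with the node labels of the
#' source-level montage, partitioned into frontal and parietal sets.
#'
#' @param sampling_rate Sampling rate in Hz. Default 500 Hz, which puts the
#'   upper edge of the gamma band (60 Hz) well below Nyquist and makes a
#'   100 ms analysis window an even 50 samples.
#' @param baseline_ms Baseline duration in ms (default 1000).
#' @param task_ms Task duration in ms (default 9000).
#' @param phase_boundaries_ms Strictly increasing offsets (ms, relative to
#'   task onset) splitting the task period into phases. The default
#'   `c(3000, 6000)` gives three 3 s phases.
#' @param frontal,parietal Character vectors of node labels; must be
#'   disjoint. Together they are the analyzed node set, in that order.
#' @return An object of class `trial_design`.
#' @examples
#' d <- trial_design()
#' d$n_nodes      # 13
#' d$baseline_n   # 500 samples
#' @export
trial_design <- function(sampling_rate = 500,
                         baseline_ms = 1000,
                         task_ms = 9000,
                         phase_boundaries_ms = c(3000, 6000),
                         frontal = paste0("F", 1:8),
                         parietal = paste0("P", 1:5)) {
  stopifnot(sampling_rate > 0, baseline_ms > 0, task_ms > 0)
  if (any(duplicated(c(frontal, parietal)))) {
    stop("frontal and parietal node sets must be disjoint and without duplicates")
  }
  pb <- as.numeric(phase_boundaries_ms)
  if (length(pb) && (any(diff(pb) <= 0) || any(pb <= 0) || any(pb >= task_ms))) {
    stop("phase_boundaries_ms must be strictly increasing within (0, task_ms)")
  }
  ms_to_n <- function(ms) ms * sampling_rate / 1000
  if (ms_to_n(baseline_ms) != round(ms_to_n(baseline_ms)) ||
      ms_to_n(task_ms) != round(ms_to_n(task_ms))) {
    stop("baseline_ms and task_ms must be integer numbers of samples at sampling_rate")
  }
  phases <- if (length(pb) == 2L) {
    c("premise_coding", "premise_integration", "conclusion")
  } else {
    paste0("phase_", seq_len(length(pb) + 1L))
  }
  structure(list(
    sampling_rate = sampling_rate,
    baseline_ms = baseline_ms,
    task_ms = task_ms,
    phase_boundaries_ms = pb,
    phase_names = phases,
    frontal = frontal,
    parietal = parietal,
    nodes = c(frontal, parietal),
    n_nodes = length(frontal) + length(parietal),
    baseline_n = as.integer(round(ms_to_n(baseline_ms))),
    task_n = as.integer(round(ms_to_n(task_ms))),
    total_n = as.integer(round(ms_to_n(baseline_ms + task_ms)))
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design> %d nodes (%d frontal, %d parietal), fs = %g Hz\n",
              x$n_nodes, length(x$frontal), length(x$parietal), x$sampling_rate))
  cat(sprintf("  baseline %g ms + task %g ms; phase boundaries at %s ms\n",
              x$baseline_ms, x$task_ms, paste(x$phase_boundaries_ms, collapse = ", ")))
  invisible(x)
}

#' AR(2) coefficients of a damped oscillator
#'
#' A stochastically driven damped oscillator with resonance `freq_hz` is the
#' AR(2) process whose complex pole pair has modulus `r` and argument
#' `2*pi*freq_hz/fs` radians per sample.
#'
#' @param freq_hz Resonance frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param r Pole modulus in (0, 1); closer to 1 gives a sharper spectral peak.
#' @return Numeric vector `c(a1, a2)`.
#' @export
oscillator_ar2 <- function(freq_hz, fs, r = 0.7) {
  stopifnot(freq_hz > 0, freq_hz < fs / 2, r > 0, r < 1)
  c(2 * r * cos(2 * pi * freq_hz / fs), -r^2)
}

#' A single scheduled directed coupling
#'
#' @param source,target Node labels (source drives target).
#' @param band `"theta"` or `"gamma"`; selects the default oscillator tuning
#'   of the two nodes (the coupling itself is a lag-1 VAR coefficient).
#' @param start_ms,end_ms Active interval in ms relative to task onset;
#'   the coupling coefficient is exactly zero outside `[start_ms, end_ms)`.
#' @param strength Dimensionless AR coefficient from the source's lagged
#'   value into the target's equation.
#' @return An object of class `coupling`.
#' @export
coupling <- function(source, target, band = c("theta", "gamma"),
                     start_ms, end_ms, strength) {
  band <- match.arg(band)
  stopifnot(is.character(source), is.character(target),
            start_ms >= 0, end_ms > start_ms, is.finite(strength))
  structure(list(source = source, target = target, band = band,
                 start_ms = start_ms, end_ms = end_ms,
                 strength = strength), class = "coupling")
}

#' Coupling scenario: node dynamics plus scheduled couplings
#'
#' Bundles everything the generator needs beyond the trial layout: the
#' oscillator tuning of each node, the innovation noise scale, an optional
#' instantaneous innovation correlation, and a list of [coupling()] entries.
#'
#' @param couplings List of [coupling()] objects (possibly empty).
#' @param theta_hz,gamma_hz Oscillator center frequencies (Hz) for
#'   theta-tuned and gamma-tuned nodes.
#' @param osc_r Pole modulus of the node oscillators. The default 0.7
#'   gives broadband resonances whose autocorrelation decays within a few
#'   samples, so that 100 ms analysis windows are approximately stationary
#'   — the premise of the windowed causality protocol. Values close to 1
#'   give sharp narrowband peaks (a genuine 4-8 Hz spectral maximum needs
#'   about 0.95 or more at a 500 Hz rate) at the price of windows that the
#'   stationarity gate rejects and noisy short-window fits.
#' @param noise_sd Innovation standard deviation.
#' @param inst_cor Pairwise instantaneous correlation of the innovations
#'   across nodes (default 0: i.i.d. innovations, no instantaneous mixing).
#'   A nonzero value exercises the partial-covariance correction of the
#'   spectral causality estimator.
#' @param node_freq_hz Optional named numeric vector giving an explicit
#'   resonance frequency per node; nodes absent from it are tuned from the
#'   bands of the couplings they participate in (theta by default).
#' @return An object of class `coupling_scenario`.
#' @export
coupling_scenario <- function(couplings = list(),
                              theta_hz = 6, gamma_hz = 40,
                              osc_r = 0.7,
                              noise_sd = 1,
                              inst_cor = 0,
                              node_freq_hz = NULL) {
  if (inherits(couplings, "coupling")) couplings <- list(couplings)
  stopifnot(all(vapply(couplings, inherits, logical(1), "coupling")),
            noise_sd >= 0, inst_cor >= 0, inst_cor < 1,
            osc_r > 0, osc_r < 1)
  structure(list(couplings = couplings,
                 theta_hz = theta_hz, gamma_hz = gamma_hz,
                 osc_r = osc_r, noise_sd = noise_sd,
                 inst_cor = inst_cor,
                 node_freq_hz = node_freq_hz), class = "coupling_scenario")
}

## Resolve each node's oscillator frequency from the scenario.
node_frequencies <- function(design, scenario) {
  freq <- stats::setNames(rep(scenario$theta_hz, design$n_nodes), design$nodes)
  for (cp in scenario$couplings) {
    f <- if (cp$band == "theta") scenario$theta_hz else scenario$gamma_hz
    freq[c(cp$source, cp$target)] <- f
  }
  if (!is.null(scenario$node_freq_hz)) {
    unknown <- setdiff(names(scenario$node_freq_hz), design$nodes)
    if (length(unknown)) {
      stop("node_freq_hz refers to unknown node(s): ", paste(unknown, collapse = ", "))
    }
    freq[names(scenario$node_freq_hz)] <- scenario$node_freq_hz
  }
  freq
}

companion_spectral_radius <- function(A) {
  n <- dim(A)[1]; p <- dim(A)[3]
  top <- matrix(0, n, n * p)
  for (k in seq_len(p)) top[, (k - 1) * n + seq_len(n)] <- A[, , k]
  comp <- rbind(top, cbind(diag(n * (p - 1)), matrix(0, n * (p - 1), n)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Build a time-varying VAR coefficient schedule
#'
#' Translates a [coupling_scenario()] into a piecewise-constant schedule of
#' VAR(2) coefficient matrices over one trial: diagonal blocks are damped
#' oscillators at each node's resonance frequency; off-diagonal lag-1
#' entries carry the scheduled couplings, exactly zero outside their active
#' intervals. Couplings are never active during the baseline period, which
#' is the reference condition of the downstream edge test.
#'
#' @param design A [trial_design()].
#' @param scenario A [coupling_scenario()].
#' @return An object of class `var_schedule`: segments of constant
#'   coefficients covering the whole trial, each with its coefficient array
#'   `A` (nodes x nodes x 2) and sample range.
#' @export
build_tv_var <- function(design, scenario) {
  stopifnot(inherits(design, "trial_design"), inherits(scenario, "coupling_scenario"))
  n <- design$n_nodes
  nodes <- design$nodes
  for (cp in scenario$couplings) {
    bad <- setdiff(c(cp$source, cp$target), nodes)
    if (length(bad)) stop("coupling refers to unknown node(s): ", paste(bad, collapse = ", "))
    if (cp$end_ms > design$task_ms) stop("coupling interval exceeds task duration")
  }
  freq <- node_frequencies(design, scenario)
  fs <- design$sampling_rate
  base <- array(0, dim = c(n, n, 2), dimnames = list(nodes, nodes, NULL))
  for (i in seq_len(n)) {
    ar <- oscillator_ar2(freq[i], fs, scenario$osc_r)
    base[i, i, 1] <- ar[1]
    base[i, i, 2] <- ar[2]
  }
  ms_to_sample <- function(ms) design$baseline_n + as.integer(round(ms * fs / 1000))
  ## segment breakpoints: trial start, each coupling on/off edge, trial end
  cuts <- sort(unique(c(0L, design$baseline_n,
                        unlist(lapply(scenario$couplings, function(cp)
                          c(ms_to_sample(cp$start_ms), ms_to_sample(cp$end_ms)))),
                        design$total_n)))
  cuts <- cuts[cuts >= 0L & cuts <= design$total_n]
  segments <- vector("list", length(cuts) - 1L)
  for (s in seq_along(segments)) {
    from <- cuts[s] + 1L
    to <- cuts[s + 1L]
    A <- base
    for (cp in scenario$couplings) {
      a <- ms_to_sample(cp$start_ms) + 1L
      b <- ms_to_sample(cp$end_ms)
      if (from >= a && to <= b) {
        A[cp$target, cp$source, 1] <- A[cp$target, cp$source, 1] + cp$strength
      }
    }
    rho <- companion_spectral_radius(A)
    if (rho >= 0.999) {
      t0 <- (from - 1L - design$baseline_n) * 1000 / fs
      t1 <- (to - design$baseline_n) * 1000 / fs
      stop(sprintf(paste0("composite VAR is unstable (spectral radius %.3f) in ",
                          "interval %g to %g ms of the task"), rho, t0, t1))
    }
    segments[[s]] <- list(from = from, to = to, A = A, spectral_radius = rho)
  }
  structure(list(segments = segments, p = 2L, design = design,
                 noise_sd = scenario$noise_sd, inst_cor = scenario$inst_cor,
                 node_freq_hz = freq), class = "var_schedule")
}

innovation_chol <- function(schedule) {
  n <- schedule$design$n_nodes
  s2 <- schedule$noise_sd^2
  rho <- schedule$inst_cor
  Sigma <- s2 * ((1 - rho) * diag(n) + rho * matrix(1, n, n))
  if (schedule$noise_sd == 0) return(matrix(0, n, n))
  t(chol(Sigma))
}

segment_id_per_sample <- function(schedule) {
  idx <- integer(schedule$design$total_n)
  for (s in seq_along(schedule$segments)) {
    seg <- schedule$segments[[s]]
    idx[seg$from:seg$to] <- s
  }
  idx
}

as_source_ts <- function(x, design, seed = NA_integer_) {
  rownames(x) <- design$nodes
  structure(x, class = c("source_ts", "matrix", "array"),
            sampling_rate = design$sampling_rate,
            baseline_n = design$baseline_n,
            frontal = design$frontal, parietal = design$parietal,
            phase_boundaries_ms = design$phase_boundaries_ms,
            seed = seed)
}

#' @export
print.source_ts <- function(x, ...) {
  cat(sprintf("<source_ts> %d nodes x %d samples @ %g Hz (baseline %d samples)\n",
              nrow(x), ncol(x), attr(x, "sampling_rate"), attr(x, "baseline_n")))
  invisible(x)
}

#' Simulate one trial from a VAR schedule
#'
#' Iterates the time-varying VAR with Gaussian innovations. A burn-in
#' period (default 2 s) under the first segment's dynamics is simulated and
#' discarded so that the trial starts from the process's stationary regime.
#' Fully reproducible from `seed`.
#'
#' @param schedule A [build_tv_var()] schedule.
#' @param seed Integer seed.
#' @param burn_in_ms Burn-in duration in ms, discarded before trial start.
#' @return A `source_ts`: nodes x samples matrix with sampling-rate,
#'   partition and phase metadata attached as attributes.
#' @export
simulate_trial <- function(schedule, seed, burn_in_ms = 2000) {
  stopifnot(inherits(schedule, "var_schedule"))
  out <- simulate_trials(schedule, seeds = seed, burn_in_ms = burn_in_ms)
  out[[1L]]
}

## Batch simulator: trials share the schedule, innovations are drawn from
## per-trial seeds, and the VAR recursion advances all trials jointly
## (column-per-trial) for speed.
simulate_trials <- function(schedule, seeds, burn_in_ms = 2000, chunk = 64L) {
  design <- schedule$design
  n <- design$n_nodes
  fs <- design$sampling_rate
  burn_n <- as.integer(round(burn_in_ms * fs / 1000))
  total <- design$total_n
  steps <- burn_n + total
  L <- innovation_chol(schedule)
  seg_of <- c(rep(1L, burn_n), segment_id_per_sample(schedule))
  out <- vector("list", length(seeds))
  for (block in split(seq_along(seeds), ceiling(seq_along(seeds) / chunk))) {
    m <- length(block)
    ## innovations: per-trial seeded streams, stacked as nodes x trials x steps
    E <- array(0, dim = c(n, m, steps))
    for (j in seq_len(m)) {
      e <- with_seed(seeds[block[j]],
                     matrix(stats::rnorm(n * steps), n, steps))
      E[, j, ] <- L %*% e
    }
    X1 <- matrix(0, n, m)   # state at t-1
    X2 <- matrix(0, n, m)   # state at t-2
    keep <- array(0, dim = c(n, m, total))
    cur_seg <- -1L
    A1 <- A2 <- NULL
    for (t in seq_len(steps)) {
      s <- seg_of[t]
      if (s != cur_seg) {
        A1 <- schedule$segments[[s]]$A[, , 1]
        A2 <- schedule$segments[[s]]$A[, , 2]
        cur_seg <- s
      }
      X <- A1 %*% X1 + A2 %*% X2 + E[, , t]
      X2 <- X1
      X1 <- X
      if (t > burn_n) keep[, , t - burn_n] <- X
    }
    if (!all(is.finite(keep))) {
      stop("non-finite sample produced during simulation; the composite VAR is unstable")
    }
    for (j in seq_len(m)) {
      out[[block[j]]] <- as_source_ts(matrix(keep[, j, ], n, total),
                                      design, seed = seeds[block[j]])
    }
  }
  out
}

#' Default cohort sizes
#'
#' Two groups: 20 subjects with 20 trials each (400 trials) and 18 subjects
#' with 21 or 22 trials (380 trials total), the retained-trial counts of the
#' emulated study design.
#'
#' @return Named list with per-group `n_subjects` and `trials_per_subject`.
#' @export
default_counts <- function() {
  list(
    gifted = list(n_subjects = 20L, trials_per_subject = rep(20L, 20L)),
    control = list(n_subjects = 18L, trials_per_subject = c(rep(21L, 16L), rep(22L, 2L)))
  )
}

#' Generate a two-group cohort of simulated trials
#'
#' Builds one VAR schedule per group from its scenario and simulates every
#' subject's trials, with all per-trial seeds derived deterministically from
#' `master_seed`: the same master seed always reproduces the same cohort.
#'
#' @param design A [trial_design()] shared by all trials.
#' @param scenarios Named list: group label -> [coupling_scenario()].
#' @param counts Named list matching `scenarios`, each entry a list with
#'   `n_subjects` and `trials_per_subject` (scalar or per-subject vector).
#'   Defaults to [default_counts()] for groups named `gifted`/`control`.
#' @param master_seed Integer master seed.
#' @return An object of class `gc_cohort`: nested group -> subject -> trial
#'   list of `source_ts`, plus the design, counts and generative metadata.
#' @export
generate_cohort <- function(design, scenarios, counts = NULL, master_seed = 1L) {
  stopifnot(inherits(design, "trial_design"), is.list(scenarios),
            length(names(scenarios)) == length(scenarios))
  if (is.null(counts)) {
    counts <- default_counts()[names(scenarios)]
    if (any(vapply(counts, is.null, logical(1)))) {
      stop("no default counts for these group names; supply `counts`")
    }
  }
  if (!setequal(names(counts), names(scenarios))) {
    stop("`counts` and `scenarios` must have the same group names")
  }
  tps <- lapply(names(scenarios), function(g) {
    ct <- counts[[g]]
    ns <- ct$n_subjects
    if (!is_count(ns)) stop("counts for group '", g, "': n_subjects must be a positive integer")
    tp <- ct$trials_per_subject
    if (length(tp) == 1L) tp <- rep(tp, ns)
    if (length(tp) != ns || !all(vapply(tp, is_count, logical(1)))) {
      stop("counts for group '", g, "': trials_per_subject must be positive integers, one per subject")
    }
    as.integer(tp)
  })
  names(tps) <- names(scenarios)
  total_trials <- sum(unlist(tps))
  seeds <- derive_seeds(master_seed, total_trials)
  offset <- 0L
  groups <- list()
  for (g in names(scenarios)) {
    schedule <- build_tv_var(design, scenarios[[g]])
    n_tr <- sum(tps[[g]])
    trial_seeds <- seeds[offset + seq_len(n_tr)]
    offset <- offset + n_tr
    sims <- simulate_trials(schedule, trial_seeds)
    subjects <- list()
    k <- 0L
    for (s in seq_along(tps[[g]])) {
      subjects[[sprintf("S%02d", s)]] <- list(trials = sims[k + seq_len(tps[[g]][s])])
      k <- k + tps[[g]][s]
    }
    groups[[g]] <- list(subjects = subjects)
  }
  structure(list(groups = groups, design = design, counts = counts,
                 trials_per_subject = tps, master_seed = master_seed,
                 scenarios = scenarios),
            class = "gc_cohort")
}

#' Number of trials in a cohort, per group
#' @param cohort A `gc_cohort`.
#' @return Named integer vector.
#' @export
cohort_trial_counts <- function(cohort) {
  stopifnot(inherits(cohort, "gc_cohort"))
  vapply(cohort$trials_per_subject, sum, integer(1))
}

#' @export
print.gc_cohort <- function(x, ...) {
  cts <- cohort_trial_counts(x)
  cat(sprintf("<gc_cohort> %d group(s), master seed %d\n", length(cts), x$master_seed))
  for (g in names(cts)) {
    cat(sprintf("  %s: %d subjects, %d trials\n", g,
                x$counts[[g]]$n_subjects, cts[[g]]))
  }
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per group/subject; each trial is stored as a little-endian
#' float64 binary array (nodes x samples, column-major) next to a JSON
#' sidecar with its metadata. A top-level `manifest.json` lists every trial.
#'
#' @param cohort A `gc_cohort`.
#' @param dir Output directory (created; must not already contain a manifest
#'   unless `force`).
#' @param force Overwrite an existing cohort directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "gc_cohort"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("cohort directory already contains a manifest; use force = TRUE to overwrite")
  }
  design <- cohort$design
  entries <- list()
  for (g in names(cohort$groups)) {
    for (s in names(cohort$groups[[g]]$subjects)) {
      subdir <- file.path(dir, g, s)
      dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
      trials <- cohort$groups[[g]]$subjects[[s]]$trials
      for (i in seq_along(trials)) {
        tr <- trials[[i]]
        stem <- file.path(subdir, sprintf("trial%03d", i))
        con <- file(paste0(stem, ".f64"), "wb")
        writeBin(as.vector(unclass(tr)), con, size = 8L, endian = "little")
        close(con)
        side <- list(nodes = design$nodes, frontal = design$frontal,
                     parietal = design$parietal,
                     sampling_rate = design$sampling_rate,
                     baseline_ms = design$baseline_ms, task_ms = design$task_ms,
                     phase_boundaries_ms = design$phase_boundaries_ms,
                     n_samples = ncol(tr), seed = attr(tr, "seed"))
        jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE)
        entries[[length(entries) + 1L]] <-
          list(group = g, subject = s, trial = i,
               data = file.path(g, s, sprintf("trial%03d.f64", i)))
      }
    }
  }
  jsonlite::write_json(list(master_seed = cohort$master_seed, trials = entries),
                       manifest_path, auto_unbox = TRUE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `gc_cohort` (scenario metadata is not restored).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  first_side <- jsonlite::read_json(
    file.path(dir, sub("\\.f64$", ".json", manifest$trials$data[1])),
    simplifyVector = TRUE)
  design <- trial_design(sampling_rate = first_side$sampling_rate,
                         baseline_ms = first_side$baseline_ms,
                         task_ms = first_side$task_ms,
                         phase_boundaries_ms = first_side$phase_boundaries_ms,
                         frontal = first_side$frontal,
                         parietal = first_side$parietal)
  groups <- list()
  tps <- list()
  for (k in seq_len(nrow(manifest$trials))) {
    row <- manifest$trials[k, ]
    path <- file.path(dir, row$data)
    con <- file(path, "rb")
    v <- readBin(con, "double", n = file.size(path) / 8L, size = 8L,
                 endian = "little")
    close(con)
    x <- as_source_ts(matrix(v, design$n_nodes), design)
    groups[[row$group]]$subjects[[row$subject]]$trials[[row$trial]] <- x
  }
  for (g in names(groups)) {
    tps[[g]] <- vapply(groups[[g]]$subjects,
                       function(s) length(s$trials), integer(1))
  }
  counts <- lapply(tps, function(v) list(n_subjects = length(v),
                                         trials_per_subject = as.integer(v)))
  structure(list(groups = groups, design = design, counts = counts,
                 trials_per_subject = tps,
                 master_seed = manifest$master_seed, scenarios = NULL),
            class = "gc_cohort")
}
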