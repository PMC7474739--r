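## Configuration and end-to-end orchestration.

merge_lists <- function(base, over) {
  if (!is.list(over)) return(over)
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
                        !is.null(names(base[[nm]]))) {
      merge_lists(base[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  base
}

#' Default pipeline configuration
#'
#' The full study-scale configuration: the 13-node montage, two groups at
#' their default sizes (400 and 380 trials), the 1-60 Hz bandpass, 100 ms
#' windows, theta/gamma analysis bands, 200 permutations. Every stage
#' parameter is overridable through [validate_config()].
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    design = list(sampling_rate = 500, baseline_ms = 1000, task_ms = 9000,
                  phase_boundaries_ms = c(3000, 6000),
                  frontal = paste0("F", 1:8), parietal = paste0("P", 1:5)),
    groups = list(
      gifted = list(counts = list(n_subjects = 20L,
                                  trials_per_subject = rep(20L, 20L))),
      control = list(counts = list(n_subjects = 18L,
                                   trials_per_subject = c(rep(21L, 16L), rep(22L, 2L))))
    ),
    scenario_defaults = list(theta_hz = 6, gamma_hz = 40, osc_r = 0.7,
                             noise_sd = 1, inst_cor = 0),
    filter = c(1, 60),
    bands = c("theta", "gamma"),
    window_ms = 100,
    n_freq = 128L,
    p_max = 3L,
    gate_rule = "both",
    pairs = NULL,
    n_perm = 200L,
    alpha = 0.05,
    cluster_alpha = 0.05,
    unreachable_rule = "zero",
    estimator = "bivariate",
    anova = list(alpha = 0.05, correction = "none", min_span = 2L),
    seed = 1L
  )
}

config_design <- function(config) {
  d <- config$design
  trial_design(sampling_rate = d$sampling_rate, baseline_ms = d$baseline_ms,
               task_ms = d$task_ms,
               phase_boundaries_ms = unlist(d$phase_boundaries_ms),
               frontal = unlist(d$frontal), parietal = unlist(d$parietal))
}

config_scenarios <- function(config, design) {
  sd <- config$scenario_defaults
  out <- list()
  for (g in names(config$groups)) {
    gc <- config$groups[[g]]
    cps <- lapply(gc$couplings %||% list(), function(cp) {
      coupling(cp$source, cp$target, cp$band %||% "theta",
               cp$start_ms, cp$end_ms, cp$strength)
    })
    out[[g]] <- coupling_scenario(cps,
                                  theta_hz = gc$theta_hz %||% sd$theta_hz,
                                  gamma_hz = gc$gamma_hz %||% sd$gamma_hz,
                                  osc_r = gc$osc_r %||% sd$osc_r,
                                  noise_sd = gc$noise_sd %||% sd$noise_sd,
                                  inst_cor = gc$inst_cor %||% sd$inst_cor)
  }
  out
}

config_counts <- function(config) {
  lapply(config$groups, function(gc) {
    list(n_subjects = gc$counts$n_subjects,
         trials_per_subject = unlist(gc$counts$trials_per_subject))
  })
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or `NULL` (full defaults);
#' fills every missing field from [default_config()] and cross-checks the
#' result: filter and band edges against Nyquist, window divisibility,
#' band ordering, group counts. A pair list whose size differs from the
#' 40-pair region-of-interest convention is accepted with a warning.
#'
#' @param x Path, list, or `NULL`.
#' @return A validated config (class `pipeline_config`).
#' @export
validate_config <- function(x = NULL) {
  raw <- if (is.null(x)) {
    list()
  } else if (is.character(x)) {
    yaml::read_yaml(x) %||% list()
  } else if (is.list(x)) {
    x
  } else {
    stop("config must be a file path, a list, or NULL")
  }
  config <- merge_lists(default_config(), raw)
  design <- tryCatch(config_design(config),
                     error = function(e) stop_field("design", conditionMessage(e)))
  nyq <- design$sampling_rate / 2
  filt <- unlist(config$filter)
  if (length(filt) != 2 || filt[1] <= 0 || filt[2] <= filt[1]) {
    stop_field("filter", "must be c(low, high) with 0 < low < high")
  }
  if (filt[2] >= nyq) {
    stop_field("filter", sprintf("upper edge %g Hz is not below Nyquist (%g Hz)", filt[2], nyq))
  }
  band_tab <- frequency_bands()
  unknown <- setdiff(unlist(config$bands), band_tab$band)
  if (length(unknown)) stop_field("bands", paste("unknown band:", paste(unknown, collapse = ", ")))
  if (any(band_tab$high[band_tab$band %in% unlist(config$bands)] > nyq)) {
    stop_field("bands", "a requested band extends beyond Nyquist")
  }
  spw <- config$window_ms * design$sampling_rate / 1000
  if (spw != round(spw)) {
    stop_field("window_ms", "window length is not an integer sample count at this rate")
  }
  if (design$task_ms %% config$window_ms != 0) {
    stop_field("window_ms", "task duration is not a multiple of the window length")
  }
  for (g in names(config$groups)) {
    ct <- config$groups[[g]]$counts
    if (!is_count(ct$n_subjects %||% 0)) {
      stop_field(paste0("groups.", g, ".counts.n_subjects"), "must be a positive integer")
    }
  }
  if (!is.null(config$pairs)) {
    pr <- config$pairs
    if (is.list(pr) && !is.data.frame(pr)) {
      pr <- data.frame(source = vapply(pr, `[[`, "", 1),
                       target = vapply(pr, `[[`, "", 2))
    }
    bad <- setdiff(c(pr$source, pr$target), design$nodes)
    if (length(bad)) stop_field("pairs", paste("unknown node(s):", paste(bad, collapse = ", ")))
    if (nrow(pr) != 40L) {
      warning(sprintf("pair list has %d pairs; the region-of-interest convention is 40", nrow(pr)))
    }
    config$pairs <- pr
  }
  if (!config$gate_rule %in% c("both", "either")) {
    stop_field("gate_rule", "must be 'both' or 'either'")
  }
  if (!config$unreachable_rule %in% c("zero", "exclude", "harmonic")) {
    stop_field("unreachable_rule", "must be 'zero', 'exclude' or 'harmonic'")
  }
  structure(config, class = "pipeline_config")
}

#' A small end-to-end demonstration configuration
#'
#' Two nodes per region, two subjects per group with five trials each, and
#' the default group-effect couplings — sized so the complete pipeline
#' runs in seconds.
#'
#' @return A validated config.
#' @export
demo_config <- function() {
  design <- trial_design(frontal = c("F1", "F2"), parietal = c("P1", "P2"))
  scens <- group_effect_scenarios(design)
  as_cfg <- function(scen, n_subjects, trials) {
    list(counts = list(n_subjects = n_subjects,
                       trials_per_subject = rep(trials, n_subjects)),
         couplings = lapply(scen$couplings, function(cp) {
           list(source = cp$source, target = cp$target, band = cp$band,
                start_ms = cp$start_ms, end_ms = cp$end_ms,
                strength = cp$strength)
         }))
  }
  validate_config(list(
    design = list(frontal = c("F1", "F2"), parietal = c("P1", "P2")),
    groups = list(gifted = as_cfg(scens$gifted, 2L, 5L),
                  control = as_cfg(scens$control, 2L, 5L))
  ))
}

#' Run the complete analysis pipeline
#'
#' simulate -> condition -> windowed causality -> binary networks ->
#' graph metrics -> group statistics, writing every stage product and a
#' manifest to `out_dir`. A directory holding a previous run is only
#' overwritten with `force = TRUE`; the same config and seed reproduce
#' identical outputs.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param out_dir Output directory.
#' @param seed Overrides the config seed if given.
#' @param force Overwrite an existing run directory.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL, force = FALSE) {
  config <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  seed <- seed %||% config$seed
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("output directory already holds a run; use force = TRUE to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- config_design(config)
  scenarios <- config_scenarios(config, design)
  counts <- config_counts(config)
  grid <- window_grid(design, config$window_ms)
  pairs <- config$pairs %||% roi_pairs(design)
  bands <- frequency_bands()
  bands <- bands[bands$band %in% unlist(config$bands), , drop = FALSE]

  cohort <- generate_cohort(design, scenarios, counts, master_seed = seed)
  tab <- window_gc_table(cohort, grid = grid, pairs = pairs, bands = bands,
                         p_max = config$p_max, filter_band = unlist(config$filter),
                         n_freq = config$n_freq, rule = config$gate_rule)
  nets <- binarize_networks(tab, pairs = pairs, n_perm = config$n_perm,
                            alpha = config$alpha,
                            cluster_alpha = config$cluster_alpha,
                            seed = seed)
  ms <- metric_series(nets, tab, rule = config$unreachable_rule)
  cd_sub <- subject_cd_series(tab, pairs)

  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
    p
  }
  wr(tab, "gc_table.tsv")
  for (g in names(nets$adjacency)) {
    for (b in names(nets$adjacency[[g]])) {
      wr(as.data.frame(nets$adjacency[[g]][[b]]),
         sprintf("adjacency_%s_%s.tsv", g, b))
    }
  }
  wr(ms$series, "metrics.csv")
  wr(ms$flow, "flow.csv")
  anova_tabs <- list()
  for (b in unique(cd_sub$band)) {
    wc <- per_window_anova(cd_sub[cd_sub$band == b, ],
                           alpha = config$anova$alpha,
                           correction = config$anova$correction,
                           min_span = config$anova$min_span)
    anova_tabs[[b]] <- wc
    wr(wc$table, sprintf("anova_%s.csv", b))
    wr(wc$spans, sprintf("anova_spans_%s.csv", b))
  }
  if (length(unique(tab$band)) >= 2) {
    for (metric in c("causal_density", "path_length")) {
      wr(phase_band_table(ms, metric = metric,
                          bands = unlist(config$bands)[1:2]),
         sprintf("phase_table_%s.csv", metric))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gcnet")),
    seed = seed,
    config = unclass(config),
    samples_per_window = grid$samples_per_window,
    n_task_windows = grid$n_task,
    n_baseline_windows = grid$n_baseline,
    trials_per_group = as.list(cohort_trial_counts(cohort)),
    gc_rows = nrow(tab),
    windows_differenced = sum(tab$differenced & tab$band == tab$band[1] &
                                tab$source == tab$source[1] & tab$target == tab$target[1]),
    gc_missing = sum(is.na(tab$gc)),
    files = names(paths)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- manifest_path
  invisible(paths)
}
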