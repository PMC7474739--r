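#' Nonoverlapping analysis-window grid
#'
#' Splits the task period into contiguous nonoverlapping windows (90
#' windows of 100 ms at the defaults) and the baseline period into
#' same-length baseline windows (10 at the defaults). The window length
#' must be an integer number of samples at the design's sampling rate.
#'
#' @param design A [trial_design()].
#' @param window_ms Window length in ms (default 100).
#' @return An object of class `window_grid`: per-window start samples
#'   (within the full trial) for task and baseline windows, the sample
#'   count per window, and a phase label per task window.
#' @export
window_grid <- function(design, window_ms = 100) {
  stopifnot(inherits(design, "trial_design"))
  fs <- design$sampling_rate
  spw <- window_ms * fs / 1000
  if (spw != round(spw)) {
    compatible <- c(100, 200, 250, 500, 1000)
    stop(sprintf(paste0("window of %g ms is not an integer sample count at %g Hz; ",
                        "compatible rates include %s Hz"),
                 window_ms, fs, paste(compatible[compatible * window_ms %% 1000 == 0],
                                      collapse = ", ")))
  }
  spw <- as.integer(spw)
  if (design$task_ms %% window_ms != 0 || design$baseline_ms %% window_ms != 0) {
    stop("task and baseline durations must be multiples of the window length")
  }
  n_task <- as.integer(design$task_ms / window_ms)
  n_base <- as.integer(design$baseline_ms / window_ms)
  task_starts <- design$baseline_n + (seq_len(n_task) - 1L) * spw + 1L
  base_starts <- (seq_len(n_base) - 1L) * spw + 1L
  win_onset_ms <- (seq_len(n_task) - 1L) * window_ms
  phase <- design$phase_names[findInterval(win_onset_ms,
                                           c(0, design$phase_boundaries_ms))]
  structure(list(window_ms = window_ms, samples_per_window = spw,
                 n_task = n_task, n_baseline = n_base,
                 task_starts = task_starts, base_starts = base_starts,
                 phase = phase, design = design),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d task + %d baseline windows of %g ms (%d samples)\n",
              x$n_task, x$n_baseline, x$window_ms, x$samples_per_window))
  invisible(x)
}

#' Slice a trial into analysis windows
#'
#' @param ts A `source_ts` (nodes x samples).
#' @param grid A [window_grid()].
#' @return List with `task` and `baseline`: each an ordered list of
#'   samples x nodes window matrices.
#' @export
slice_windows <- function(ts, grid) {
  stopifnot(inherits(grid, "window_grid"))
  spw <- grid$samples_per_window
  cut1 <- function(s) t(ts[, s:(s + spw - 1L), drop = FALSE])
  list(task = lapply(grid$task_starts, cut1),
       baseline = lapply(grid$base_starts, cut1))
}

#' Default region-of-interest pair set
#'
#' Every ordered (frontal source, parietal target) pair of the design:
#' 8 x 5 = 40 directed pairs at the default montage.
#'
#' @param design A [trial_design()].
#' @param sources,targets Node label vectors (defaults: frontal sources,
#'   parietal targets).
#' @return Data frame with columns `source`, `target`.
#' @export
roi_pairs <- function(design, sources = design$frontal, targets = design$parietal) {
  bad <- setdiff(c(sources, targets), design$nodes)
  if (length(bad)) stop("unknown node(s) in pair set: ", paste(bad, collapse = ", "))
  out <- expand.grid(target = targets, source = sources,
                     stringsAsFactors = FALSE)[, c("source", "target")]
  rownames(out) <- NULL
  if (anyDuplicated(paste(out$source, out$target))) stop("duplicate pairs")
  out
}

## R reference for the batch kernel: band-resolved spectral GC for all
## windows of one pair, after the per-window conditioning protocol.
gc_pair_windows_r <- function(x, starts, len, p_max, freq_hz, fs, rule = "both") {
  nf <- length(freq_hz)
  nw <- length(starts)
  f21 <- matrix(NA_real_, nw, nf)
  f12 <- matrix(NA_real_, nw, nf)
  order <- rep(NA_integer_, nw)
  flags <- matrix(0L, nw, 5L,
                  dimnames = list(NULL, c("differenced", "nonstationary",
                                          "usable", "clip21", "clip12")))
  for (wi in seq_len(nw)) {
    w <- x[starts[wi]:(starts[wi] + len - 1L), , drop = FALSE]
    pw <- preprocess_window(w, rule = rule)
    flags[wi, "differenced"] <- as.integer(pw$differenced)
    flags[wi, "nonstationary"] <- as.integer(pw$nonstationary)
    if (!pw$usable) next
    p <- suppressWarnings(select_order_bic(pw$window, p_max))
    if (is.na(p)) next
    order[wi] <- p
    model <- tryCatch(fit_var(pw$window, p), error = function(e) NULL)
    if (is.null(model)) next
    sgc <- spectral_gc_pair(model, fs, freq_hz)
    if (!sgc$usable) next
    f21[wi, ] <- sgc$f[, 1]
    f12[wi, ] <- sgc$f[, 2]
    flags[wi, "usable"] <- 1L
    flags[wi, "clip21"] <- sgc$clipped[1]
    flags[wi, "clip12"] <- sgc$clipped[2]
  }
  list(f21 = f21, f12 = f12, order = order, flags = flags)
}

band_means <- function(fmat, freq_hz, bands) {
  out <- matrix(NA_real_, nrow(fmat), nrow(bands),
                dimnames = list(NULL, bands$band))
  for (b in seq_len(nrow(bands))) {
    sel <- freq_hz >= bands$low[b] & freq_hz < bands$high[b]
    if (!any(sel)) stop("frequency grid has no points in band ", bands$band[b])
    out[, b] <- rowMeans(fmat[, sel, drop = FALSE])
  }
  out
}

#' Per-window band-averaged causality table for a cohort
#'
#' Runs the full per-trial protocol — zero-phase bandpass, baseline
#' correction, window conditioning (detrend, stationarity gate, first
#' difference where gated), BIC order selection, bivariate VAR fit and
#' spectral causality — for every requested node pair, and returns a
#' long-format table of band-averaged values for every task and baseline
#' window. Both directions of each pair are reported. Unusable windows
#' appear with `NA` causality (never 0) and carry their flags.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param grid A [window_grid()] (default: the cohort design's grid).
#' @param pairs Data frame of directed pairs (default [roi_pairs()]).
#' @param bands Band table from [frequency_bands()], optionally subset.
#' @param p_max Largest candidate VAR order (default 3, keeping the
#'   bivariate regression well-posed on 50-sample windows).
#' @param filter_band `c(low, high)` Hz for the trial bandpass, or `NULL`
#'   to skip filtering.
#' @param n_freq Number of spectral grid points.
#' @param rule Stationarity-gate rule.
#' @param engine `"cpp"` (compiled batch kernel) or `"r"` (reference
#'   implementation); both produce the same numbers.
#' @return Data frame with columns `group`, `subject`, `trial`, `segment`
#'   (`"task"`/`"baseline"`), `window`, `source`, `target`, `band`, `gc`,
#'   `order`, `differenced`, `nonstationary`, `usable`.
#' @export
window_gc_table <- function(cohort, grid = NULL, pairs = NULL,
                            bands = frequency_bands()[c(1, 4), ],
                            p_max = 3L, filter_band = c(1, 60),
                            n_freq = 128L, rule = "both",
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cohort, "gc_cohort"))
  design <- cohort$design
  grid <- grid %||% window_grid(design)
  pairs <- pairs %||% roi_pairs(design)
  fs <- design$sampling_rate
  freq_hz <- default_grid(fs, n_freq)
  omega <- 2 * pi * freq_hz / fs
  starts <- c(grid$base_starts, grid$task_starts)
  segment <- rep(c("baseline", "task"), c(grid$n_baseline, grid$n_task))
  window_id <- c(seq_len(grid$n_baseline), seq_len(grid$n_task))
  len <- grid$samples_per_window
  rule_code <- match(rule, c("both", "either")) - 1L

  ## unordered node pairs to evaluate (each yields both directions)
  key <- unique(t(apply(cbind(pairs$source, pairs$target), 1L, sort)))
  out <- vector("list", 2048L)
  oi <- 0L
  for (g in names(cohort$groups)) {
    subjects <- cohort$groups[[g]]$subjects
    for (s in names(subjects)) {
      trials <- subjects[[s]]$trials
      for (tr in seq_along(trials)) {
        x <- trials[[tr]]
        if (!is.null(filter_band)) x <- bandpass_filter(x, filter_band[1], filter_band[2])
        x <- baseline_correct(x, design$baseline_n)
        xt <- t(unclass(x))
        for (kp in seq_len(nrow(key))) {
          n1 <- key[kp, 1]; n2 <- key[kp, 2]
          xx <- xt[, c(n1, n2), drop = FALSE]
          res <- if (engine == "cpp") {
            gc_pair_windows_cpp(xx, as.integer(starts), len, as.integer(p_max),
                                omega, rule_code)
          } else {
            gc_pair_windows_r(xx, starts, len, p_max, freq_hz, fs, rule)
          }
          usable <- res$flags[, 3] == 1L
          bm21 <- band_means(res$f21, freq_hz, bands)  # n2 -> n1
          bm12 <- band_means(res$f12, freq_hz, bands)  # n1 -> n2
          bm21[!usable, ] <- NA_real_
          bm12[!usable, ] <- NA_real_
          nw <- length(starts)
          nb <- nrow(bands)
          oi <- oi + 1L
          out[[oi]] <- data.frame(
            group = g, subject = s, trial = tr,
            segment = rep(segment, 2L * nb),
            window = rep(window_id, 2L * nb),
            source = rep(c(n1, n2), each = nw * nb),
            target = rep(c(n2, n1), each = nw * nb),
            band = rep(rep(bands$band, each = nw), 2L),
            gc = c(as.vector(bm12), as.vector(bm21)),
            order = rep(as.integer(res$order), 2L * nb),
            differenced = rep(res$flags[, 1] == 1L, 2L * nb),
            nonstationary = rep(res$flags[, 2] == 1L, 2L * nb),
            usable = rep(usable, 2L * nb))
        }
      }
    }
  }
  tab <- do.call(rbind, out[seq_len(oi)])
  ## keep requested directed pairs plus their reverses (both directions are
  ## informative: the reverse direction is the negative control)
  want <- unique(c(paste(pairs$source, pairs$target),
                   paste(pairs$target, pairs$source)))
  tab <- tab[paste(tab$source, tab$target) %in% want, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "grid") <- grid
  attr(tab, "bands") <- bands
  attr(tab, "pairs") <- pairs
  tab
}

#' Cluster-based permutation test of task vs. baseline values
#'
#' For one directed pair: each task window's values across trials are
#' contrasted with the pooled baseline-window values by a one-sided Welch
#' t statistic ("significantly above baseline"). Windows exceeding the
#' cluster-forming threshold are grouped into contiguous-in-time clusters
#' whose mass (sum of t) is compared against the permutation distribution
#' of the maximum cluster mass, obtained by permuting the window labels
#' within each trial (task and baseline values are exchangeable within a
#' trial under the null). Windows in clusters with permutation
#' `p < alpha` are marked significant.
#'
#' @param task Trials x task-windows matrix of causality values (`NA`
#'   allowed, treated as missing).
#' @param baseline Trials x baseline-windows matrix.
#' @param n_perm Number of permutations (>= 100; default 200, which limits
#'   the attainable p-resolution to 1/200).
#' @param alpha Cluster significance level.
#' @param cluster_alpha Cluster-forming (pointwise) threshold.
#' @param seed Permutation seed; fixed seed gives identical masks.
#' @return Logical mask over task windows, with attributes `clusters`
#'   (data frame: start, end, mass, p) and `t` (observed statistics).
#' @export
cluster_permutation_test <- function(task, baseline, n_perm = 200L,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = NULL) {
  task <- as.matrix(task)
  baseline <- as.matrix(baseline)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!ncol(baseline) || !nrow(baseline)) stop("baseline pool must be nonempty")
  W <- ncol(task)
  B <- ncol(baseline)
  M <- cbind(baseline, task)               # trials x (B + W)
  n_tr <- nrow(M)

  window_t <- function(Mp) {
    bvals <- as.vector(Mp[, seq_len(B)])
    bvals <- bvals[!is.na(bvals)]
    nb <- length(bvals)
    if (nb < 2L) return(rep(0, W))
    mb <- mean(bvals)
    vb <- stats::var(bvals)
    tv <- Mp[, B + seq_len(W), drop = FALSE]
    nt <- colSums(!is.na(tv))
    mt <- colMeans(tv, na.rm = TRUE)
    vt <- col_vars(tv, na.rm = TRUE)
    se <- sqrt(vt / nt + vb / nb)
    tt <- (mt - mb) / se
    tt[!is.finite(tt) | nt < 2L] <- 0
    df <- (vt / nt + vb / nb)^2 /
      ((vt / nt)^2 / pmax(nt - 1, 1) + (vb / nb)^2 / (nb - 1))
    attr(tt, "df") <- df
    tt
  }

  cluster_masses <- function(tt) {
    df <- attr(tt, "df")
    thr <- stats::qt(1 - cluster_alpha, pmax(df, 1))
    supra <- is.finite(tt) & tt > thr
    if (!any(supra)) return(data.frame(start = integer(), end = integer(),
                                       mass = numeric()))
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(which(keep), function(i)
                 sum(tt[starts[i]:ends[i]]), numeric(1)))
  }

  t_obs <- window_t(M)
  if (all(t_obs == 0)) {
    warning("zero-variance inputs; no significance assessed")
    mask <- rep(FALSE, W)
    attr(mask, "clusters") <- data.frame(start = integer(), end = integer(),
                                         mass = numeric(), p = numeric())
    attr(mask, "t") <- t_obs
    return(mask)
  }
  cl <- cluster_masses(t_obs)

  perm_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- t(vapply(seq_len(n_tr), function(r) sample.int(B + W), integer(B + W)))
      Mp <- matrix(M[cbind(rep(seq_len(n_tr), B + W), as.vector(idx))], n_tr, B + W)
      cm <- cluster_masses(window_t(Mp))
      if (nrow(cm)) max(cm$mass) else 0
    }, numeric(1))
  })

  cl$p <- vapply(cl$mass, function(m) (1 + sum(perm_max >= m)) / (n_perm + 1),
                 numeric(1))
  mask <- rep(FALSE, W)
  for (i in seq_len(nrow(cl))) {
    if (cl$p[i] < alpha) mask[cl$start[i]:cl$end[i]] <- TRUE
  }
  attr(mask, "clusters") <- cl
  attr(mask, "t") <- t_obs
  mask
}

#' Binary directed networks from a causality table
#'
#' For every group, band and directed pair, contrasts the per-window task
#' causality with the baseline pool via [cluster_permutation_test()] and
#' sets the pair's edge to 1 in every significant window. Missing
#' (unusable) windows are never imputed; their coverage is reported.
#'
#' @param gc_table A [window_gc_table()] result.
#' @param pairs Directed pairs to binarize (default: the table's pair
#'   attribute). Every requested pair must be present in the table.
#' @param n_perm,alpha,cluster_alpha Test parameters (see
#'   [cluster_permutation_test()]).
#' @param seed Master seed; per-(group, band, pair) seeds are derived from
#'   it, so a fixed seed gives identical networks.
#' @return An object of class `binary_networks`: per group and band a
#'   windows x pairs 0/1 adjacency matrix, plus coverage matrices,
#'   cluster details, the pair list and test provenance.
#' @export
binarize_networks <- function(gc_table, pairs = attr(gc_table, "pairs"),
                              n_perm = 200L, alpha = 0.05,
                              cluster_alpha = 0.05, seed = 1L) {
  grid <- attr(gc_table, "grid")
  if (is.null(grid)) stop("gc_table must come from window_gc_table()")
  groups <- unique(gc_table$group)
  bands <- unique(gc_table$band)
  pair_names <- paste0(pairs$source, "->", pairs$target)
  n_combo <- length(groups) * length(bands) * nrow(pairs)
  seeds <- derive_seeds(seed, n_combo)
  si <- 0L
  adjacency <- list()
  coverage <- list()
  clusters <- list()
  for (g in groups) {
    for (b in bands) {
      adj <- matrix(0L, grid$n_task, nrow(pairs),
                    dimnames = list(NULL, pair_names))
      cov <- matrix(NA_real_, grid$n_task, nrow(pairs),
                    dimnames = list(NULL, pair_names))
      for (pi in seq_len(nrow(pairs))) {
        si <- si + 1L
        sub <- gc_table[gc_table$group == g & gc_table$band == b &
                          gc_table$source == pairs$source[pi] &
                          gc_table$target == pairs$target[pi], , drop = FALSE]
        if (!nrow(sub)) {
          stop(sprintf("no causality values for pair %s in group %s, band %s",
                       pair_names[pi], g, b))
        }
        trial_key <- paste(sub$subject, sub$trial)
        task_rows <- sub$segment == "task"
        task <- matrix(NA_real_, length(unique(trial_key)), grid$n_task)
        base <- matrix(NA_real_, length(unique(trial_key)), grid$n_baseline)
        tk <- match(trial_key, unique(trial_key))
        task[cbind(tk[task_rows], sub$window[task_rows])] <- sub$gc[task_rows]
        base[cbind(tk[!task_rows], sub$window[!task_rows])] <- sub$gc[!task_rows]
        mask <- cluster_permutation_test(task, base, n_perm = n_perm,
                                         alpha = alpha,
                                         cluster_alpha = cluster_alpha,
                                         seed = seeds[si])
        adj[, pi] <- as.integer(mask)
        cov[, pi] <- colMeans(!is.na(task))
        clusters[[paste(g, b, pair_names[pi], sep = "|")]] <- attr(mask, "clusters")
      }
      adjacency[[g]][[b]] <- adj
      coverage[[g]][[b]] <- cov
    }
  }
  structure(list(adjacency = adjacency, coverage = coverage,
                 clusters = clusters, pairs = pairs, grid = grid,
                 provenance = list(alpha = alpha, cluster_alpha = cluster_alpha,
                                   n_perm = n_perm, seed = seed,
                                   cluster_rule = "contiguous windows, one-sided Welch t vs pooled baseline")),
            class = "binary_networks")
}

#' @export
print.binary_networks <- function(x, ...) {
  cat(sprintf("<binary_networks> %d group(s) x %d band(s), %d windows x %d pairs\n",
              length(x$adjacency), length(x$adjacency[[1]]),
              x$grid$n_task, nrow(x$pairs)))
  for (g in names(x$adjacency)) {
    for (b in names(x$adjacency[[g]])) {
      cat(sprintf("  %s / %s: edge rate %.3f\n", g, b, mean(x$adjacency[[g]][[b]])))
    }
  }
  invisible(x)
}
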