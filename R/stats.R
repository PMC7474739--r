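#' Significance stars
#'
#' The conventional legend: `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

## one-way ANOVA from raw vectors; returns c(F, df1, df2, p).
## Cross-checked against stats::aov in the test suite.
oneway_f <- function(value, group) {
  ok <- !is.na(value)
  value <- value[ok]
  group <- group[ok]
  g <- unique(group)
  k <- length(g)
  n <- length(value)
  if (k < 2L || n - k < 1L) return(c(NA, NA, NA, NA))
  gm <- mean(value)
  means <- tapply(value, group, mean)
  sizes <- tapply(value, group, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((value - means[match(group, names(means))])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw <= 1e-24 * max(ssb, 1e-300)) {
    ## zero within-group variance: exact ties
    if (ssb <= 1e-24) return(c(0, df1, df2, 1))   # all values identical
    return(c(Inf, df1, df2, 0))                    # perfectly separated; degenerate
  }
  f <- (ssb / df1) / (ssw / df2)
  c(f, df1, df2, stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Per-window one-way ANOVA between groups
#'
#' For each task window, a one-way ANOVA compares the subject-level metric
#' values across groups. Contiguous significant spans (the shaded regions
#' of a metric time course) require at least `min_span` consecutive
#' significant windows; the per-window mask itself is thresholded on the
#' (optionally corrected) p-values.
#'
#' @param df Data frame with columns `group`, `window`, `value` (one row
#'   per subject per window; a `subject` column is allowed and ignored).
#' @param alpha Significance level.
#' @param correction `"none"` (default) or `"BH"` (Benjamini-Hochberg over
#'   windows).
#' @param min_span Minimum run length for a reported span.
#' @return An object of class `window_comparison`: `table` (window,
#'   statistic, df1, df2, p, p_adj, significant, degenerate), `spans`
#'   (start, end), plus the settings.
#' @export
per_window_anova <- function(df, alpha = 0.05, correction = c("none", "BH"),
                             min_span = 2L) {
  correction <- match.arg(correction)
  stopifnot(all(c("group", "window", "value") %in% names(df)))
  windows <- sort(unique(df$window))
  res <- t(vapply(windows, function(w) {
    sel <- df$window == w
    oneway_f(df$value[sel], df$group[sel])
  }, numeric(4)))
  tab <- data.frame(window = windows, statistic = res[, 1],
                    df1 = res[, 2], df2 = res[, 3], p = res[, 4])
  tab$degenerate <- is.infinite(tab$statistic)
  tab$p_adj <- if (correction == "BH") stats::p.adjust(tab$p, "BH") else tab$p
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  r <- rle(tab$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_span
  spans <- data.frame(start = tab$window[starts[keep]],
                      end = tab$window[ends[keep]])
  structure(list(table = tab, spans = spans, alpha = alpha,
                 correction = correction, min_span = min_span),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat(sprintf("<window_comparison> %d windows, %d significant at alpha %g (%s)\n",
              nrow(x$table), sum(x$table$significant), x$alpha, x$correction))
  if (nrow(x$spans)) {
    cat("  spans:", paste(sprintf("%d-%d", x$spans$start, x$spans$end),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Phase-by-band summary table of a metric series
#'
#' For each group and task phase: mean and standard deviation of the
#' metric over the phase's windows per band, and a Welch two-sample test
#' between the two bands' window values, with the conventional
#' significance stars. The observation unit is the window-level group
#' value; phase SDs therefore describe within-phase variation over time.
#'
#' @param ms A [metric_series()] result or its `series` data frame.
#' @param metric Which metric to summarise (`"causal_density"` or
#'   `"path_length"`).
#' @param bands Character vector of exactly two band names to compare.
#' @return Data frame: group, metric, phase, per-band mean/sd columns,
#'   `statistic`, `p`, `stars`, `degenerate`.
#' @export
phase_band_table <- function(ms, metric = "causal_density",
                             bands = c("theta", "gamma")) {
  df <- if (inherits(ms, "metric_series")) ms$series else ms
  stopifnot(length(bands) == 2L)
  df <- df[df$metric == metric & df$band %in% bands, , drop = FALSE]
  if (!nrow(df)) stop("no rows for metric '", metric, "' and the requested bands")
  phases <- unique(df$phase)
  rows <- list()
  for (g in unique(df$group)) {
    for (ph in phases) {
      x1 <- df$value[df$group == g & df$phase == ph & df$band == bands[1]]
      x2 <- df$value[df$group == g & df$phase == ph & df$band == bands[2]]
      if (!length(x1) || !length(x2)) stop("empty phase '", ph, "' for group ", g)
      degenerate <- stats::sd(x1) < 1e-12 && stats::sd(x2) < 1e-12
      if (degenerate) {
        stat <- NA_real_
        p <- if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else NA_real_
      } else {
        tt <- stats::t.test(x1, x2)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
      row <- data.frame(group = g, metric = metric, phase = ph,
                        mean_1 = mean(x1), sd_1 = stats::sd(x1),
                        mean_2 = mean(x2), sd_2 = stats::sd(x2),
                        statistic = stat, p = p, stars = p_stars(p),
                        degenerate = degenerate)
      names(row)[4:7] <- c(paste0(bands[1], c("_mean", "_sd")),
                           paste0(bands[2], c("_mean", "_sd")))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a phase-by-band table as text
#'
#' @param tab A [phase_band_table()] result.
#' @return Character vector of formatted lines (also printed).
#' @export
format_phase_table <- function(tab) {
  bands <- sub("_mean$", "", grep("_mean$", names(tab), value = TRUE))
  lines <- character(0)
  for (g in unique(tab$group)) {
    lines <- c(lines, sprintf("%s (%s)", g, tab$metric[1]),
               sprintf("  %-22s %14s %14s   p", "phase",
                       paste0(bands[1], "-band"), paste0(bands[2], "-band")))
    sub <- tab[tab$group == g, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      pcell <- if (!is.na(sub$stars[i]) && nzchar(sub$stars[i])) sub$stars[i] else
        formatC(sub$p[i], digits = 3, format = "g")
      lines <- c(lines, sprintf("  %-22s %6.2f ± %.2f  %6.2f ± %.2f   %s",
                                sub$phase[i],
                                sub[[paste0(bands[1], "_mean")]][i],
                                sub[[paste0(bands[1], "_sd")]][i],
                                sub[[paste0(bands[2], "_mean")]][i],
                                sub[[paste0(bands[2], "_sd")]][i],
                                pcell))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
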