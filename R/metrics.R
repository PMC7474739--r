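#' Adjacency matrix over the node set induced by a pair list
#'
#' @param mask 0/1 (or logical) vector over pairs, one entry per row of
#'   `pairs`.
#' @param pairs Data frame with `source`, `target`.
#' @param nodes Node set (default: union of pair nodes, in first-seen
#'   order).
#' @return Square 0/1 matrix with `nodes` dimnames.
#' @export
adjacency_from_pairs <- function(mask, pairs, nodes = NULL) {
  nodes <- nodes %||% unique(c(pairs$source, pairs$target))
  adj <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  on <- as.logical(mask)
  adj[cbind(match(pairs$source[on], nodes), match(pairs$target[on], nodes))] <- 1L
  adj
}

#' Directed unweighted shortest-path matrix
#'
#' Breadth-first search from every node of a binary directed network.
#' Unreachable pairs are marked `NA` (distinctly, not as a number);
#' the diagonal is `NA` as well (self-distances are excluded from the
#' path-length average).
#'
#' @param adj Square 0/1 adjacency matrix.
#' @return Integer matrix `m` with `m[i, j]` the shortest path length from
#'   i to j.
#' @export
shortest_path_matrix <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj), all(adj %in% c(0, 1)))
  out <- matrix(NA_integer_, n, n, dimnames = dimnames(adj))
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    frontier <- s
    d <- 0L
    visited <- logical(n)
    visited[s] <- TRUE
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      dist[nxt] <- d
      visited[nxt] <- TRUE
      frontier <- nxt
    }
    dist[s] <- NA_integer_
    out[s, ] <- dist
  }
  out
}

## Brute-force all-pairs reference (Floyd-Warshall); used as the oracle in
## equivalence checks, never as the production path.
floyd_warshall_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  out <- matrix(NA_integer_, n, n, dimnames = dimnames(adj))
  out[is.finite(d)] <- as.integer(d[is.finite(d)])
  diag(out) <- NA_integer_
  out
}

#' Characteristic path length of a binary directed network
#'
#' `L = (1/n) sum_i L_i` with `L_i = sum_{j != i} m_ij / (n - 1)`, the
#' average minimum number of edges between ordered node pairs. A short
#' characteristic path length indicates higher parallel information
#' transfer. The handling of unreachable pairs is configurable:
#' `"zero"` (default) counts them as 0 — the convention under which sparse
#' networks can have `L < 1`; `"exclude"` averages over reachable pairs
#' only; `"harmonic"` returns the inverse of the mean inverse distance
#' (unreachable contributing 0). The reachable-pair fraction is always
#' reported alongside.
#'
#' @param m Shortest-path matrix from [shortest_path_matrix()], or a 0/1
#'   adjacency matrix (distances are then computed first).
#' @param rule Unreachable-pair rule.
#' @return An object of class `path_length`: `L`, per-node `L_i`, `m`,
#'   `reachable_fraction`, `rule`.
#' @export
characteristic_path_length <- function(m, rule = c("zero", "exclude", "harmonic")) {
  rule <- match.arg(rule)
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("path length needs at least 2 nodes")
  if (all(m %in% c(0, 1)) && isTRUE(any(diag(m) == 0))) {
    ## looks like an adjacency matrix
    m <- shortest_path_matrix(m)
  }
  off <- !diag(n)
  reachable_fraction <- mean(!is.na(m[off]))
  L_i <- switch(rule,
    zero = rowSums(m, na.rm = TRUE) / (n - 1),
    exclude = {
      li <- rowMeans(m, na.rm = TRUE)
      li[is.nan(li)] <- NA_real_
      li
    },
    harmonic = {
      inv <- 1 / m
      inv[is.na(inv)] <- 0
      diag(inv) <- 0
      rs <- rowSums(inv) / (n - 1)
      1 / rs
    })
  L <- switch(rule,
    zero = mean(L_i),
    exclude = if (all(is.na(L_i))) 0 else mean(L_i, na.rm = TRUE),
    harmonic = {
      inv <- 1 / m
      inv[is.na(inv)] <- 0
      if (mean(inv[off]) == 0) Inf else 1 / mean(inv[off])
    })
  structure(list(L = L, L_i = L_i, m = m,
                 reachable_fraction = reachable_fraction, rule = rule),
            class = "path_length")
}

#' @export
print.path_length <- function(x, ...) {
  cat(sprintf("<path_length> L = %.4f (%s rule), reachable fraction %.2f\n",
              x$L, x$rule, x$reachable_fraction))
  invisible(x)
}

#' Causal density
#'
#' The mean directed causality over ordered node pairs — a tightness
#' measure of the causal network; higher values mean more closely coupled
#' nodes. Accepts either a square matrix of pairwise values (off-diagonal
#' entries are used) or a vector of per-pair values. Missing values are
#' excluded and counted, never imputed.
#'
#' @param x Square numeric matrix (diagonal ignored) or numeric vector of
#'   directed pair values (nats).
#' @param estimator Label recorded with the result (`"bivariate"` by
#'   default; `"conditional"` when the values come from the conditional
#'   time-domain estimator).
#' @return An object of class `causal_density`: `cd`, `n_values`,
#'   `n_missing`, `estimator`.
#' @export
causal_density <- function(x, estimator = "bivariate") {
  vals <- if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("matrix input must be square")
    x[!diag(nrow(x))]
  } else {
    as.numeric(x)
  }
  n_missing <- sum(is.na(vals))
  if (n_missing == length(vals)) stop("all causality values missing")
  cd <- mean(vals, na.rm = TRUE)
  structure(list(cd = cd, n_values = length(vals) - n_missing,
                 n_missing = n_missing, estimator = estimator),
            class = "causal_density")
}

#' @export
print.causal_density <- function(x, ...) {
  cat(sprintf("<causal_density> CD = %.4f nats (%s, %d values, %d missing)\n",
              x$cd, x$estimator, x$n_values, x$n_missing))
  invisible(x)
}

#' Causal flow per node
#'
#' `flow(i) = sum of outgoing values from i - sum of incoming values to i`;
#' on a binary network this is out-degree minus in-degree. Positive flow
#' marks a causal source, negative a causal sink; flows always sum to zero
#' over the node set.
#'
#' @param x Square matrix of directed values (binary adjacency or
#'   causality), rows = sources. `NA` entries contribute nothing.
#' @param node Optional node label or index; if given, that node's flow is
#'   returned as a scalar.
#' @return Named numeric vector of flows (or a scalar for one `node`).
#' @export
causal_flow <- function(x, node = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == ncol(x))
  diag(x) <- NA
  flow <- rowSums(x, na.rm = TRUE) - colSums(x, na.rm = TRUE)
  if (!is.null(node)) {
    if (is.character(node)) {
      if (!node %in% rownames(x)) stop("unknown node: ", node)
      return(flow[[node]])
    }
    return(flow[[node]])
  }
  flow
}

#' Per-window network metric series
#'
#' Computes, for every group, band and task window: the causal density of
#' the trial-averaged causality over the configured pairs, and the
#' characteristic path length of the binary network; plus per-node causal
#' flow (out-degree minus in-degree of the binary network). Phase labels
#' from the window grid are attached.
#'
#' @param networks A [binarize_networks()] result.
#' @param gc_table The matching [window_gc_table()].
#' @param rule Unreachable-pair rule for the path length.
#' @return An object of class `metric_series`: `series` (data frame:
#'   group, band, window, phase, metric, value) and `flow` (data frame:
#'   group, band, window, phase, node, flow).
#' @export
metric_series <- function(networks, gc_table, rule = "zero") {
  stopifnot(inherits(networks, "binary_networks"))
  grid <- networks$grid
  if (!identical(grid$n_task, attr(gc_table, "grid")$n_task)) {
    stop("networks and gc_table are not aligned on the same window grid")
  }
  pairs <- networks$pairs
  nodes <- unique(c(pairs$source, pairs$target))
  rows <- list()
  frows <- list()
  for (g in names(networks$adjacency)) {
    for (b in names(networks$adjacency[[g]])) {
      adj <- networks$adjacency[[g]][[b]]
      sub <- gc_table[gc_table$group == g & gc_table$band == b &
                        gc_table$segment == "task", , drop = FALSE]
      pk <- match(paste(sub$source, sub$target),
                  paste(pairs$source, pairs$target))
      sub <- sub[!is.na(pk), , drop = FALSE]
      pk <- pk[!is.na(pk)]
      ## mean causality per (window, pair) across trials
      mg <- tapply(sub$gc, list(sub$window, pk), mean, na.rm = TRUE)
      for (w in seq_len(grid$n_task)) {
        cd <- causal_density(as.numeric(mg[as.character(w), ]))$cd
        net_w <- adjacency_from_pairs(adj[w, ], pairs, nodes)
        pl <- characteristic_path_length(shortest_path_matrix(net_w), rule)$L
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, band = b, window = w, phase = grid$phase[w],
          metric = c("causal_density", "path_length"), value = c(cd, pl))
        fl <- causal_flow(net_w)
        frows[[length(frows) + 1L]] <- data.frame(
          group = g, band = b, window = w, phase = grid$phase[w],
          node = names(fl), flow = as.numeric(fl))
      }
    }
  }
  structure(list(series = do.call(rbind, rows), flow = do.call(rbind, frows),
                 grid = grid, pairs = pairs, rule = rule),
            class = "metric_series")
}

#' Subject-level causal-density series
#'
#' Per subject, band and window: the mean causality over the configured
#' directed pairs and the subject's trials — the observation unit of the
#' per-window group comparison.
#'
#' @param gc_table A [window_gc_table()] result.
#' @param pairs Directed pairs to average over (default: the table's
#'   requested pair set).
#' @param segment `"task"` (default) or `"baseline"`.
#' @return Data frame: `group`, `subject`, `band`, `window`, `value`.
#' @export
subject_cd_series <- function(gc_table, pairs = attr(gc_table, "pairs"),
                              segment = "task") {
  sub <- gc_table[gc_table$segment == segment, , drop = FALSE]
  pk <- paste(sub$source, sub$target) %in% paste(pairs$source, pairs$target)
  sub <- sub[pk, , drop = FALSE]
  agg <- stats::aggregate(gc ~ group + subject + band + window, data = sub,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  names(agg)[names(agg) == "gc"] <- "value"
  agg[order(agg$group, agg$subject, agg$band, agg$window), , drop = FALSE]
}
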