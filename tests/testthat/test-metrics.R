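test_that("shortest paths agree with brute force and handle unreachability", {
  ## 3-node directed cycle: distances are 1, 2 around the ring
  cyc <- matrix(0L, 3, 3)
  cyc[cbind(1:3, c(2, 3, 1))] <- 1L
  m <- shortest_path_matrix(cyc)
  expect_equal(m[1, 2], 1L)
  expect_equal(m[1, 3], 2L)
  expect_equal(m[3, 2], 2L)
  expect_true(all(is.na(diag(m))))
  ## empty graph: everything unreachable
  m0 <- shortest_path_matrix(matrix(0L, 4, 4))
  expect_true(all(is.na(m0)))
  ## oracle: Floyd-Warshall on random digraphs (and igraph as referee)
  set.seed(121)
  for (i in 1:100) {
    adj <- rand_digraph(10, 0.2)
    expect_identical(shortest_path_matrix(adj),
                     gcnet:::floyd_warshall_distances(adj))
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    set.seed(122)
    adj <- rand_digraph(12, 0.15)
    gi <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    di <- igraph::distances(gi, mode = "out")
    di[is.infinite(di)] <- NA
    diag(di) <- NA
    expect_equal(unname(shortest_path_matrix(adj)), unname(di),
                 ignore_attr = TRUE)
  }
})

test_that("characteristic path length follows its averaging rule", {
  cyc <- matrix(0L, 3, 3)
  cyc[cbind(1:3, c(2, 3, 1))] <- 1L
  expect_equal(characteristic_path_length(shortest_path_matrix(cyc))$L, 1.5)
  ## complete digraph: all distances 1
  comp <- matrix(1L, 4, 4); diag(comp) <- 0L
  expect_equal(characteristic_path_length(shortest_path_matrix(comp))$L, 1)
  ## empty graph under the zero rule
  empty <- shortest_path_matrix(matrix(0L, 4, 4))
  pl <- characteristic_path_length(empty, rule = "zero")
  expect_equal(pl$L, 0)
  expect_equal(pl$reachable_fraction, 0)
  ## sparse graphs can have L below 1 under the zero rule
  one_edge <- matrix(0L, 4, 4); one_edge[1, 2] <- 1L
  expect_lt(characteristic_path_length(shortest_path_matrix(one_edge))$L, 1)
  ## rules differ as documented
  chain <- matrix(0L, 3, 3); chain[1, 2] <- chain[2, 3] <- 1L
  mch <- shortest_path_matrix(chain)
  expect_equal(characteristic_path_length(mch, "zero")$L,
               mean(c(1 + 2, 1, 0) / 2))
  expect_equal(characteristic_path_length(mch, "exclude")$L,
               mean(c(mean(c(1, 2)), 1)))
  expect_error(characteristic_path_length(matrix(NA_integer_, 1, 1)), "at least 2")
})

test_that("path length is invariant under node relabeling", {
  set.seed(131)
  for (i in 1:20) {
    adj <- rand_digraph(8, 0.25)
    perm <- sample(8)
    L1 <- characteristic_path_length(shortest_path_matrix(adj))$L
    L2 <- characteristic_path_length(shortest_path_matrix(adj[perm, perm]))$L
    expect_equal(L1, L2)
  }
})

test_that("causal density is the mean over ordered pairs", {
  expect_equal(causal_density(matrix(0, 3, 3))$cd, 0)
  cm <- matrix(0.7, 3, 3)
  expect_equal(causal_density(cm)$cd, 0.7)
  single <- matrix(0, 3, 3); single[1, 2] <- 0.6
  expect_equal(causal_density(single)$cd, 0.1)
  ## missing entries are excluded and counted, never imputed
  withna <- single; withna[2, 1] <- NA
  res <- causal_density(withna)
  expect_equal(res$n_missing, 1L)
  expect_equal(res$cd, 0.6 / 5)
  expect_error(causal_density(matrix(NA_real_, 2, 2)), "all causality values missing")
  ## monotonicity: filling a zero with a positive value never lowers CD
  set.seed(141)
  for (i in 1:20) {
    g <- matrix(runif(16), 4, 4); diag(g) <- 0
    z <- which(g == 0 | upper.tri(g), arr.ind = TRUE)[1, ]
    g2 <- g; g2[z[1], z[2]] <- g[z[1], z[2]] + runif(1)
    expect_gte(causal_density(g2)$cd, causal_density(g)$cd)
  }
})

test_that("causal flow is out minus in and conserves to zero", {
  sym <- matrix(0.4, 4, 4); diag(sym) <- 0
  expect_true(all(causal_flow(sym) == 0))
  ## star with hub -> leaves: hub flow k, leaves -1
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L
  fl <- causal_flow(star)
  expect_equal(unname(fl[1]), 4)
  expect_true(all(fl[2:5] == -1))
  set.seed(151)
  g <- matrix(runif(25), 5, 5)
  expect_lt(abs(sum(causal_flow(g))), 1e-10)
  rownames(g) <- colnames(g) <- letters[1:5]
  expect_equal(causal_flow(g, "a"), unname(causal_flow(g)[1]))
  expect_error(causal_flow(g, "z"), "unknown node")
})

test_that("metric series aligns windows, phases and groups", {
  d <- trial_design(frontal = c("F1", "F2"), parietal = c("P1", "P2"))
  scen <- coupling_scenario(coupling("F1", "P1", "theta", 3000, 6000, 0.35))
  cohort <- generate_cohort(d, list(g = scen),
                            list(g = list(n_subjects = 2L, trials_per_subject = 4L)),
                            master_seed = 17)
  tab <- window_gc_table(cohort, bands = frequency_bands()[1, , drop = FALSE],
                         pairs = roi_pairs(d))
  nets <- binarize_networks(tab, n_perm = 100, seed = 7)
  ms <- metric_series(nets, tab)
  cd <- ms$series[ms$series$metric == "causal_density", ]
  pl <- ms$series[ms$series$metric == "path_length", ]
  expect_equal(nrow(cd), 90L)
  expect_equal(nrow(pl), 90L)
  expect_equal(unique(cd$phase[cd$window <= 30]), "premise_coding")
  expect_equal(unique(cd$phase[cd$window > 60]), "conclusion")
  expect_true(all(is.finite(cd$value)))
  ## flow table covers every node and window and sums to zero per window
  fl <- ms$flow
  expect_equal(nrow(fl), 90L * 4L)
  sums <- tapply(fl$flow, fl$window, sum)
  expect_true(all(abs(sums) < 1e-10))
  ## the designed coupling raises causal density inside its interval
  expect_gt(mean(cd$value[cd$window %in% 31:60]),
            mean(cd$value[cd$window %in% 61:90]))
})

test_that("subject-level causal density has one value per subject, band and window", {
  d <- pair_design2()
  scen <- coupling_scenario()
  cohort <- generate_cohort(d, list(g = scen),
                            list(g = list(n_subjects = 3L, trials_per_subject = 2L)),
                            master_seed = 19)
  tab <- window_gc_table(cohort, bands = frequency_bands()[1, , drop = FALSE],
                         pairs = data.frame(source = "F1", target = "P1"))
  cd <- subject_cd_series(tab)
  expect_equal(nrow(cd), 3L * 90L)
  expect_true(all(table(cd$subject) == 90L))
})
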