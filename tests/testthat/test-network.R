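test_that("the window grid tiles the task and baseline exactly", {
  d <- trial_design()
  g <- window_grid(d)
  expect_equal(g$n_task, 90L)
  expect_equal(g$n_baseline, 10L)
  expect_equal(g$samples_per_window, 50L)
  expect_equal(g$phase, rep(c("premise_coding", "premise_integration", "conclusion"),
                            each = 30L))
  ## incompatible rates and window lengths are rejected
  d2 <- trial_design(sampling_rate = 333)
  expect_error(window_grid(d2), "integer sample count")
  expect_error(window_grid(d, window_ms = 70), "multiple")
})

test_that("slicing partitions the trial and concatenates back exactly", {
  d <- pair_design2()
  sch <- build_tv_var(d, coupling_scenario())
  tr <- simulate_trial(sch, seed = 5)
  g <- window_grid(d)
  sl <- slice_windows(tr, g)
  expect_length(sl$task, 90L)
  expect_length(sl$baseline, 10L)
  rebuilt <- do.call(rbind, sl$task)
  expect_equal(rebuilt, t(unclass(tr))[(d$baseline_n + 1):d$total_n, ],
               ignore_attr = TRUE)
})

test_that("the causality table has the contracted shape and missingness semantics", {
  d <- pair_design2()
  scen <- coupling_scenario()
  cohort <- generate_cohort(d, list(g = scen),
                            list(g = list(n_subjects = 1L, trials_per_subject = 1L)),
                            master_seed = 9)
  tab <- window_gc_table(cohort, bands = frequency_bands()[c(1, 4), ],
                         pairs = data.frame(source = "F1", target = "P1"))
  ## (90 + 10) windows x 2 bands x 2 directions
  expect_equal(nrow(tab), 100L * 2L * 2L)
  expect_setequal(unique(tab$band), c("theta", "gamma"))
  expect_setequal(unique(paste(tab$source, tab$target)), c("F1 P1", "P1 F1"))
  ## unusable windows are missing, never zero
  expect_true(all(is.na(tab$gc[!tab$usable])))
  expect_true(all(tab$gc[tab$usable] >= 0))
  ## both engines agree
  tab_r <- window_gc_table(cohort, bands = frequency_bands()[c(1, 4), ],
                           pairs = data.frame(source = "F1", target = "P1"),
                           engine = "r")
  expect_equal(tab$gc, tab_r$gc, tolerance = 1e-8)
})

test_that("roi pairs default to the 40-pair frontal-to-parietal convention", {
  d <- trial_design()
  pr <- roi_pairs(d)
  expect_equal(nrow(pr), 40L)
  expect_true(all(pr$source %in% d$frontal))
  expect_true(all(pr$target %in% d$parietal))
  expect_error(roi_pairs(d, sources = "XX"), "unknown node")
})

test_that("cluster permutation finds nothing when task equals baseline", {
  set.seed(101)
  base <- matrix(rnorm(200), 20, 10)
  task <- base[, rep(1:10, length.out = 90)]
  mask <- cluster_permutation_test(task, base, seed = 1)
  expect_false(any(mask))
})

test_that("cluster permutation detects a strong shifted block", {
  hits <- vapply(1:50, function(i) {
    set.seed(200 + i)
    base <- matrix(rnorm(200), 20, 10)
    task <- matrix(rnorm(1800), 20, 90)
    task[, 40:49] <- task[, 40:49] + 5
    mask <- cluster_permutation_test(task, base, seed = i)
    all(mask[40:49])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cluster permutation controls the family-wise error rate", {
  fwer <- vapply(1:200, function(i) {
    set.seed(400 + i)
    base <- matrix(rnorm(200), 20, 10)
    task <- matrix(rnorm(1800), 20, 90)
    any(cluster_permutation_test(task, base, seed = i))
  }, logical(1))
  expect_lte(mean(fwer), 0.075)
})

test_that("cluster permutation is deterministic in its seed and flags zero variance", {
  set.seed(111)
  base <- matrix(rnorm(100), 10, 10)
  task <- matrix(rnorm(900), 10, 90)
  m1 <- cluster_permutation_test(task, base, seed = 42)
  m2 <- cluster_permutation_test(task, base, seed = 42)
  expect_identical(as.logical(m1), as.logical(m2))
  expect_warning(ze <- cluster_permutation_test(matrix(1, 5, 90), matrix(1, 5, 10)),
                 "zero-variance")
  expect_false(any(ze))
  expect_error(cluster_permutation_test(task, base, n_perm = 50), "at least 100")
})

test_that("binarization produces 0/1 stacks and rejects missing pairs", {
  d <- pair_design2()
  scen <- coupling_scenario()
  cohort <- generate_cohort(d, list(g = scen),
                            list(g = list(n_subjects = 2L, trials_per_subject = 3L)),
                            master_seed = 13)
  tab <- window_gc_table(cohort, bands = frequency_bands()[1, , drop = FALSE],
                         pairs = data.frame(source = "F1", target = "P1"))
  nets <- binarize_networks(tab, pairs = data.frame(source = c("F1", "P1"),
                                                    target = c("P1", "F1")),
                            n_perm = 100, seed = 3)
  adj <- nets$adjacency$g$theta
  expect_true(all(adj %in% c(0L, 1L)))
  expect_equal(dim(adj), c(90L, 2L))
  expect_true(all(nets$coverage$g$theta >= 0 & nets$coverage$g$theta <= 1))
  ## a pair absent from the table is an error, never a silent default
  expect_error(binarize_networks(tab, pairs = data.frame(source = "F9", target = "P1"),
                                 n_perm = 100, seed = 3),
               "no causality values")
  ## determinism
  nets2 <- binarize_networks(tab, pairs = data.frame(source = c("F1", "P1"),
                                                     target = c("P1", "F1")),
                             n_perm = 100, seed = 3)
  expect_identical(nets$adjacency, nets2$adjacency)
})
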