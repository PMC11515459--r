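test_that("rf_config validates its fields and presets sit in the grid", {
  expect_error(rf_config(0), ">= 1")
  cfg <- rf_preset("tibia_semitryptic")
  grid <- rf_grid()
  expect_true(cfg$n_estimators %in% grid$n_estimators)
  expect_true(cfg$max_depth %in% grid$max_depth)
  expect_equal(cfg$min_samples_split, 2L)
  expect_equal(cfg$min_samples_leaf, 2L)
  expect_equal(cfg$max_features, "sqrt")
})

test_that("hyperparameter search is deterministic and grid-contained", {
  st <- tibia_stratum(seed = 2)
  ab <- st$abundance[c("sample", planted_trio(), "ALBU", "HBB")]

  single <- rf_grid(n_estimators = 150, max_depth = 10)
  cfg <- hyperparameter_search(ab, st$labels, single, n_candidates = 3,
                               seed = 1)
  expect_equal(cfg$n_estimators, 150L)
  expect_equal(cfg$max_depth, 10)

  grid <- rf_grid(n_estimators = c(120, 250), max_depth = c(5, 15))
  cfg <- hyperparameter_search(ab, st$labels, grid, n_candidates = 8,
                               seed = 7)
  expect_true(cfg$n_estimators %in% grid$n_estimators)
  expect_true(cfg$max_depth %in% grid$max_depth)
  # winner is the argmax of the scored candidate table, ties to first
  search <- attr(cfg, "search")
  best <- which.max(search$cv_accuracy)
  expect_equal(cfg$n_estimators, search$n_estimators[best])
  expect_equal(cfg$max_depth, search$max_depth[best])

  cfg2 <- hyperparameter_search(ab, st$labels, grid, n_candidates = 8,
                                seed = 7)
  expect_equal(unclass(cfg), unclass(cfg2))

  tiny <- ab[c(1, 6), ]
  expect_error(hyperparameter_search(tiny, st$labels[c(1, 6)], grid,
                                     n_candidates = 2, seed = 1),
               "stratification")
})

test_that("resampled evaluation keeps its per-iteration invariants", {
  st <- tibia_stratum(seed = 5)
  ev <- suppressMessages(
    resampled_evaluation(st$abundance, st$labels, small_config(),
                         n_iter = 15, base_seed = 2))
  samples <- st$abundance$sample
  for (i in seq_len(nrow(ev$records))) {
    tr <- ev$records$train[[i]]; te <- ev$records$test[[i]]
    expect_setequal(c(tr, te), samples)
    expect_length(intersect(tr, te), 0)
    expect_equal(sum(ev$records$importance[[i]]), 1, tolerance = 1e-9)
  }
  expect_true(all(ev$records$accuracy >= 0 & ev$records$accuracy <= 1))
  expect_true(all(ev$records$f1 >= 0 & ev$records$f1 <= 1))

  # SHAP local accuracy for every record
  err <- ev$shap |>
    dplyr::group_by(iteration, sample, class) |>
    dplyr::summarise(s = sum(value), .groups = "drop") |>
    dplyr::left_join(ev$shap_base, by = c("iteration", "sample", "class")) |>
    dplyr::mutate(err = abs(s + base - predicted))
  expect_lt(max(err$err), 1e-6)

  # coverage: every sample appears in train and in test at least once
  expect_setequal(unique(unlist(ev$records$train)), samples)
  expect_setequal(unique(unlist(ev$records$test)), samples)
})

test_that("resampled evaluation is deterministic run-to-run", {
  st <- tibia_stratum(seed = 6)
  ab <- st$abundance[c("sample", planted_trio(), "ALBU")]
  e1 <- suppressMessages(resampled_evaluation(ab, st$labels, small_config(),
                                              n_iter = 8, base_seed = 3))
  e2 <- suppressMessages(resampled_evaluation(ab, st$labels, small_config(),
                                              n_iter = 8, base_seed = 3))
  expect_identical(e1$records, e2$records)
  expect_identical(e1$shap, e2$shap)
})

test_that("planted features with disjoint supports classify perfectly", {
  st <- tibia_stratum(seed = 4)
  ab <- st$abundance[c("sample", planted_trio())]
  ev <- suppressMessages(
    resampled_evaluation(ab, st$labels, rf_preset("tibia_semitryptic"),
                         n_iter = 25, base_seed = 4))
  expect_equal(ev$records$accuracy, rep(1, nrow(ev$records)))
  expect_equal(ev$records$f1, rep(1, nrow(ev$records)))
})

test_that("mean importance averages records and checks key consistency", {
  fake <- tibble::tibble(importance = list(c(A = 0.6, B = 0.4),
                                           c(A = 0.2, B = 0.8)))
  expect_equal(mean_importance(fake), c(A = 0.4, B = 0.6))

  set.seed(31)
  recs <- tibble::tibble(importance = lapply(1:5, function(i) {
    v <- runif(4); stats::setNames(v / sum(v), c("A", "B", "C", "D"))
  }))
  got <- mean_importance(recs)
  want <- colMeans(do.call(rbind, recs$importance))
  expect_equal(got, want)
  expect_equal(sum(got), 1, tolerance = 1e-6)

  bad <- tibble::tibble(importance = list(c(A = 1), c(B = 1)))
  expect_error(mean_importance(bad), "inconsistent")
})

test_that("shap_summary pools order statistics per class", {
  ev <- structure(list(
    classes = c("PMI15", "PMI20"),
    labels = c(s1 = "PMI15", s2 = "PMI20"),
    shap = tibble::tibble(
      iteration = c(1, 2, 3, 1),
      sample = c("s1", "s1", "s1", "s2"),
      protein = "pA",
      class = c("PMI15", "PMI15", "PMI15", "PMI20"),
      value = c(-1, 0, 2, 0.4))), class = "rf_evaluation")
  s <- shap_summary(ev, "PMI15")
  expect_equal(s$median, 0)
  expect_equal(s$min, -1)
  expect_equal(s$max, 2)
  s2 <- shap_summary(ev, "PMI20")
  expect_equal(s2$median, 0.4)
  expect_equal(s2$min, s2$max)
  expect_error(shap_summary(ev, "PMI99"), "Unknown class")

  # sort oracle on random pooled values
  set.seed(8)
  vals <- rnorm(40)
  ev$shap <- tibble::tibble(iteration = rep(1:10, 4), sample = "s1",
                            protein = rep(c("pA", "pB"), each = 20),
                            class = "PMI15", value = vals)
  s <- shap_summary(ev, "PMI15")
  expect_equal(s$median[s$protein == "pA"], stats::median(vals[1:20]))
  expect_equal(s$q05[s$protein == "pB"],
               unname(stats::quantile(vals[21:40], 0.05)))
})

test_that("macro F1 matches the per-class harmonic mean definition", {
  truth <- factor(c("a", "a", "b", "b", "b"), levels = c("a", "b"))
  pred <- factor(c("a", "b", "b", "b", "a"), levels = c("a", "b"))
  # class a: P = 1/2, R = 1/2 -> F1 = 1/2; class b: P = 2/3, R = 2/3
  expect_equal(pmiscreen:::macro_f1(truth, pred, c("a", "b")),
               mean(c(0.5, 2 / 3)))
})
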