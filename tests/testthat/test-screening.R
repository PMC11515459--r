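test_that("importance filter keeps strict exceedances of the threshold", {
  imp <- c(A = 0.6, B = 0.3, C = 0.05, D = 0.03, E = 0.02)
  expect_setequal(importance_filter(imp, 0.04), c("A", "B", "C"))
  expect_setequal(importance_filter(imp, 0), names(imp))
  expect_error(importance_filter(imp, 0.7), "lower the threshold")
  expect_error(importance_filter(c(A = 0.4, B = 0.4)), "sum to 1")
})

make_summary <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(class = c("c1", "c2"), protein = r$protein,
                   median = r$median, min = r$min,
                   max = abs(r$median) + 0.2)
  }))
}

test_that("SHAP elimination applies the near-zero and negative-tail rules", {
  s <- make_summary(list(protein = "dead", median = c(0, 0),
                         min = c(-0.2, -0.1)),
                    list(protein = "marker", median = c(0.9, 0.8),
                         min = c(0.5, 0.4)))
  expect_equal(shap_elimination_candidates(s, batch = 2), "dead")

  # a large positive median in one class protects a protein
  s <- make_summary(list(protein = "mixed", median = c(0, 0.95),
                         min = c(-0.3, 0.2)),
                    list(protein = "other", median = c(0.2, 0.2),
                         min = c(-0.1, 0.1)))
  expect_false("mixed" %in% shap_elimination_candidates(s, epsilon = 0.5))

  # three qualifiers, batch 2: the two smallest-tail proteins are returned
  s <- make_summary(list(protein = "q1", median = c(0.01, 0.01),
                         min = c(-0.5, -0.1)),
                    list(protein = "q2", median = c(0.02, 0.01),
                         min = c(-0.3, -0.2)),
                    list(protein = "q3", median = c(0.03, 0.02),
                         min = c(-0.1, -0.05)),
                    list(protein = "keep", median = c(0.9, 0.9),
                         min = c(0.4, 0.5)))
  expect_equal(shap_elimination_candidates(s, epsilon = 0.5, batch = 2),
               c("q1", "q2"))

  # never returns the whole remaining candidate set
  s <- make_summary(list(protein = "q1", median = c(0, 0),
                         min = c(-0.5, -0.1)),
                    list(protein = "q2", median = c(0, 0),
                         min = c(-0.3, -0.2)))
  expect_equal(shap_elimination_candidates(s, batch = 5), "q1")

  expect_error(shap_elimination_candidates(s, epsilon = -1), ">= 0")
})

test_that("screening recovers the planted trio on the reference study", {
  st <- tibia_stratum(seed = 7)
  tr <- suppressMessages(
    minimal_biomarker_search(st$abundance, st$labels,
                             rf_preset("tibia_semitryptic"),
                             n_iter = 100, base_seed = 7))
  expect_setequal(tr$final, planted_trio())
  last <- tr$rounds[nrow(tr$rounds), ]
  expect_equal(last$mean_accuracy, 1)
  expect_equal(last$mean_f1, 1)
  expect_true(tr$sustained)

  # monotone bookkeeping: every initial protein is final or dropped once
  expect_setequal(c(tr$final, tr$dropped$protein), tr$initial)
  expect_equal(anyDuplicated(tr$dropped$protein), 0)
  expect_true(all(tr$dropped$rule %in%
                    c("importance", "shap-median", "leave-one-out")))
  # candidate sets strictly decrease across rounds
  expect_true(all(diff(tr$rounds$n_proteins) < 0))
  expect_lte(nrow(tr$rounds), length(tr$initial))
})

test_that("a trio-only input needs one modeling round plus certification", {
  st <- tibia_stratum(seed = 9)
  ab <- st$abundance[c("sample", planted_trio())]
  tr <- suppressMessages(
    minimal_biomarker_search(ab, st$labels, small_config(),
                             n_iter = 20, base_seed = 9))
  expect_setequal(tr$final, planted_trio())
  expect_true(tr$sustained)
  # each planted marker separates alone, so the strict leave-one-out
  # certificate cannot hold for the redundant trio
  expect_false(tr$loo_minimal)
  expect_lte(nrow(tr$rounds), 2)
})

test_that("pure-noise studies terminate with bounded rounds", {
  set.seed(55)
  n <- 10
  ab <- dplyr::bind_cols(
    tibble::tibble(sample = paste0("s", seq_len(n))),
    tibble::as_tibble(matrix(10^rnorm(n * 6, 7, 0.4), n, 6,
                             dimnames = list(NULL, paste0("p", 1:6)))))
  labs <- rep(c("x", "y"), each = 5)
  tr <- suppressMessages(
    minimal_biomarker_search(ab, labs, small_config(), n_iter = 15,
                             base_seed = 3, threshold = 0))
  expect_s3_class(tr, "screening_trace")
  expect_lte(nrow(tr$rounds), 7)
  expect_gte(length(tr$final), 1)
  expect_setequal(c(tr$final, tr$dropped$protein), tr$initial)
})

test_that("tidy and glance expose the trace at the expected grain", {
  st <- tibia_stratum(seed = 10)
  ab <- st$abundance[c("sample", planted_trio(), "ALBU")]
  tr <- suppressMessages(
    minimal_biomarker_search(ab, st$labels, small_config(),
                             n_iter = 10, base_seed = 10))
  td <- tidy(tr)
  expect_true(all(c("round", "n_proteins", "mean_accuracy") %in% names(td)))
  g <- glance(tr)
  expect_equal(g$n_initial, 4)
  expect_equal(g$n_final, length(tr$final))
})
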