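#' Importance pre-filter
#'
#' Keeps proteins whose mean Mean-Decrease-in-Gini importance share is
#' strictly greater than `threshold` (default 4%).
#'
#' @param importance Named numeric vector of mean importance shares
#'   (summing to 1).
#' @param threshold Minimum share (exclusive).
#' @return Character vector of retained protein ids.
#' @export
importance_filter <- function(importance, threshold = 0.04) {
  if (abs(sum(importance) - 1) > 1e-6) {
    abort("Importance shares must sum to 1.")
  }
  keep <- names(importance)[importance > threshold]
  if (length(keep) == 0L) {
    abort(paste0("No protein exceeds the ", threshold,
                 " importance threshold; lower the threshold."))
  }
  keep
}

#' SHAP-rule elimination candidates
#'
#' A protein qualifies for elimination when, in every class, the absolute
#' pooled SHAP median lies within `epsilon` of zero relative to the
#' largest absolute pooled SHAP value over all proteins and classes, and
#' its pooled minimum (the smallest value over its classes) is negative.
#' Qualifying proteins are ranked by ascending maximum absolute median
#' over classes and at most `batch` are returned; the full remaining
#' candidate set is never returned.
#'
#' With the default per-class pooling of [shap_summary_all()] the
#' negative-tail condition is the sharp gate: a biomarker that
#' consistently raises its own class's probability has a nonnegative
#' lower tail of own-class attributions, while chance-correlated proteins
#' misclassify in many resampling rounds and dip below zero. When the
#' summaries carry a `q05` column (the 5% lower-tail quantile pooled over
#' 100 iterations), it is used instead of the raw minimum: trees split
#' raw intensities at midpoints that sit close below the higher group, so
#' even a perfect marker is misrouted in isolated iterations, and the
#' minimum — an extreme statistic of hundreds of pooled values — flags
#' such one-off events where the tail quantile does not. The median band
#' is deliberately permissive (`epsilon` default 0.75 of the global
#' maximum): it only spares proteins whose attributions are essentially
#' at the top of the observed range, and lets the tail condition decide
#' the rest. Candidates are removed deepest negative tail first: spurious
#' competitors poison the attributions of genuine markers, so the worst
#' offender is removed and the remainder re-assessed on the retrained
#' model rather than condemned in one pass.
#'
#' @param summaries Tibble from [shap_summary_all()] covering every
#'   candidate protein in every class.
#' @param epsilon Near-zero band as a fraction of the global maximum
#'   absolute SHAP value.
#' @param batch Maximum number of proteins to return.
#' @return Character vector of proteins to drop (possibly empty).
#' @export
shap_elimination_candidates <- function(summaries, epsilon = 0.75,
                                        batch = 2L) {
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  stopifnot(all(c("class", "protein", "median", "min", "max") %in%
                  names(summaries)))
  global_max <- max(abs(c(summaries$min, summaries$max, summaries$median)))
  band <- epsilon * global_max
  summaries$lower_tail <- if ("q05" %in% names(summaries)) {
    summaries$q05
  } else {
    summaries$min
  }

  per_protein <- summaries |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      qualifies = all(abs(.data$median) <= band) &&
        min(.data$lower_tail) < 0,
      deepest = min(.data$lower_tail), .groups = "drop")
  n_remaining <- nrow(per_protein)

  cand <- per_protein |>
    dplyr::filter(.data$qualifies) |>
    dplyr::arrange(.data$deepest, .data$protein)
  utils::head(cand$protein, min(batch, n_remaining - 1L))
}

target_met <- function(records, target) {
  mean(records$accuracy) >= target && min(records$accuracy) >= target &&
    mean(records$f1) >= target && min(records$f1) >= target
}

#' Minimal biomarker panel search
#'
#' The supervised variable-screening loop. Round 0 evaluates the full
#' panel with [resampled_evaluation()]; round 1 applies the importance
#' pre-filter to the mean importances of round 0; every later round drops
#' the SHAP-rule elimination candidates of the previous round and
#' retrains. The loop stops when no protein qualifies for elimination or
#' the candidate set can shrink no further. On stopping, the
#' best-performing round's set is returned (performance first, then the
#' smaller set); if it meets the target a leave-one-out check certifies
#' whether any single remaining protein could still be removed without
#' falling below target. `sustained` reports target attainment of the
#' final set; `loo_minimal` reports the certificate.
#'
#' With `prune_loo = TRUE`, leave-one-out removable proteins are pruned
#' (tagged `leave-one-out`) before stopping, which can shrink a panel of
#' mutually redundant biomarkers further than the SHAP rules alone.
#'
#' @inheritParams resampled_evaluation
#' @param threshold Importance pre-filter share (see
#'   [importance_filter()]).
#' @param epsilon,batch SHAP elimination parameters (see
#'   [shap_elimination_candidates()]).
#' @param target Target mean and minimum accuracy and F1 (default 1.0).
#' @param prune_loo Prune leave-one-out removable proteins at the end.
#' @return A `screening_trace`: list with `rounds` (tibble: round,
#'   protein list-column, metrics, drop records), `final` (protein ids),
#'   `sustained`, `loo_minimal`, `dropped` (tibble: protein, rule,
#'   round), and the final round's `evaluation`.
#' @export
minimal_biomarker_search <- function(abundance, labels, config,
                                     n_iter = 100L, threshold = 0.04,
                                     epsilon = 0.75, batch = 2L,
                                     target = 1.0, base_seed = 1L,
                                     prune_loo = FALSE,
                                     feature_scale = c("log10", "raw")) {
  feature_scale <- match.arg(feature_scale)
  m <- abundance_matrix(abundance)
  all_proteins <- colnames(m)
  if (length(all_proteins) < 3L) abort("Need at least 3 proteins.")
  labels <- as_labels(labels, nrow(m))

  subset_abundance <- function(proteins) {
    abundance[c("sample", proteins)]
  }
  evaluate <- function(proteins, shap = TRUE) {
    resampled_evaluation(subset_abundance(proteins), labels, config,
                         n_iter = n_iter, base_seed = base_seed,
                         compute_shap = shap, feature_scale = feature_scale)
  }

  rounds <- list()
  dropped <- tibble::tibble(protein = character(), rule = character(),
                            round = integer())
  evaluations <- list()
  record_round <- function(proteins, evaluation, drops) {
    r <- length(rounds)
    rounds[[r + 1L]] <<- tibble::tibble(
      round = r, n_proteins = length(proteins),
      proteins = list(proteins),
      mean_accuracy = mean(evaluation$records$accuracy),
      min_accuracy = min(evaluation$records$accuracy),
      mean_f1 = mean(evaluation$records$f1),
      min_f1 = min(evaluation$records$f1))
    evaluations[[r + 1L]] <<- evaluation
    if (nrow(drops)) {
      dropped <<- dplyr::bind_rows(dropped,
                                   dplyr::mutate(drops, round = r))
    }
  }

  # round 0: full panel
  current <- all_proteins
  eval_cur <- evaluate(current)
  record_round(current, eval_cur,
               tibble::tibble(protein = character(), rule = character()))

  # round 1: importance pre-filter (applied once, up front)
  keep <- importance_filter(mean_importance(eval_cur), threshold)
  keep <- all_proteins[all_proteins %in% keep]  # stable order
  if (length(keep) < length(current)) {
    drops <- tibble::tibble(protein = setdiff(current, keep),
                            rule = "importance")
    current <- keep
    eval_cur <- evaluate(current)
    record_round(current, eval_cur, drops)
  }

  # SHAP elimination rounds
  repeat {
    if (length(current) <= 1L) break
    cand <- shap_elimination_candidates(shap_summary_all(eval_cur),
                                        epsilon = epsilon, batch = batch)
    if (length(cand) == 0L) break
    drops <- tibble::tibble(protein = cand, rule = "shap-median")
    current <- setdiff(current, cand)
    eval_cur <- evaluate(current)
    record_round(current, eval_cur, drops)
  }

  rounds_tbl <- dplyr::bind_rows(rounds)

  # best-performing round: metrics first, then the smaller set, then later
  ord <- order(-(rounds_tbl$mean_accuracy + rounds_tbl$mean_f1),
               -(rounds_tbl$min_accuracy + rounds_tbl$min_f1),
               rounds_tbl$n_proteins, -rounds_tbl$round)
  best <- ord[1]
  final <- rounds_tbl$proteins[[best]]
  eval_final <- evaluations[[best]]
  sustained <- target_met(eval_final$records, target)

  loo_removable <- function(proteins) {
    removable <- character(0)
    for (p in proteins) {
      rest <- setdiff(proteins, p)
      if (length(rest) == 0L) next
      ev <- resampled_evaluation(subset_abundance(rest), labels, config,
                                 n_iter = n_iter, base_seed = base_seed,
                                 compute_shap = FALSE,
                                 feature_scale = feature_scale)
      if (target_met(ev$records, target)) removable <- c(removable, p)
    }
    removable
  }

  loo_minimal <- NA
  if (sustained) {
    removable <- loo_removable(final)
    loo_minimal <- length(removable) == 0L
    while (prune_loo && length(removable) > 0L && length(final) > 1L) {
      p <- removable[1]
      final <- setdiff(final, p)
      eval_final <- evaluate(final)
      record_round(final, eval_final,
                   tibble::tibble(protein = p, rule = "leave-one-out"))
      rounds_tbl <- dplyr::bind_rows(rounds)
      sustained <- target_met(eval_final$records, target)
      removable <- if (sustained) loo_removable(final) else character(0)
      loo_minimal <- length(removable) == 0L
    }
  }

  structure(list(rounds = rounds_tbl, final = final, sustained = sustained,
                 loo_minimal = loo_minimal, dropped = dropped,
                 evaluation = eval_final, target = target,
                 initial = all_proteins),
            class = "screening_trace")
}

#' @export
print.screening_trace <- function(x, ...) {
  cat("<screening_trace> ", nrow(x$rounds), " rounds; final set: ",
      paste(x$final, collapse = ", "), "\n", sep = "")
  cat("  sustained:", x$sustained, " loo_minimal:", x$loo_minimal, "\n")
  print(dplyr::select(x$rounds, -"proteins"))
  invisible(x)
}

#' @export
tidy.screening_trace <- function(x, ...) {
  dplyr::select(x$rounds, -"proteins")
}

#' @export
glance.screening_trace <- function(x, ...) {
  last <- x$rounds[which(vapply(x$rounds$proteins, identical, logical(1),
                                x$final))[1], ]
  tibble::tibble(n_rounds = nrow(x$rounds),
                 n_initial = length(x$initial),
                 n_final = length(x$final),
                 sustained = x$sustained,
                 loo_minimal = x$loo_minimal,
                 mean_accuracy = last$mean_accuracy,
                 mean_f1 = last$mean_f1)
}
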