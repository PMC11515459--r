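#' Proteins identified in one sample
#'
#' A protein counts as identified in a sample when its intensity is
#' present (not the "not identified" `NA` state). The unique-peptide
#' identification criterion is applied upstream by the search engine;
#' users of real LFQ exports should pre-filter accordingly.
#'
#' @param abundance Abundance tibble (`sample` column + protein columns).
#' @param sample A sample id present in the table.
#' @return Character vector of identified protein ids.
#' @export
identified_set <- function(abundance, sample) {
  m <- abundance_matrix(abundance)
  if (!sample %in% rownames(m)) {
    abort(paste0("Unknown sample id: ", sample, "."))
  }
  colnames(m)[!is.na(m[sample, ])]
}

#' Consistent proteome of one condition
#'
#' The consistent proteome of a condition is the set of proteins
#' identified in every biological replicate of that condition
#' (consistency filtering): the intersection of the per-replicate
#' identified sets.
#'
#' @inheritParams identified_set
#' @param meta Sample annotation tibble (`sample`, `pmi_class`, `bone`,
#'   `search`, `replicate`).
#' @param pmi_class,bone Condition selectors.
#' @param search Optional search-type selector (ignored when `NULL`).
#' @return A `condition_proteome`: list with the condition key fields and
#'   the `proteins` character vector.
#' @export
consistent_proteome <- function(abundance, meta, pmi_class, bone,
                                search = NULL) {
  sel <- meta$pmi_class == pmi_class & meta$bone == bone
  if (!is.null(search)) sel <- sel & meta$search == search
  ids <- meta$sample[sel]
  if (length(ids) == 0L) {
    abort(paste0("Empty condition: no replicates for (", pmi_class, ", ",
                 bone, ")."))
  }
  sets <- lapply(ids, function(s) identified_set(abundance, s))
  structure(list(pmi_class = pmi_class, bone = bone,
                 search = search %||% unique(meta$search[sel]),
                 n_replicates = length(ids),
                 proteins = Reduce(intersect, sets)),
            class = "condition_proteome")
}

#' @export
print.condition_proteome <- function(x, ...) {
  cat("<condition_proteome> ", condition_key(x$pmi_class, x$bone), " (",
      x$n_replicates, " replicates): ", length(x$proteins),
      " proteins\n", sep = "")
  invisible(x)
}

#' All condition proteomes of a study
#'
#' @inheritParams consistent_proteome
#' @return Tibble with one row per (pmi_class, bone) condition and a
#'   `proteins` list-column.
#' @export
condition_proteomes <- function(abundance, meta) {
  conds <- dplyr::distinct(meta, .data$pmi_class, .data$bone)
  conds |>
    dplyr::mutate(
      proteins = purrr::map2(.data$pmi_class, .data$bone, function(p, b) {
        consistent_proteome(abundance, meta, p, b)$proteins
      }),
      n = lengths(.data$proteins))
}

# Accept a list of condition_proteome objects, a named list of character
# vectors, or a tibble with a `proteins` list-column; return a named list
# of character vectors.
as_proteome_list <- function(proteomes) {
  if (is.data.frame(proteomes)) {
    stopifnot("proteins" %in% names(proteomes))
    nm <- if (all(c("pmi_class", "bone") %in% names(proteomes))) {
      condition_key(proteomes$pmi_class, proteomes$bone)
    } else {
      paste0("set", seq_len(nrow(proteomes)))
    }
    return(stats::setNames(proteomes$proteins, nm))
  }
  if (inherits(proteomes, "condition_proteome")) proteomes <- list(proteomes)
  stopifnot(is.list(proteomes))
  out <- lapply(proteomes, function(p) {
    if (inherits(p, "condition_proteome")) p$proteins else as.character(p)
  })
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    nm <- vapply(seq_along(proteomes), function(i) {
      p <- proteomes[[i]]
      if (inherits(p, "condition_proteome")) {
        condition_key(p$pmi_class, p$bone)
      } else {
        paste0("set", i)
      }
    }, character(1))
    names(out) <- nm
  }
  out
}

#' Representative protein set
#'
#' The representative proteins of a search type are the union of the
#' per-condition consistent proteomes.
#'
#' @param proteomes Condition proteomes: a list of `condition_proteome`
#'   objects, a (named) list of character vectors, or a tibble with a
#'   `proteins` list-column.
#' @return Character vector (union of the input sets).
#' @export
representative_set <- function(proteomes) {
  sets <- as_proteome_list(proteomes)
  if (length(sets) == 0L) abort("Need at least one condition proteome.")
  unique(unlist(sets, use.names = FALSE))
}

#' UpSet-style intersection counts
#'
#' For every nonempty membership signature over the input sets, counts the
#' proteins carrying exactly that signature. Counts over all signatures sum
#' to the size of the union; proteins absent from every set are not
#' reported.
#'
#' @inheritParams representative_set
#' @return Tibble with one logical column per input set, plus `n` (the
#'   count) and `signature` (a readable label).
#' @export
intersection_counts <- function(proteomes) {
  sets <- as_proteome_list(proteomes)
  if (length(sets) < 2L) abort("Need at least two sets.")
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  sig <- tidyr::crossing(!!!stats::setNames(
    rep(list(c(TRUE, FALSE)), length(sets)), names(sets)))
  sig <- sig[rowSums(as.matrix(sig)) > 0L, , drop = FALSE]
  sig$n <- vapply(seq_len(nrow(sig)), function(i) {
    pattern <- as.logical(sig[i, names(sets)])
    sum(apply(member, 1, function(row) all(row == pattern)))
  }, integer(1))
  sig$signature <- vapply(seq_len(nrow(sig)), function(i) {
    paste(names(sets)[as.logical(sig[i, names(sets)])], collapse = "&")
  }, character(1))
  dplyr::arrange(sig, dplyr::desc(.data$n))
}

#' Normality-gated two-group comparison
#'
#' Tests each group for normality with a Shapiro-Wilk test at `alpha`; if
#' both groups pass, a two-sided two-sample t-test (equal variances) is
#' reported, otherwise a two-sided Mann-Whitney U test. Groups whose
#' values are all identical cannot be assessed by Shapiro-Wilk and are
#' treated as non-normal.
#'
#' @param values_a,values_b Numeric vectors, each with >= 3 values.
#' @param alpha Significance level of the normality gate.
#' @return One-row tibble: `test` ("t-test" or "Mann-Whitney U"),
#'   `statistic`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    abort("Each group needs >= 3 values (normality test undefined).")
  }
  normal <- function(x) {
    if (length(unique(x)) == 1L) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
  }
  if (normal(values_a) && normal(values_b)) {
    fit <- stats::t.test(values_a, values_b, var.equal = TRUE)
    tibble::tibble(test = "t-test",
                   statistic = unname(fit$statistic),
                   p_value = fit$p.value)
  } else {
    fit <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                               exact = FALSE))
    tibble::tibble(test = "Mann-Whitney U",
                   statistic = unname(fit$statistic),
                   p_value = fit$p.value)
  }
}

#' Synthetic per-condition proteome lists
#'
#' Loads the package's bundled synthetic reconstruction of per-condition
#' consistent proteome lists for both search types. The lists are a
#' constructed stand-in (no real identifications): they are built to be
#' consistent with the reference study design's set sizes
#' (per-condition sizes, union sizes of 16 tryptic / 21 semitryptic
#' representative proteins, and the number of proteins unique to the
#' earliest PMI class), and are used to exercise set operations at
#' realistic shape.
#'
#' @param search `"tryptic"` or `"semitryptic"`.
#' @return Tibble with `condition` and a `proteins` list-column.
#' @export
example_condition_proteomes <- function(search = c("semitryptic",
                                                   "tryptic")) {
  search <- match.arg(search)
  path <- system.file("extdata", "synthetic_condition_proteomes.tsv",
                      package = "pmiscreen", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  tbl <- tbl[tbl$search == search, ]
  out <- tbl |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(proteins = list(.data$protein), .groups = "drop")
  out[match(unique(tbl$condition), out$condition), ]
}
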