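# Average residue masses (Da) for the 20 standard amino acids, and the
# mass of one water added to close the chain. These are the conventional
# values used for average protein molecular weight reporting.
AA_AVERAGE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

ACIDIC_RESIDUES <- c("D", "E")
BASIC_RESIDUES <- c("K", "R", "H")

split_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || !nzchar(sequence)) {
    abort("`sequence` must be a single nonempty amino-acid string.")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(AA_AVERAGE_MASS))
  if (length(bad)) {
    abort(paste0("Unknown residue symbol '", res[bad[1]], "' at position ",
                 bad[1], "."))
  }
  res
}

#' Average protein molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da), the
#' convention used for reporting protein molecular weights from sequence.
#'
#' @param sequence Amino-acid string(s) over the 20 standard residues.
#' @return Molecular weight(s) in Daltons.
#' @examples
#' molecular_weight("G")   # 75.07
#' @export
molecular_weight <- function(sequence) {
  vapply(sequence, function(s) {
    sum(AA_AVERAGE_MASS[split_residues(s)]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Acidic or basic residue percentage
#'
#' Percentage of residues belonging to the requested charge class:
#' acidic = D, E; basic = K, R, H. Histidine is only weakly basic at
#' physiological pH; set `include_histidine = FALSE` to count K, R only.
#'
#' @inheritParams molecular_weight
#' @param class `"acidic"` or `"basic"`.
#' @param include_histidine Count H as basic (default `TRUE`).
#' @return Percentage(s) in \[0, 100\].
#' @export
residue_class_fraction <- function(sequence, class = c("acidic", "basic"),
                                   include_histidine = TRUE) {
  class <- match.arg(class)
  members <- if (class == "acidic") {
    ACIDIC_RESIDUES
  } else if (include_histidine) {
    BASIC_RESIDUES
  } else {
    c("K", "R")
  }
  vapply(sequence, function(s) {
    res <- split_residues(s)
    100 * sum(res %in% members) / length(res)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Biochemical profiles of a protein set
#'
#' @param sequences Tibble with `protein` and `sequence` columns, or a
#'   named character vector of sequences.
#' @inheritParams residue_class_fraction
#' @return Tibble: `protein`, `length`, `molecular_weight`, `acidic_pct`,
#'   `basic_pct`.
#' @export
biochem_profile <- function(sequences, include_histidine = TRUE) {
  sequences <- as_sequence_tbl(sequences)
  tibble::tibble(
    protein = sequences$protein,
    length = nchar(sequences$sequence),
    molecular_weight = molecular_weight(sequences$sequence),
    acidic_pct = residue_class_fraction(sequences$sequence, "acidic"),
    basic_pct = residue_class_fraction(sequences$sequence, "basic",
                                       include_histidine))
}

#' Early-exclusive versus late proteome biochemical contrast
#'
#' Groups proteomes into an early-exclusive set (proteins seen early but
#' in no late condition: the early set minus the union of the late sets)
#' and a late set (the union of the late condition proteomes), profiles
#' both, and compares molecular weight, acidic percentage, and basic
#' percentage between the groups with the normality-gated two-group test
#' of [compare_groups()].
#'
#' @param early Early-condition proteome (character vector or
#'   `condition_proteome`).
#' @param lates List of late-condition proteomes.
#' @param sequences Sequences covering every protein involved (tibble or
#'   named character vector).
#' @param alpha Significance level for the normality gate.
#' @return Object of class `pmi_contrast`: list with `profiles` (tibble
#'   with a `group` column), `tests` (tibble, one row per metric; `NULL`
#'   when a group is empty or has fewer than 3 proteins), and
#'   `empty_group` flag.
#' @export
early_late_contrast <- function(early, lates, sequences, alpha = 0.05) {
  early <- as_proteome_list(list(early))[[1]]
  late <- representative_set(lates)
  early_excl <- setdiff(early, late)
  sequences <- as_sequence_tbl(sequences)

  missing <- setdiff(c(early_excl, late), sequences$protein)
  if (length(missing)) {
    abort(paste0("Missing sequences for: ",
                 paste(missing, collapse = ", "), "."))
  }

  prof <- function(ids, group) {
    if (length(ids) == 0L) return(NULL)
    dplyr::mutate(
      biochem_profile(sequences[match(ids, sequences$protein), ]),
      group = group, .before = 1)
  }
  profiles <- dplyr::bind_rows(prof(early_excl, "early_exclusive"),
                               prof(late, "late"))
  empty <- length(early_excl) == 0L || length(late) == 0L

  tests <- NULL
  if (!empty && length(early_excl) >= 3L && length(late) >= 3L) {
    metrics <- c("molecular_weight", "acidic_pct", "basic_pct")
    tests <- purrr::map_dfr(metrics, function(mcol) {
      a <- profiles[[mcol]][profiles$group == "early_exclusive"]
      b <- profiles[[mcol]][profiles$group == "late"]
      dplyr::mutate(compare_groups(a, b, alpha = alpha),
                    metric = mcol,
                    mean_early_exclusive = mean(a), mean_late = mean(b),
                    .before = 1)
    })
  }
  structure(list(early_exclusive = early_excl, late = late,
                 profiles = profiles, tests = tests, empty_group = empty),
            class = "pmi_contrast")
}

#' @export
print.pmi_contrast <- function(x, ...) {
  cat("<pmi_contrast> early-exclusive: ", length(x$early_exclusive),
      " proteins; late: ", length(x$late), " proteins\n", sep = "")
  if (x$empty_group) {
    cat("  empty group: no tests performed\n")
  } else if (is.null(x$tests)) {
    cat("  group too small (< 3): no tests performed\n")
  } else {
    print(x$tests)
  }
  invisible(x)
}

#' @export
tidy.pmi_contrast <- function(x, ...) {
  if (is.null(x$tests)) tibble::tibble() else x$tests
}
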