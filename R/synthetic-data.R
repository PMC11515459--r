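#' Specify a synthetic bone-proteome study
#'
#' A `synthetic_spec` fixes everything the study generator needs: the
#' (PMI class, bone) conditions, the protein panel, per-condition log10
#' abundance means, a common log10 standard deviation, per-condition
#' detection probabilities (identification dropout), additive bone effects
#' on the log10 scale, and a set of planted biomarkers whose
#' class-conditional intensity ranges are guaranteed disjoint.
#'
#' Intensities are modelled log10-normal: LFQ protein intensities are
#' positive and heavy-tailed, so a detected cell for protein \eqn{p} in a
#' sample of condition \eqn{c} is drawn as
#' \eqn{10^{N(\mu_{pc} + b_{p,\mathrm{bone}(c)},\ \sigma)}}. A cell that is
#' not detected (with probability \eqn{1 - d_{pc}}) is recorded as `NA`
#' ("not identified"), never as 0, so downstream imputation stays an
#' explicit, visible choice.
#'
#' Planted biomarkers must be detectable everywhere (`detection_prob = 1`)
#' and their class-conditional intervals \eqn{\mu \pm 3\sigma} (bone effect
#' included) must be pairwise disjoint across PMI classes, which makes the
#' planted class separation a checkable arithmetic property of the spec.
#'
#' @param conditions Data frame with columns `pmi_class` and `bone`.
#' @param replicates Biological replicates per condition.
#' @param proteins Character vector of protein ids (the panel).
#' @param log10_mean Numeric matrix `proteins x conditions` (columns named
#'   `"<pmi_class>_<bone>"`), or a single number recycled to all cells.
#' @param log10_sd Common log10-scale standard deviation (>= 0).
#' @param detection_prob Matrix like `log10_mean` with values in \[0, 1\],
#'   or a single probability.
#' @param bone_effect Numeric matrix `proteins x bones` (columns named by
#'   bone) of additive log10 shifts, or `NULL` for no bone effect.
#' @param planted Character vector of planted biomarker ids.
#' @param search Search type label stored in the sample annotations,
#'   `"tryptic"` or `"semitryptic"`.
#' @param seed Integer seed; generation is a pure function of the spec.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [synthetic_spec_default()], [generate_study()]
#' @export
synthetic_spec <- function(conditions, replicates = 5L, proteins,
                           log10_mean, log10_sd = 0.3, detection_prob = 1,
                           bone_effect = NULL, planted = character(),
                           search = c("semitryptic", "tryptic"), seed = 1L) {
  search <- match.arg(search)
  conditions <- tibble::as_tibble(conditions)
  if (!all(c("pmi_class", "bone") %in% names(conditions))) {
    abort("`conditions` needs columns `pmi_class` and `bone`.")
  }
  keys <- condition_key(conditions$pmi_class, conditions$bone)
  if (anyDuplicated(keys)) abort("Duplicated (pmi_class, bone) condition.")
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins)) abort("Protein ids must be unique.")

  expand <- function(x, what) {
    if (is.matrix(x)) {
      if (!setequal(rownames(x), proteins) || !setequal(colnames(x), keys)) {
        abort(paste0("`", what, "` must be a proteins x conditions matrix ",
                     "with matching dimnames."))
      }
      x[proteins, keys, drop = FALSE]
    } else if (length(x) == 1L) {
      matrix(x, length(proteins), length(keys),
             dimnames = list(proteins, keys))
    } else {
      abort(paste0("`", what, "` must be a matrix or a single number."))
    }
  }
  log10_mean <- expand(log10_mean, "log10_mean")
  detection_prob <- expand(detection_prob, "detection_prob")

  bones <- unique(conditions$bone)
  if (is.null(bone_effect)) {
    bone_effect <- matrix(0, length(proteins), length(bones),
                          dimnames = list(proteins, bones))
  } else {
    if (!is.matrix(bone_effect) || !setequal(rownames(bone_effect), proteins) ||
        !all(bones %in% colnames(bone_effect))) {
      abort("`bone_effect` must be a proteins x bones matrix.")
    }
    bone_effect <- bone_effect[proteins, bones, drop = FALSE]
  }

  spec <- structure(
    list(conditions = conditions, replicates = as.integer(replicates),
         proteins = proteins, log10_mean = log10_mean,
         log10_sd = as.numeric(log10_sd), detection_prob = detection_prob,
         bone_effect = bone_effect, planted = as.character(planted),
         search = search, seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

#' Validate a synthetic study specification
#'
#' Checks the spec invariants: probabilities in \[0, 1\], nonnegative
#' noise, planted biomarkers always detectable, and pairwise-disjoint
#' planted 3-sd intervals across PMI classes (bone effects included).
#' Violations raise an error naming the broken invariant.
#'
#' @param spec A [synthetic_spec()].
#' @return The spec, invisibly, when valid.
#' @export
validate_synthetic_spec <- function(spec) {
  if (spec$replicates < 1L) abort("Invariant violated: replicates >= 1.")
  if (is.na(spec$log10_sd) || spec$log10_sd < 0) {
    abort("Invariant violated: log10_sd must be nonnegative.")
  }
  p <- spec$detection_prob
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("Invariant violated: detection_prob values must lie in [0, 1].")
  }
  bad <- setdiff(spec$planted, spec$proteins)
  if (length(bad)) {
    abort(paste0("Invariant violated: planted biomarkers not in panel: ",
                 paste(bad, collapse = ", "), "."))
  }
  for (b in spec$planted) {
    if (any(p[b, ] < 1)) {
      abort(paste0("Invariant violated: planted biomarker ", b,
                   " must have detection_prob = 1 in all conditions."))
    }
  }
  # 3-sd disjointness of planted class-conditional intervals (bone effect in)
  keys <- condition_key(spec$conditions$pmi_class, spec$conditions$bone)
  centre <- function(prot, i) {
    spec$log10_mean[prot, keys[i]] +
      spec$bone_effect[prot, spec$conditions$bone[i]]
  }
  n <- nrow(spec$conditions)
  for (b in spec$planted) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && spec$conditions$pmi_class[i] != spec$conditions$pmi_class[j]) {
        gap <- abs(centre(b, i) - centre(b, j))
        if (gap <= 6 * spec$log10_sd) {
          abort(paste0(
            "Invariant violated: planted biomarker ", b,
            " has overlapping 3-sd intervals between ", keys[i], " and ",
            keys[j], " (gap ", signif(gap, 3), " <= 6 * sd)."))
        }
      }
    }
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat("  conditions: ", paste(condition_key(x$conditions$pmi_class,
                                            x$conditions$bone),
                              collapse = ", "), "\n", sep = "")
  cat("  replicates per condition:", x$replicates, "\n")
  cat("  proteins:", length(x$proteins),
      " planted:", paste(x$planted, collapse = ", "), "\n")
  cat("  log10 sd:", x$log10_sd, " search:", x$search,
      " seed:", x$seed, "\n")
  invisible(x)
}

# The 21-protein semitryptic panel the study reports on; the tryptic panel
# is its first 16 entries.
panel_semitryptic <- function() {
  c("ALBU", "THRB", "FETUA", "HBA", "HBB", "CO1A1", "CO1A2", "CO3A1",
    "PGS1", "K2C1", "K2C4", "K1C10", "K1C13", "SEMG1", "S10AB", "S10A9",
    "H10", "H12", "H14", "G3P", "S10A8")
}

collagen_family <- function() c("CO1A1", "CO1A2", "CO3A1", "PGS1")

#' Default synthetic study specification
#'
#' Builds the spec the package treats as its reference study design: five
#' conditions (PMI1 rib; PMI15 rib and tibia; PMI20 rib and tibia) with five
#' replicates each (25 samples), the 21-protein semitryptic panel, and three
#' planted biomarkers (PGS1, K1C13, CO3A1) whose class-conditional log10
#' means are separated by well over 6 standard deviations, so their
#' intensity ranges cannot overlap between PMI classes.
#'
#' Non-planted proteins carry no PMI signal in their means but are subject
#' to PMI-dependent identification dropout (detection probability 0.95,
#' 0.80, 0.65 for PMI1, PMI15, PMI20), reflecting proteome decay. The
#' collagen family (CO1A1, CO1A2, CO3A1, PGS1) gets a +0.8 log10 bone
#' effect in tibia, so bone type is a dominant source of abundance
#' variance, as observed in real bone proteomes.
#'
#' @param seed Integer seed stored in the spec.
#' @param replicates Replicates per condition.
#' @param search Search type label for the generated annotations.
#' @return A [synthetic_spec()].
#' @export
synthetic_spec_default <- function(seed = 1L, replicates = 5L,
                                   search = "semitryptic") {
  conditions <- tibble::tibble(
    pmi_class = c("PMI1", "PMI15", "PMI15", "PMI20", "PMI20"),
    bone      = c("rib",  "rib",   "tibia", "rib",   "tibia"))
  proteins <- panel_semitryptic()
  keys <- condition_key(conditions$pmi_class, conditions$bone)

  baseline <- rep(c(7.2, 6.8, 7.6, 7.0, 7.4), length.out = length(proteins))
  log10_mean <- matrix(baseline, length(proteins), length(keys),
                       dimnames = list(proteins, keys))
  # Planted biomarkers: distinct monotone patterns across PMI classes,
  # class-mean gaps of 2.5-3 log10 units (>> 6 * sd = 1.8).
  planted_means <- list(
    K1C13 = c(PMI1 = 9.0, PMI15 = 6.0, PMI20 = 3.0),  # keratin, early-high
    CO3A1 = c(PMI1 = 3.0, PMI15 = 6.0, PMI20 = 9.0),  # collagen, late-high
    PGS1  = c(PMI1 = 3.5, PMI15 = 9.0, PMI20 = 6.0))  # proteoglycan
  for (b in names(planted_means)) {
    log10_mean[b, ] <- planted_means[[b]][conditions$pmi_class]
  }

  dropout <- c(PMI1 = 0.95, PMI15 = 0.80, PMI20 = 0.65)
  detection_prob <- matrix(rep(dropout[conditions$pmi_class],
                               each = length(proteins)),
                           length(proteins), length(keys),
                           dimnames = list(proteins, keys))
  detection_prob[names(planted_means), ] <- 1

  bone_effect <- matrix(0, length(proteins), 2,
                        dimnames = list(proteins, c("rib", "tibia")))
  bone_effect[collagen_family(), "tibia"] <- 0.8

  synthetic_spec(conditions, replicates = replicates, proteins = proteins,
                 log10_mean = log10_mean, log10_sd = 0.3,
                 detection_prob = detection_prob, bone_effect = bone_effect,
                 planted = names(planted_means), search = search, seed = seed)
}

#' Generate a synthetic study from a spec
#'
#' Draws one abundance table row per (condition, replicate). Each
#' (sample, protein) cell is detected with the spec's detection
#' probability; detected cells are `10^Normal(mean + bone effect, sd)`,
#' undetected cells are `NA` ("not identified"). The same spec always
#' produces a bit-identical table.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `pmi_study` with elements `abundance` (tibble:
#'   `sample` column plus one column per protein) and `meta` (tibble:
#'   `sample`, `pmi_class`, `bone`, `search`, `replicate`).
#' @examples
#' study <- generate_study(synthetic_spec_default(seed = 7))
#' dim(study$abundance)
#' @export
generate_study <- function(spec) {
  validate_synthetic_spec(spec)
  keys <- condition_key(spec$conditions$pmi_class, spec$conditions$bone)
  n_prot <- length(spec$proteins)

  meta <- tidyr::crossing(
    tibble::tibble(pmi_class = spec$conditions$pmi_class,
                   bone = spec$conditions$bone, key = keys),
    replicate = seq_len(spec$replicates)) |>
    dplyr::arrange(match(.data$key, keys), .data$replicate) |>
    dplyr::mutate(sample = paste0(.data$key, "_r", .data$replicate),
                  search = spec$search) |>
    dplyr::select("sample", "pmi_class", "bone", "search", "replicate",
                  "key")

  intensities <- with_seed(spec$seed, {
    t(vapply(seq_len(nrow(meta)), function(i) {
      key <- meta$key[i]
      mu <- spec$log10_mean[, key] + spec$bone_effect[, meta$bone[i]]
      detected <- stats::runif(n_prot) <= spec$detection_prob[, key]
      vals <- 10^stats::rnorm(n_prot, mean = mu, sd = spec$log10_sd)
      vals[!detected] <- NA_real_
      vals
    }, numeric(n_prot)))
  })
  colnames(intensities) <- spec$proteins

  abundance <- dplyr::bind_cols(
    tibble::tibble(sample = meta$sample),
    tibble::as_tibble(intensities))
  structure(list(abundance = abundance,
                 meta = dplyr::select(meta, -"key")),
            class = "pmi_study")
}

#' @export
print.pmi_study <- function(x, ...) {
  cat("<pmi_study> ", nrow(x$abundance), " samples x ",
      ncol(x$abundance) - 1L, " proteins\n", sep = "")
  print(dplyr::count(x$meta, .data$pmi_class, .data$bone))
  invisible(x)
}

#' Generate random protein sequences with controlled residue composition
#'
#' Produces amino-acid sequences whose acidic (D, E) and basic (K, R, H)
#' residue fractions match the requested targets to within one residue,
#' for exercising the biochemical profiling stage. Residue counts are set
#' by rounding `length * target / 100`; positions are shuffled uniformly.
#'
#' @param n Number of sequences.
#' @param length Sequence length (>= 1).
#' @param acidic_target,basic_target Target percentages; their sum must not
#'   exceed 100.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param prefix Protein id prefix.
#' @return Tibble with columns `protein` and `sequence`.
#' @export
generate_sequences <- function(n, length, acidic_target, basic_target,
                               seed = 1L, prefix = "SYN") {
  if (length < 1L) abort("`length` must be >= 1.")
  if (acidic_target < 0 || basic_target < 0 ||
      acidic_target + basic_target > 100) {
    abort("Infeasible targets: acidic_target + basic_target must be <= 100.")
  }
  acidic <- c("D", "E")
  basic <- c("K", "R", "H")
  other <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   c(acidic, basic))
  n_acid <- round(length * acidic_target / 100)
  n_basic <- round(length * basic_target / 100)
  if (n_acid + n_basic > length) n_basic <- length - n_acid
  n_other <- length - n_acid - n_basic

  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      res <- c(sample(acidic, n_acid, replace = TRUE),
               sample(basic, n_basic, replace = TRUE),
               sample(other, n_other, replace = TRUE))
      paste(res[sample.int(length)], collapse = "")
    }, character(1))
    tibble::tibble(protein = sprintf("%s%03d", prefix, seq_len(n)),
                   sequence = seqs)
  })
}

#' Read and write study tables
#'
#' The on-disk interchange format is TSV: the abundance table has a first
#' column `sample` and one column per protein, with blank cells meaning
#' "not identified"; the annotation table carries `sample`, `pmi_class`,
#' `bone`, `search`, `replicate`.
#'
#' @param study A `pmi_study` (list with `abundance` and `meta`).
#' @param dir Output directory (created if missing).
#' @return `write_study()` returns the paths written, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             meta = file.path(dir, "meta.tsv"))
  readr::write_tsv(study$abundance, paths[["abundance"]], na = "")
  readr::write_tsv(study$meta, paths[["meta"]], na = "")
  invisible(paths)
}

#' @rdname write_study
#' @param path Path to a TSV file.
#' @export
read_abundance_tsv <- function(path) {
  tbl <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE)
  names(tbl)[1] <- "sample"
  tbl$sample <- as.character(tbl$sample)
  tbl
}

#' @rdname write_study
#' @export
read_sample_meta_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample = readr::col_character()))
}

#' FASTA sequence input and output
#'
#' Thin wrappers around `seqinr` for the plain-text FASTA files used to
#' supply protein sequences to the biochemical profiling stage.
#'
#' @param sequences Tibble with `protein` and `sequence` columns, or a
#'   named character vector.
#' @param path FASTA file path.
#' @return `read_sequences_fasta()` returns a tibble with `protein` and
#'   `sequence` columns.
#' @export
write_sequences_fasta <- function(sequences, path) {
  sequences <- as_sequence_tbl(sequences)
  seqinr::write.fasta(as.list(sequences$sequence),
                      names = sequences$protein, file.out = path,
                      as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' @rdname write_sequences_fasta
#' @export
read_sequences_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  tibble::tibble(protein = names(seqs),
                 sequence = toupper(vapply(seqs, `[[`, character(1), 1)))
}

as_sequence_tbl <- function(sequences) {
  if (is.character(sequences) && !is.null(names(sequences))) {
    return(tibble::tibble(protein = names(sequences),
                          sequence = unname(sequences)))
  }
  stopifnot(is.data.frame(sequences),
            all(c("protein", "sequence") %in% names(sequences)))
  tibble::as_tibble(sequences)
}
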