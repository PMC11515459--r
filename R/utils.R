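# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib pmiscreen, .registration = TRUE
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps generators pure functions of their spec/seed without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

condition_key <- function(pmi_class, bone) paste(pmi_class, bone, sep = "_")

# Coerce a wide abundance tibble (first column `sample`, one column per
# protein, NA = not identified) into a numeric matrix with sample rownames.
abundance_matrix <- function(abundance) {
  stopifnot(is.data.frame(abundance))
  if (!"sample" %in% names(abundance)) {
    abort("Abundance table must have a `sample` column.")
  }
  m <- as.matrix(abundance[setdiff(names(abundance), "sample")])
  storage.mode(m) <- "double"
  rownames(m) <- abundance$sample
  if (anyDuplicated(rownames(m))) abort("Sample ids must be unique.")
  if (anyDuplicated(colnames(m))) abort("Protein ids must be unique.")
  if (any(m < 0, na.rm = TRUE)) abort("Intensities must be nonnegative.")
  m
}

zero_fill <- function(m) {
  m[is.na(m)] <- 0
  m
}
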