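#' Standardize an abundance table for ordination
#'
#' Replaces "not identified" entries by the imputation rule (`zero_fill`:
#' intensity 0, the natural LFQ below-detection stand-in), optionally
#' applies `log10(1 + x)`, then centers every protein column to mean 0 and
#' scales it to population standard deviation 1 (dividing by
#' \eqn{\sqrt{\sum (x - \bar x)^2 / n}}). Constant columns carry no
#' variance and are dropped with a warning.
#'
#' @param abundance Abundance tibble (`sample` + protein columns).
#' @param imputation Missing-value rule; only `"zero_fill"` is defined.
#' @param log10 Apply `log10(1 + x)` before standardizing (off by
#'   default: the reference protocol standardizes raw abundances).
#' @return Numeric matrix (samples x proteins) with attribute `dropped`
#'   listing removed constant columns.
#' @export
standardize_abundance <- function(abundance, imputation = "zero_fill",
                                  log10 = FALSE) {
  imputation <- match.arg(imputation, "zero_fill")
  m <- zero_fill(abundance_matrix(abundance))
  if (nrow(m) == 0L || ncol(m) == 0L) abort("Abundance table is empty.")
  if (log10) m <- log10(1 + m)
  n <- nrow(m)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  constant <- sd_pop == 0
  if (all(constant)) abort("All protein columns are constant.")
  if (any(constant)) {
    warn(paste0("Dropping constant columns: ",
                paste(colnames(m)[constant], collapse = ", "), "."))
  }
  z <- sweep(sweep(m[, !constant, drop = FALSE], 2, mu[!constant]),
             2, sd_pop[!constant], "/")
  attr(z, "dropped") <- colnames(m)[constant]
  z
}

new_ordination <- function(scores, loadings, explained, method,
                           degenerate = FALSE) {
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, method = method,
                 degenerate = degenerate),
            class = "pmi_ordination")
}

#' Principal component analysis of a standardized matrix
#'
#' Plain PCA by eigendecomposition of the sample covariance of `z`
#' (via singular value decomposition): components are ordered by
#' eigenvalue, the explained variance ratio of component \eqn{i} is
#' \eqn{\lambda_i / \sum_j \lambda_j}, scores are the projections of the
#' rows, and loadings are the eigenvector coordinates per variable.
#'
#' @param z Numeric matrix from [standardize_abundance()] (samples x
#'   variables, columns centered).
#' @param n_components Components to keep; defaults to the full rank
#'   `min(rows - 1, cols)`.
#' @return A `pmi_ordination`: `scores` tibble (`sample` + `PC1..`),
#'   `loadings` tibble (`protein` + `PC1..`), `explained` tibble
#'   (`component`, `variance_ratio`, `cumulative`).
#' @export
pca_abundance <- function(z, n_components = NULL) {
  z <- as.matrix(z)
  full <- min(nrow(z) - 1L, ncol(z))
  n_components <- n_components %||% full
  if (n_components > full) {
    abort(paste0("n_components must be <= min(rows - 1, cols) = ", full, "."))
  }
  fit <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  eig <- fit$sdev^2
  ratio <- eig / sum(eig)
  keep <- seq_len(n_components)

  scores <- tibble::as_tibble(fit$x[, keep, drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(z) %||% as.character(seq_len(nrow(z)))),
    scores)
  loadings <- dplyr::bind_cols(
    tibble::tibble(protein = colnames(z)),
    tibble::as_tibble(fit$rotation[, keep, drop = FALSE]))
  explained <- tibble::tibble(component = paste0("PC", keep),
                              variance_ratio = ratio[keep],
                              cumulative = cumsum(ratio)[keep])
  new_ordination(scores, loadings, explained, "pca")
}

#' @export
print.pmi_ordination <- function(x, ...) {
  cat("<pmi_ordination> method: ", x$method, "\n", sep = "")
  if (x$degenerate) cat("  degenerate: zero total inertia\n")
  print(x$explained)
  invisible(x)
}

#' @export
tidy.pmi_ordination <- function(x, ...) x$explained

#' @export
glance.pmi_ordination <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_components = nrow(x$explained),
                 cumulative_variance = max(x$explained$cumulative),
                 degenerate = x$degenerate)
}

# k-means++ seeding: first centre uniform, later centres sampled with
# probability proportional to squared distance to the nearest centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centres <- integer(k)
  centres[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[centres[1], ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centres[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centres[j], ])^2))
    }
  }
  x[centres, , drop = FALSE]
}

#' K-means clustering on ordination components
#'
#' Lloyd's algorithm with k-means++ seeding, restarted `n_init` times;
#' the partition with the lowest within-cluster sum of squares wins.
#' Deterministic given `seed`.
#'
#' @param scores Score matrix or the `scores` tibble of a
#'   [pca_abundance()] result.
#' @param k Number of clusters (1 <= k <= number of samples).
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @return Tibble with `sample` and `cluster` (integer labels 1..k).
#' @export
kmeans_components <- function(scores, k, seed = 1L, n_init = 25L) {
  if (is.data.frame(scores)) {
    samples <- if ("sample" %in% names(scores)) scores$sample else NULL
    x <- as.matrix(scores[setdiff(names(scores), "sample")])
  } else {
    x <- as.matrix(scores)
    samples <- rownames(x)
  }
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(x)) abort("`k` must be <= number of samples.")
  samples <- samples %||% as.character(seq_len(nrow(x)))

  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      init <- kmeanspp_init(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = init, algorithm = "Lloyd",
                      iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) {
        best <- fit
      }
    }
  })
  tibble::tibble(sample = samples, cluster = unname(best$cluster))
}

#' Multiple correspondence analysis of protein presence/absence
#'
#' Correspondence analysis of the complete disjunctive (indicator) table:
#' each protein contributes a present and an absent indicator column; the
#' standardized residual matrix
#' \eqn{D_r^{-1/2} (P - r c^\top) D_c^{-1/2}} is decomposed by SVD; sample
#' coordinates are the principal row coordinates and each dimension's
#' inertia fraction is its squared singular value over the total.
#' Proteins observed in only one state across all samples carry no
#' information and are dropped with a warning; if all samples are
#' identical, total inertia is zero and the result is flagged degenerate.
#'
#' @param presence Abundance tibble (presence = intensity present) or a
#'   samples x proteins binary/logical matrix.
#' @param n_components Dimensions to keep (default: all positive ones).
#' @return A `pmi_ordination` with `method = "mca"`.
#' @export
mca_presence <- function(presence, n_components = NULL) {
  if (is.data.frame(presence) && "sample" %in% names(presence)) {
    m <- !is.na(abundance_matrix(presence))
  } else {
    m <- as.matrix(presence) > 0
  }
  if (nrow(m) == 0L || ncol(m) == 0L) abort("Presence matrix is empty.")
  samples <- rownames(m) %||% as.character(seq_len(nrow(m)))

  both <- colSums(m) > 0 & colSums(m) < nrow(m)
  if (!any(both)) {
    warn("All proteins are constant; MCA is degenerate.")
    expl <- tibble::tibble(component = character(), variance_ratio = numeric(),
                           cumulative = numeric())
    return(new_ordination(tibble::tibble(sample = samples),
                          tibble::tibble(protein = character()),
                          expl, "mca", degenerate = TRUE))
  }
  if (any(!both)) {
    warn(paste0("Dropping single-state proteins: ",
                paste(colnames(m)[!both], collapse = ", "), "."))
  }
  m <- m[, both, drop = FALSE]

  ind <- cbind(m * 1, (!m) * 1)
  colnames(ind) <- c(paste0(colnames(m), "_present"),
                     paste0(colnames(m), "_absent"))
  P <- ind / sum(ind)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  if (!any(pos)) {
    expl <- tibble::tibble(component = character(), variance_ratio = numeric(),
                           cumulative = numeric())
    return(new_ordination(tibble::tibble(sample = samples),
                          tibble::tibble(protein = colnames(m)),
                          expl, "mca", degenerate = TRUE))
  }
  d <- sv$d[pos]
  inertia <- d^2 / sum(d^2)
  keep <- seq_len(min(n_components %||% length(d), length(d)))

  row_coord <- diag(1 / sqrt(r)) %*% sv$u[, pos, drop = FALSE] %*% diag(d,
    nrow = length(d))
  col_coord <- diag(1 / sqrt(cc)) %*% sv$v[, pos, drop = FALSE] %*% diag(d,
    nrow = length(d))
  dims <- paste0("Dim", keep)

  scores <- tibble::as_tibble(row_coord[, keep, drop = FALSE],
                              .name_repair = ~dims)
  scores <- dplyr::bind_cols(tibble::tibble(sample = samples), scores)
  loadings <- tibble::as_tibble(col_coord[, keep, drop = FALSE],
                                .name_repair = ~dims)
  loadings <- dplyr::bind_cols(tibble::tibble(category = colnames(ind)),
                               loadings)
  explained <- tibble::tibble(component = dims,
                              variance_ratio = inertia[keep],
                              cumulative = cumsum(inertia)[keep])
  new_ordination(scores, loadings, explained, "mca")
}
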