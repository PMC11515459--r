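test_that("standardization centers and scales by population sd", {
  ab <- abundance_tbl(list(s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5)),
                      c("pA", "pB"))
  expect_warning(z <- standardize_abundance(ab), "pB")
  expect_equal(unname(z[, "pA"]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(attr(z, "dropped"), "pB")

  const <- abundance_tbl(list(s1 = c(5), s2 = c(5)), "pA")
  expect_error(suppressWarnings(standardize_abundance(const)),
               "constant")

  study <- generate_study(synthetic_spec_default(seed = 17))
  z <- suppressWarnings(standardize_abundance(study$abundance))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  pop_sd <- sqrt(colMeans(sweep(z, 2, colMeans(z))^2))
  expect_true(all(abs(pop_sd - 1) < 1e-9))
})

test_that("PCA matches a dense eigendecomposition of the covariance", {
  # rank-1 data: two perfectly correlated variables
  ab <- abundance_tbl(list(s1 = c(1, 2), s2 = c(2, 4), s3 = c(3, 6),
                           s4 = c(4, 8)), c("pA", "pB"))
  z <- standardize_abundance(ab)
  fit <- pca_abundance(z)
  expect_equal(fit$explained$variance_ratio[1], 1, tolerance = 1e-9)

  set.seed(12)
  z <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6),
                                               paste0("p", 1:4)))
  fit <- pca_abundance(z)
  eig <- sort(eigen(stats::cov(scale(z, scale = FALSE)))$values,
              decreasing = TRUE)
  expect_equal(fit$explained$variance_ratio, eig / sum(eig),
               tolerance = 1e-9)
  expect_equal(sum(fit$explained$variance_ratio), 1, tolerance = 1e-9)
  # scores centered with diagonal covariance
  sc <- as.matrix(fit$scores[, -1])
  expect_true(all(abs(colMeans(sc)) < 1e-9))
  cv <- stats::cov(sc)
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-9))
  expect_error(pca_abundance(z, n_components = 10), "n_components")
})

test_that("k-means recovers separated clouds and the brute-force optimum", {
  set.seed(5)
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 5, 0.1), 5, 2))
  rownames(x) <- paste0("s", 1:10)
  cl <- kmeans_components(x, k = 2, seed = 1)
  expect_equal(length(unique(cl$cluster[1:5])), 1)
  expect_equal(length(unique(cl$cluster[6:10])), 1)
  expect_false(cl$cluster[1] == cl$cluster[6])

  cl_n <- kmeans_components(x, k = nrow(x), seed = 1)
  expect_equal(sort(unique(cl_n$cluster)), 1:10)

  # brute-force over all 2-partitions at n = 7
  set.seed(9)
  y <- matrix(rnorm(14), 7, 2)
  rownames(y) <- paste0("s", 1:7)
  wcss <- function(assign) {
    sum(vapply(unique(assign), function(k) {
      pts <- y[assign == k, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
  }
  best <- Inf
  for (code in 1:(2^6 - 1)) {  # fix point 1 in cluster 1
    assign <- c(1, as.integer(intToBits(code))[1:6] + 1L)
    if (length(unique(assign)) == 2) best <- min(best, wcss(assign))
  }
  cl_bf <- kmeans_components(y, k = 2, seed = 3)
  expect_equal(wcss(cl_bf$cluster), best, tolerance = 1e-9)

  # row-permutation invariance up to relabeling
  perm <- sample(nrow(x))
  cl_p <- kmeans_components(x[perm, ], k = 2, seed = 1)
  agree <- table(cl$cluster[perm], cl_p$cluster)
  expect_true(all(rowSums(agree > 0) == 1))
  expect_error(kmeans_components(x, k = 0), ">= 1")
})

test_that("MCA matches a direct SVD and flags degenerate inputs", {
  # identical samples: zero inertia
  pres <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4),
                                          paste0("p", 1:3)))
  expect_warning(fit <- mca_presence(pres), "constant|degenerate")
  expect_true(fit$degenerate)

  # two groups with disjoint proteomes separate on dimension 1
  pres <- rbind(matrix(rep(c(1, 1, 0, 0), each = 3), 3, 4, byrow = FALSE),
                matrix(rep(c(0, 0, 1, 1), each = 3), 3, 4, byrow = FALSE))
  dimnames(pres) <- list(paste0("s", 1:6), paste0("p", 1:4))
  fit <- mca_presence(pres)
  d1 <- fit$scores$Dim1
  expect_true(all(sign(d1[1:3]) == sign(d1[1])))
  expect_true(all(sign(d1[4:6]) == -sign(d1[1])))

  # random binary matrix: inertias equal a dense SVD recomputation
  set.seed(33)
  repeat {
    pres <- matrix(rbinom(40, 1, 0.5), 8, 5,
                   dimnames = list(paste0("s", 1:8), paste0("p", 1:5)))
    if (all(colSums(pres) > 0 & colSums(pres) < 8)) break
  }
  fit <- mca_presence(pres)
  ind <- cbind(pres, 1 - pres)
  P <- ind / sum(ind)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  d <- svd(S)$d
  d <- d[d > 1e-12]
  expect_equal(fit$explained$variance_ratio, d^2 / sum(d^2),
               tolerance = 1e-9)
})

test_that("bone effect dominating the variance drives PC1 clustering", {
  study <- generate_study(bone_dominant_spec(seed = 3))
  z <- suppressWarnings(standardize_abundance(study$abundance))
  pc <- pca_abundance(z, 3)
  cl <- kmeans_components(pc$scores[c("sample", "PC1")], k = 2, seed = 1)
  tab <- table(cl$cluster, study$meta$bone)
  expect_true(all(rowSums(tab > 0) == 1))  # clusters = bone types exactly
})
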