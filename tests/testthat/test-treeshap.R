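# Independent R oracle for per-tree Shapley values, built on ranger's
# documented treeInfo() accessor (a different code path from the C++
# engine, which reads the raw forest lists).
oracle_shap <- function(rf, x_train, x_test) {
  nfeat <- ncol(x_train)
  classes <- rf$forest$levels[rf$forest$class.values]
  ntrees <- rf$num.trees
  phi <- array(0, c(nrow(x_test), nfeat, length(classes)))
  base <- numeric(length(classes))
  for (t in seq_len(ntrees)) {
    info <- ranger::treeInfo(rf, t)
    leafval <- as.matrix(info[, grep("^pred\\.", names(info)), drop = FALSE])
    cover <- numeric(nrow(info))
    for (r in seq_len(nrow(x_train))) {
      w <- rf$inbag.counts[[t]][r]
      if (w == 0) next
      node <- 1
      repeat {
        cover[node] <- cover[node] + w
        if (info$terminal[node]) break
        node <- if (x_train[r, info$splitvarName[node]] <=
                    info$splitval[node]) {
          info$leftChild[node] + 1
        } else {
          info$rightChild[node] + 1
        }
      }
    }
    used <- unique(info$splitvarName[!info$terminal])
    v <- function(x, S) {  # conditional expectation given feature set S
      rec <- function(node, w) {
        if (info$terminal[node]) return(w * leafval[node, ])
        f <- info$splitvarName[node]
        l <- info$leftChild[node] + 1; r <- info$rightChild[node] + 1
        if (f %in% S) {
          nxt <- if (x[f] <= info$splitval[node]) l else r
          rec(nxt, w)
        } else {
          tot <- cover[l] + cover[r]
          rec(l, w * cover[l] / tot) + rec(r, w * cover[r] / tot)
        }
      }
      rec(1, 1)
    }
    k <- length(used)
    for (s in seq_len(nrow(x_test))) {
      x <- x_test[s, ]
      subsets <- if (k == 0) list(character(0)) else
        unlist(lapply(0:k, function(m) combn(used, m, simplify = FALSE)),
               recursive = FALSE)
      key <- function(S) paste0("{", paste(sort(S), collapse = "|"), "}")
      vals <- lapply(subsets, function(S) v(x, S))
      names(vals) <- vapply(subsets, key, character(1))
      for (f in used) {
        fi <- match(f, colnames(x_train))
        for (S in subsets) {
          if (f %in% S) next
          m <- length(S)
          w <- factorial(m) * factorial(k - m - 1) / factorial(k)
          key_s <- key(S)
          key_sf <- key(c(S, f))
          phi[s, fi, ] <- phi[s, fi, ] +
            w * (vals[[key_sf]] - vals[[key_s]])
        }
      }
      if (s == 1) base <- base + vals[[key(character(0))]]
    }
  }
  list(phi = phi / ntrees, base = base / ntrees, classes = classes)
}

fit_probability_forest <- function(x, y, num.trees = 7, seed = 1) {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = num.trees,
                 mtry = 2, min.node.size = 2, min.bucket = 1,
                 probability = TRUE, keep.inbag = TRUE,
                 importance = "impurity", seed = seed, num.threads = 1)
}

test_that("C++ SHAP engine matches the independent treeInfo oracle", {
  set.seed(21)
  x <- matrix(rnorm(12 * 4), 12, 4,
              dimnames = list(paste0("s", 1:12), paste0("p", 1:4)))
  for (nclass in 2:3) {
    y <- factor(rep_len(paste0("c", seq_len(nclass)), 12))
    rf <- fit_probability_forest(x, y, num.trees = 7, seed = nclass)
    got <- treeshap_ranger(rf, x, x[1:3, , drop = FALSE])
    want <- oracle_shap(rf, x, x[1:3, , drop = FALSE])
    for (s in 1:3) for (f in 1:4) for (cl in seq_along(want$classes)) {
      row <- got$values[got$values$sample == paste0("s", s) &
                          got$values$protein == paste0("p", f) &
                          got$values$class == want$classes[cl], ]
      expect_equal(row$value, want$phi[s, f, cl], tolerance = 1e-10)
    }
    expect_equal(unname(got$base[want$classes]), unname(want$base),
                 tolerance = 1e-10)
  }
})

test_that("SHAP values satisfy local accuracy against ranger predictions", {
  set.seed(22)
  x <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(paste0("s", 1:10), paste0("p", 1:5)))
  y <- factor(rep(c("a", "b"), each = 5))
  rf <- fit_probability_forest(x, y, num.trees = 50, seed = 3)
  sh <- treeshap_ranger(rf, x, x)
  pred <- stats::predict(rf, as.data.frame(x), num.threads = 1)$predictions
  for (cl in colnames(pred)) {
    for (s in rownames(x)) {
      tot <- sum(sh$values$value[sh$values$sample == s &
                                   sh$values$class == cl])
      expect_equal(unname(sh$base[cl]) + tot,
                   unname(pred[match(s, rownames(x)), cl]),
                   tolerance = 1e-6)
    }
  }
})

test_that("features unused by the forest receive zero attribution", {
  set.seed(23)
  x <- cbind(sig = rep(c(0, 10), each = 4), dead = rep(1, 8))
  rownames(x) <- paste0("s", 1:8)  # constant column can never be split on
  y <- factor(rep(c("a", "b"), each = 4))
  rf <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = 20,
                       mtry = 1, min.node.size = 2, min.bucket = 2,
                       probability = TRUE, keep.inbag = TRUE,
                       seed = 9, num.threads = 1)
  sh <- treeshap_ranger(rf, x, x[1:2, , drop = FALSE])
  expect_true(all(sh$values$value[sh$values$protein == "dead"] == 0))
  sig_attr <- abs(sh$values$value[sh$values$protein == "sig"])
  expect_gt(max(sig_attr), 0.1)
})

test_that("the engine requires inbag counts and a probability forest", {
  set.seed(24)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("u", "v"), 5))
  rf <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = 5,
                       probability = TRUE, seed = 1, num.threads = 1)
  expect_error(treeshap_ranger(rf, x, x), "keep.inbag")
})
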