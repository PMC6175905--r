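test_that("gini impurity closed forms", {
  expect_equal(gini(c(10, 0)), 0)
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(3, 1)), 0.375)
  expect_error(gini(c(0, 0)), "all-zero")
})

test_that("a separable 1-D problem is solved by a single split", {
  set.seed(61)
  x <- matrix(c(runif(20, -2, -0.1), runif(20, 1.1, 3)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c("epitope", "nonepitope"), each = 20)
  tree <- train_tree(x, y, min_leaf = 1, min_split = 2)
  nd <- tree$nodes
  expect_identical(nrow(nd), 3L)          # root + two pure leaves
  expect_identical(sum(is.na(nd$attribute)), 2L)
  expect_equal(mean((predict_tree(tree, x) >= 0.5) == (y == "epitope")), 1)
})

test_that("XOR needs depth 2; depth 1 cannot exceed 75% accuracy", {
  x <- expand.grid(f1 = c(0, 1), f2 = c(0, 1))
  x <- as.matrix(x[rep(1:4, each = 3), ])
  y <- ifelse(xor(x[, 1] > 0.5, x[, 2] > 0.5), "epitope", "nonepitope")
  deep <- train_tree(x, y, max_depth = 2, min_leaf = 1, min_split = 2)
  expect_equal(mean((predict_tree(deep, x) >= 0.5) == (y == "epitope")), 1)
  shallow <- train_tree(x, y, max_depth = 1, min_leaf = 1, min_split = 2)
  expect_lte(mean((predict_tree(shallow, x) >= 0.5) == (y == "epitope")),
             0.75)
})

test_that("training is deterministic: identical data gives identical models", {
  set.seed(62)
  x <- matrix(runif(300), ncol = 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- ifelse(x[, 2] + 0.3 * runif(100) > 0.6, "epitope", "nonepitope")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tree_model(train_tree(x, y), f1)
  write_tree_model(train_tree(x, y), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every accepted split matches the exhaustive brute-force optimum", {
  set.seed(63)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    x <- matrix(sample(0:9, 2 * n, replace = TRUE), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- sample(c("epitope", "nonepitope"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    tree <- train_tree(x, y, max_depth = 3, min_leaf = 1, min_split = 2)
    sets <- node_row_sets(tree, x)
    nd <- tree$nodes
    for (id in which(!is.na(nd$attribute))) {
      idx <- sets[[id]]
      oracle <- best_split_oracle(x[idx, , drop = FALSE],
                                  (y == "epitope")[idx], min_leaf = 1)
      # achieved Gini decrease equals the brute-force optimum
      pos <- (y == "epitope")[idx]
      l <- x[idx, nd$attribute[id]] <= nd$threshold[id]
      g2 <- function(a, b) if (a + b == 0) 0 else 1 - (a/(a+b))^2 - (b/(a+b))^2
      dec <- g2(sum(pos), sum(!pos)) -
        (sum(l) / length(l)) * g2(sum(pos & l), sum(!pos & l)) -
        (sum(!l) / length(l)) * g2(sum(pos & !l), sum(!pos & !l))
      expect_equal(dec, oracle$decrease, tolerance = 1e-10)
      expect_gte(dec, 0)
    }
    # class counts are conserved down the tree
    for (id in which(!is.na(nd$attribute))) {
      expect_identical(nd$n_epitope[id],
                       nd$n_epitope[nd$left[id]] + nd$n_epitope[nd$right[id]])
      expect_identical(nd$n_other[id],
                       nd$n_other[nd$left[id]] + nd$n_other[nd$right[id]])
    }
  }
})

test_that("prediction is the leaf epitope fraction, piecewise constant", {
  leaf_tree <- structure(list(
    nodes = data.frame(id = 1:3,
                       attribute = c(1L, NA, NA),
                       threshold = c(0.5, NA, NA),
                       left = c(2L, NA, NA), right = c(3L, NA, NA),
                       n_epitope = c(59L, 49L, 10L),
                       n_other = c(51L, 51L, 0L),
                       depth = c(0L, 1L, 1L)),
    attributes = "f1", positive = "epitope"), class = "epitree_tree")
  x <- matrix(c(0.1, 0.2, 0.9), ncol = 1, dimnames = list(NULL, "f1"))
  p <- predict_tree(leaf_tree, x)
  expect_equal(p, c(0.49, 0.49, 1.0))   # leaf (49,51) scores 0.49
  expect_identical(p[1], p[2])          # same leaf, same score
  expect_error(predict_tree(leaf_tree,
                            matrix(1, 1, 1, dimnames = list(NULL, "zz"))),
               "missing attribute")
})

test_that("single-class input yields one warning leaf", {
  x <- matrix(runif(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(tree <- train_tree(x, rep("epitope", 10)), "single-class")
  expect_identical(nrow(tree$nodes), 1L)
  expect_equal(predict_tree(tree, x), rep(1, 10))
})

test_that("forest importance recovers a planted signal attribute", {
  set.seed(64)
  n <- 300
  x <- cbind(signal = c(rnorm(n / 2, 2), rnorm(n / 2, -2)),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  y <- rep(c("epitope", "nonepitope"), each = n / 2)
  imp <- forest_importance(x, y, n_trees = 200, seed = 1)
  expect_identical(imp$attribute[1], "signal")
  expect_identical(imp$attribute[which.max(imp$decreased_accuracy)],
                   "signal")
  # pure-noise attributes sit near zero accuracy importance
  noise_acc <- imp$decreased_accuracy[imp$attribute != "signal"]
  expect_lt(max(abs(noise_acc)), imp$decreased_accuracy[1] / 2)
  # degenerate single-tree ensemble still runs
  one <- forest_importance(x, y, n_trees = 1, seed = 2)
  expect_identical(nrow(one), 4L)
  expect_error(forest_importance(x, y, n_trees = 0), "n_trees")
})
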