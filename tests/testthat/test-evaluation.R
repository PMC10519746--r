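test_that("confusion counts, recall and accuracy match a brute-force tally", {
  set.seed(41)
  truth <- sample(c("A", "B"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, ifelse(truth == "A", "B", "A"))
  cc <- confusion_counts(truth, pred, "A", "B")
  expect_equal(cc$T_A, sum(truth == "A" & pred == "A"))
  expect_equal(cc$F_B, sum(truth == "A" & pred == "B"))
  expect_equal(recall(cc, "A"),
               100 * mean(pred[truth == "A"] == "A"))
  expect_equal(recall(cc, "B"),
               100 * mean(pred[truth == "B"] == "B"))
  expect_equal(accuracy(cc), 100 * mean(truth == pred))
  # labels outside the two classes are ignored
  cc2 <- confusion_counts(c(truth, "C"), c(pred, "A"), "A", "B")
  expect_equal(accuracy(cc2), accuracy(cc))
  expect_error(confusion_counts("C", "C", "A", "B"), "no elements")
})

test_that("build_split samples exact frame counts and never shares cells", {
  specs <- list(X = phenotype_spec("X", radius_mean = 4, delta_n_mean = 0.03,
                                   n_views_range = c(8L, 15L)),
                Y = phenotype_spec("Y", radius_mean = 5, delta_n_mean = 0.03,
                                   n_views_range = c(8L, 15L)))
  man <- simulate_manifest(specs, c(12L, 9L), seed = 6)
  plan <- split_plan(c(X = 5L, Y = 4L), qpms_per_cell = 8L, seed = 2)
  sp <- build_split(man, plan)
  expect_equal(nrow(sp$train), 9L * 8L)
  expect_equal(as.vector(table(sp$train$cell_id)), rep(8L, 9))
  expect_length(intersect(sp$train$cell_id, sp$test$cell_id), 0)
  # test keeps ALL frames of every non-training cell
  rest <- man[!(man$cell_id %in% sp$train_cells), ]
  expect_equal(nrow(sp$test), nrow(rest))
  # deterministic under the plan seed
  expect_identical(sp$train, build_split(man, plan)$train)
  # too few eligible cells is an error
  expect_error(build_split(man, split_plan(c(X = 50L), 8L)), "cells with")
})

test_that("pca_first2 agrees with an eigen-decomposition oracle", {
  set.seed(51)
  x <- matrix(rnorm(300), 60, 5)
  x[, 2] <- x[, 1] + rnorm(60, 0, 0.3)
  p <- pca_first2(x)
  expect_identical(dim(p$scores), c(60L, 2L))

  e <- eigen(stats::cor(x), symmetric = TRUE)
  expect_equal(p$explained, e$values[1:2] / sum(e$values), tolerance = 1e-9)
  for (j in 1:2) {
    v <- e$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])     # the package's sign convention
    expect_equal(unname(p$loadings[, j]), v, tolerance = 1e-8)
  }
  expect_true(all(vapply(1:2, function(j) {
    p$loadings[which.max(abs(p$loadings[, j])), j] > 0
  }, logical(1))))
  expect_error(pca_first2(matrix(1, 10, 3)), "rank")
})

test_that("fisher_criterion matches its closed form", {
  a <- rbind(c(0, 0), c(2, 0))            # mean (1,0), tr cov = 2
  b <- rbind(c(4, 0), c(6, 0))            # mean (5,0), tr cov = 2
  expect_equal(fisher_criterion(a, b), 16 / 4)
  # separating the groups further increases J
  b2 <- b + 10
  expect_gt(fisher_criterion(a, b2), fisher_criterion(a, b))
  degenerate <- rbind(c(0, 0), c(0, 0))
  expect_error(fisher_criterion(degenerate, degenerate + 1),
               "zero total scatter")
})

test_that("grouped_correlation averages |r| within and across groups", {
  set.seed(61)
  f1 <- rnorm(100)
  x <- data.frame(f1 = f1, f2 = f1, g1 = rnorm(100), g2 = rnorm(100))
  groups <- list(A = c("f1", "f2"), B = c("g1", "g2"))
  M <- grouped_correlation(x, groups)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(M, t(M))
  expect_equal(M["A", "A"], 1)            # f2 duplicates f1
  expect_equal(M["A", "B"],
               mean(abs(stats::cor(x[c("f1", "f2")], x[c("g1", "g2")]))),
               tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
})

test_that("relief_rank promotes informative features and drops duplicates", {
  set.seed(71)
  n <- 120
  y <- rep(c("a", "b"), each = n / 2)
  signal <- ifelse(y == "a", 0, 3) + rnorm(n, 0, 0.5)
  x <- data.frame(signal = signal,
                  dup = signal,                  # r = 1 with 'signal'
                  noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  rk <- relief_rank(x, y, corr_threshold = 0.9, k = 10L)
  expect_false("dup" %in% rk$feature)            # filtered before ranking
  expect_equal(rk$feature[1], "signal")
  expect_gt(rk$weight[1], max(rk$weight[-1]))
  expect_error(relief_rank(x[, "signal", drop = FALSE], rep("a", n)))
})
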