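test_that("max_vote counts frames and breaks ties by mean posterior", {
  v <- max_vote(c("A", "A", "B"))
  expect_s3_class(v, "vote_result")
  expect_equal(v$winner, "A")
  expect_equal(unname(v$counts[c("A", "B")]), c(2L, 1L))
  expect_false(v$tie)

  probs <- rbind(c(A = 0.9, B = 0.1), c(A = 0.2, B = 0.8),
                 c(A = 0.55, B = 0.45), c(A = 0.1, B = 0.9))
  vt <- max_vote(c("A", "B", "A", "B"), probs = probs)
  expect_true(vt$tie)
  expect_equal(vt$winner, "B")   # mean posterior 0.5625 for B vs 0.4375 A
  expect_error(max_vote(character(0)), "empty")
})

test_that("global_probability composes and rounds path recalls", {
  expect_equal(global_probability(0.979), 97.9)
  expect_equal(global_probability(c(0.950, 0.983, 0.954)), 89.1)
  expect_equal(global_probability(c(0.5, 0.5)), 25)
  expect_error(global_probability(c(0.9, 1.2)))
  expect_error(global_probability(numeric(0)))
})

test_that("hierarchy_paths lays out one recall vector per leaf", {
  paths <- hierarchy_paths(reference_recalls())
  expect_named(paths, c("Monocyte", "CHP212", "SKNBE2", "SHSY5Y", "SKNSH"))
  expect_equal(lengths(paths),
               c(Monocyte = 1L, CHP212 = 3L, SKNBE2 = 3L,
                 SHSY5Y = 3L, SKNSH = 3L))
  expect_equal(paths$CHP212, c(0.950, 0.983, 0.954))
  expect_equal(paths$SKNSH[1:2], paths$SHSY5Y[1:2])  # shared prefix
})

test_that("the shallow net separates well-separated Gaussians and not noise", {
  set.seed(31)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 4), n, 4))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("lo", "hi"), each = n)
  spec <- shallow_net_spec(hidden_units = 20L, cv_folds = 5L)
  m <- train_level(x, y, spec, seed = 3)
  expect_s3_class(m, "shallow_net")
  expect_gte(m$cv_accuracy, 0.95)
  P <- predict(m, x, type = "prob")
  expect_equal(unname(rowSums(P)), rep(1, 2 * n), tolerance = 1e-9)
  expect_equal(as.character(predict(m, x)), y)

  # identical seed, identical weights
  m2 <- train_level(x, y, spec, seed = 3)
  expect_identical(m$theta, m2$theta)

  # shuffled labels carry no signal
  set.seed(32)
  m0 <- train_level(x, sample(y), spec, seed = 3)
  expect_lt(m0$cv_accuracy, 0.7)

  expect_error(train_level(x, rep(c("a", "b", "c"), 40), spec),
               "2 classes")
})

test_that("train_hierarchy resolves a structured toy problem end to end", {
  tab <- toy_feature_table()
  model <- train_hierarchy(tab, seed = 5)
  expect_s3_class(model, "hierarchy_model")
  expect_named(model$levels, c("L1", "L2", "L3.1", "L3.2"))
  expect_equal(model$levels$L3.2$feature_names, feature_set("fractal"))

  cells <- classify_cells(model, tab)
  expect_equal(nrow(cells), length(unique(tab$cell_id)))
  expect_true(all(cells$leaf %in% unique(tab$class)))
  expect_gte(mean(cells$leaf == cells$class), 0.9)
  # every classified cell carries its root-to-leaf vote path
  expect_true(all(vapply(cells$path, function(p)
    inherits(p$L1, "vote_result"), logical(1))))

  frames <- classify_frames(model, tab)
  expect_length(frames, nrow(tab))
  expect_gte(mean(frames == tab$class), 0.8)

  # retraining is deterministic
  model2 <- train_hierarchy(tab, seed = 5)
  expect_identical(model$levels$L1$theta, model2$levels$L1$theta)
})

test_that("baseline construction requires all five classes", {
  tab <- toy_feature_table(cells_per_class = 4L, frames_per_cell = 3L)
  expect_error(build_baselines(tab[tab$class != "SKNSH", ]),
               "five classes")
  base <- build_baselines(tab, spec = shallow_net_spec(hidden_units = 10L,
                                                       cv_folds = 0L),
                          seed = 2)
  expect_s3_class(base, "baseline_models")
  flat <- classify_cells_baseline(base, tab, "flat")
  two <- classify_cells_baseline(base, tab, "two_level")
  expect_equal(nrow(flat), 20)
  expect_true(all(two$leaf %in% unique(tab$class)))
})
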