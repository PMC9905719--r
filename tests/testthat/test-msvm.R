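test_that("kernel specifications carry exactly the parameters of their kind", {
  k <- kernel_spec("rbf", C = 10, r = 0.5)
  expect_equal(k$r, 0.5)
  expect_null(k$d)
  expect_null(kernel_spec("linear", C = 1)$r)
  expect_equal(kernel_spec("polynomial", C = 1, d = 2)$d, 2)
  expect_error(kernel_spec("rbf", C = -1), "positive")
  expect_error(kernel_spec("rbf", C = 1, r = 0), "positive width")
  expect_error(kernel_spec("polynomial", C = 1, d = 0.5), "integer degree")
})

test_that("one-vs-one training builds k(k-1)/2 binary models on class pairs", {
  d <- generate_water_data(synth_config(n_per_class = 10, seed = 5))
  feats <- c("do", "nh3n", "codmn", "tds")
  m6 <- train_ovo(d[feats], d$label, kernel_spec("linear", C = 10))
  expect_length(m6$models, 15L)
  d5 <- d[d$label != 6, ]
  m5 <- train_ovo(d5[feats], d5$label, kernel_spec("linear", C = 10))
  expect_length(m5$models, 10L)
  expect_error(train_ovo(d[d$label == 1, feats], rep(1, 10)),
               "at least 2 classes")
})

test_that("a wide-margin separable problem is fit perfectly; k = 2 reduces to one model", {
  toy <- toy_separable(20, seed = 8)
  m <- train_ovo(toy$x, toy$y, kernel_spec("linear", C = 100))
  expect_length(m$models, 1L)
  expect_equal(predict(m, toy$x), toy$y)
})

test_that("votes follow the majority and cycles fall to the decision-value tie-break", {
  pairs <- list(c("1", "2"), c("1", "3"), c("2", "3"))
  # 1 beats 2, 1 beats 3, 2 beats 3 -> class 1 with two votes
  expect_equal(ovo_vote(matrix(c(1, 1, 1), 1), pairs, c("1", "2", "3"))[1], "1")
  # cycle: 1>2, 2>3, 3>1, one vote each; summed signed scores decide
  dec <- matrix(c(0.2, -0.9, 0.4), 1)  # scores: 1: -0.7, 2: 0.2, 3: 0.5
  expect_equal(ovo_vote(dec, pairs, c("1", "2", "3"))[1], "3")
  # full tie in votes and scores -> lowest class id
  dec0 <- matrix(c(0.5, -0.5, 0.5), 1)  # cycle, all scores 0
  expect_equal(ovo_vote(dec0, pairs, c("1", "2", "3"))[1], "1")
})

test_that("voting agrees with the brute-force oracle on random decision tables", {
  set.seed(13)
  for (trial in 1:50) {
    k <- sample(2:6, 1)
    classes <- as.character(seq_len(k))
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    dec <- matrix(runif(8 * length(pairs), -1, 1), 8)
    expect_equal(as.character(ovo_vote(dec, pairs, classes)),
                 brute_vote(dec, pairs, classes))
  }
})

test_that("prediction is invariant to the order in which pairs were trained", {
  d <- generate_water_data(synth_config(n_per_class = 12, seed = 21))
  feats <- c("do", "nh3n", "codmn", "tds")
  m <- train_ovo(d[feats], d$label, kernel_spec("rbf", C = 10, r = 1))
  p0 <- predict(m, d[feats])
  set.seed(1)
  perm <- sample(length(m$pairs))
  m2 <- m
  m2$pairs <- m$pairs[perm]
  m2$models <- m$models[perm]
  expect_equal(predict(m2, d[feats]), p0)
})

test_that("prediction validates its feature columns", {
  toy <- toy_separable(10, seed = 3)
  m <- train_ovo(toy$x, toy$y, kernel_spec("linear", C = 10))
  bad <- toy$x
  colnames(bad) <- c("g1", "g2")
  expect_error(predict(m, bad[, "g1", drop = FALSE]), "feature mismatch")
})

test_that("cross-validated fitness is deterministic and hits the expected extremes", {
  toy <- toy_separable(25, seed = 2)
  loss <- cv_fitness(toy$x, toy$y, "linear", params = 2, folds = 5, seed = 3)
  expect_equal(loss, 0)
  expect_identical(cv_fitness(toy$x, toy$y, "linear", 2, 5, 3),
                   cv_fitness(toy$x, toy$y, "linear", 2, 5, 3))
  # shuffled labels on balanced classes: error near chance level
  d <- generate_water_data(synth_config(n_per_class = 20, seed = 31))
  feats <- c("do", "nh3n", "codmn", "tds")
  set.seed(77)
  yperm <- sample(d$label)
  loss_chance <- cv_fitness(d[feats], yperm, "rbf", c(0, 0), folds = 4, seed = 5)
  expect_gt(loss_chance, 5 / 6 - 0.12)
})

test_that("tuning searches the box and returns the kernel at the global best", {
  toy <- toy_separable(15, seed = 6)
  cfg <- pso_config(cbind(c(0, 1)), swarm_size = 5, t_max = 5, seed = 2)
  fit <- pso_tune(toy$x, toy$y, "linear", pso_cfg = cfg,
                  search_bounds = cbind(c(1, 1 + 1e-9)), folds = 3)
  expect_equal(fit$kernel$C, 10, tolerance = 1e-6)  # box collapsed on log10 C = 1
  expect_equal(fit$kernel$kind, "linear")
  expect_true(all(diff(fit$history) <= 0))
})
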