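# tiny dense fixtures wrapped as feature matrices
fm_of <- function(X, y) {
  structure(list(matrix = Matrix::Matrix(X, sparse = TRUE),
                 labels = y, row_ids = as.character(seq_along(y))),
            class = "feature_matrix")
}

separable_fixture <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y + rnorm(n, sd = 0.05), rnorm(n))
  fm_of(X, y)
}

test_that("network gradients match finite differences", {
  set.seed(3)
  cfg <- model_config(input_dim = 4, hidden_layers = 2, hidden_width = 3,
                      max_iterations = 1, seed = 1)
  params <- palliascreen:::init_params(cfg)
  act <- palliascreen:::activation_fns("selu")
  X <- matrix(rnorm(20), 5, 4)
  y <- c(1, 0, 1, 1, 0)
  g <- palliascreen:::grad_step(params, X, y, act)
  loss_at <- function(p) {
    logit <- palliascreen:::forward_logits(p, X, act)
    pr <- 1 / (1 + exp(-logit))
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  eps <- 1e-6
  for (l in seq_along(params$W)) {
    for (idx in sample(length(params$W[[l]]), min(4, length(params$W[[l]])))) {
      p2 <- params; p2$W[[l]][idx] <- p2$W[[l]][idx] + eps
      num <- (loss_at(p2) - g$loss) / eps
      expect_equal(g$dW[[l]][idx], num, tolerance = 1e-4)
    }
    p2 <- params; p2$b[[l]][1] <- p2$b[[l]][1] + eps
    expect_equal(g$db[[l]][1], (loss_at(p2) - g$loss) / eps, tolerance = 1e-4)
  }
})

test_that("a logistic baseline separates linearly separable toy data perfectly", {
  fm <- separable_fixture()
  cfg <- model_config(input_dim = 2, hidden_layers = 0, hidden_width = 1,
                      learning_rate = 0.05, max_iterations = 600,
                      snapshot_interval = 200, batch_size = 32, seed = 2)
  m <- train_mortality_model(fm, fm, cfg)
  expect_equal(max(m$ap_history$validation_ap), 1.0)
  expect_equal(m$selected_iteration,
               min(m$ap_history$iteration[m$ap_history$validation_ap == 1.0]))
})

test_that("training is deterministic given the seed", {
  fm <- separable_fixture(n = 120, seed = 5)
  cfg <- model_config(input_dim = 2, hidden_layers = 1, hidden_width = 8,
                      max_iterations = 150, snapshot_interval = 50,
                      batch_size = 16, seed = 9)
  m1 <- train_mortality_model(fm, fm, cfg)
  m2 <- train_mortality_model(fm, fm, cfg)
  expect_equal(m1$ap_history, m2$ap_history)
  expect_equal(m1$weights, m2$weights)
  m3 <- train_mortality_model(fm, fm, modifyList(cfg, list(seed = 10)))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("the selected snapshot maximizes validation AP, earliest on ties", {
  fm <- separable_fixture(n = 150, seed = 7)
  cfg <- model_config(input_dim = 2, hidden_layers = 1, hidden_width = 4,
                      max_iterations = 300, snapshot_interval = 60,
                      batch_size = 25, seed = 3)
  m <- train_mortality_model(fm, fm, cfg)
  best <- max(m$ap_history$validation_ap)
  expect_equal(m$ap_history$validation_ap[m$ap_history$iteration ==
                                            m$selected_iteration], best)
  expect_equal(m$selected_iteration,
               min(m$ap_history$iteration[m$ap_history$validation_ap == best]))
  # the returned weights really are the snapshot's: revalidate
  scores <- predict_probability(m, fm)
  expect_equal(average_precision(scores, fm$labels), best)
})

test_that("training loss decreases over the first epoch at a small learning rate", {
  fm <- separable_fixture(n = 256, seed = 11)
  act <- palliascreen:::activation_fns("selu")
  cfg <- model_config(input_dim = 2, hidden_layers = 1, hidden_width = 8,
                      max_iterations = 2, seed = 13)
  X <- as.matrix(fm$matrix)
  set.seed(13)
  params <- palliascreen:::init_params(cfg)
  first <- palliascreen:::grad_step(params, X, fm$labels, act)
  # one plain gradient step on the full batch
  for (l in seq_along(params$W)) {
    params$W[[l]] <- params$W[[l]] - 0.05 * first$dW[[l]]
    params$b[[l]] <- params$b[[l]] - 0.05 * first$db[[l]]
  }
  second <- palliascreen:::grad_step(params, X, fm$labels, act)
  expect_lt(second$loss, first$loss)
})

test_that("predictions are stateless, order-preserving and in (0,1)", {
  voc_names <- c("f1", "f2")
  m <- manual_logistic_model(
    tibble::tibble(feature = voc_names, kind = "SLICE",
                   support = 1L, position = 0:1),
    weights = list(f1 = 0.7, f2 = -0.2), bias = 0.1)
  X <- matrix(rnorm(10), 5, 2)
  p <- predict_probability(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, vapply(1:5, function(i)
    predict_probability(m, X[i, , drop = FALSE]), 0))
  expect_equal(predict_probability(m, X[c(2, 2), ]),
               rep(p[2], 2))
  # zero-weight model outputs exactly 0.5
  m0 <- manual_logistic_model(
    tibble::tibble(feature = voc_names, kind = "SLICE",
                   support = 1L, position = 0:1),
    weights = list(f1 = 0, f2 = 0), bias = 0)
  expect_equal(predict_probability(m0, X), rep(0.5, 5))
  expect_error(predict_probability(m, matrix(0, 2, 3)), "columns")
})

test_that("models survive a save/load round trip", {
  fm <- separable_fixture(n = 100, seed = 21)
  cfg <- model_config(input_dim = 2, hidden_layers = 1, hidden_width = 4,
                      max_iterations = 60, snapshot_interval = 30,
                      batch_size = 20, seed = 4)
  m <- train_mortality_model(fm, fm, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_probability(m2, fm), predict_probability(m, fm))
  expect_equal(m2$config, m$config)
  expect_error(load_model(file.path(tempdir(), "nope.rds")), "no such model")
})

test_that("dimension and label mismatches are errors", {
  fm <- separable_fixture(n = 64, seed = 30)
  cfg <- model_config(input_dim = 3, hidden_layers = 0, hidden_width = 1,
                      max_iterations = 10)
  expect_error(train_mortality_model(fm, fm, cfg), "input_dim")
  bad <- fm; bad$labels <- bad$labels + 1
  cfg2 <- model_config(input_dim = 2, hidden_layers = 0, hidden_width = 1,
                       max_iterations = 10)
  expect_error(train_mortality_model(bad, bad, cfg2), "0/1")
  empty <- fm_of(matrix(0, 0, 2), integer(0))
  expect_error(train_mortality_model(empty, fm, cfg2), "empty")
})
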