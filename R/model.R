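# Fully connected probabilistic classifier.
#
# A feedforward network with `hidden_layers` layers of `hidden_width` units,
# SeLU activation (self-normalizing; LeCun-normal initialization), a sigmoid
# output, log loss, and the Adam optimizer on mini-batches. hidden_layers = 0
# degenerates to logistic regression trained by the same loop. Snapshots of
# the weights are scored on validation average precision every
# `snapshot_interval` mini-batches (and at the last iteration); the
# best-scoring snapshot — earliest on ties — is the returned model.
#
# Written in plain dense matrix algebra: batches are densified on the fly
# from the sparse feature matrix, so memory stays at
# O(batch_size x input_dim).

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

#' Configure the mortality classifier
#'
#' @param input_dim Number of input features (vocabulary size).
#' @param hidden_layers Number of hidden layers; 0 gives a logistic
#'   regression baseline. The full-scale configuration uses 18.
#' @param hidden_width Units per hidden layer (full scale: 512).
#' @param activation `"selu"` (default), `"relu"` or `"tanh"`.
#' @param learning_rate Adam learning rate, default 0.001.
#' @param batch_size Mini-batch size, default 128.
#' @param snapshot_interval Mini-batches between validation snapshots,
#'   default 250.
#' @param max_iterations Total mini-batch iterations to run.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `model_config` list.
#' @export
model_config <- function(input_dim,
                         hidden_layers = 18L,
                         hidden_width = 512L,
                         activation = c("selu", "relu", "tanh"),
                         learning_rate = 0.001,
                         batch_size = 128L,
                         snapshot_interval = 250L,
                         max_iterations = 2000L,
                         seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, hidden_layers >= 0,
            hidden_layers == 0 || hidden_width >= 1,
            learning_rate > 0, batch_size >= 1, snapshot_interval >= 1,
            max_iterations >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 activation = activation,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 snapshot_interval = as.integer(snapshot_interval),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "model_config")
}

activation_fns <- function(name) {
  switch(name,
    selu = list(
      f = function(z) SELU_LAMBDA * ifelse(z > 0, z, SELU_ALPHA * (exp(z) - 1)),
      df = function(z) SELU_LAMBDA * ifelse(z > 0, 1, SELU_ALPHA * exp(z))
    ),
    relu = list(
      f = function(z) pmax(z, 0),
      df = function(z) (z > 0) * 1
    ),
    tanh = list(
      f = tanh,
      df = function(z) 1 - tanh(z)^2
    )
  )
}

init_params <- function(config) {
  dims <- c(config$input_dim,
            rep(config$hidden_width, config$hidden_layers), 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    # LeCun normal: the initialization under which SeLU self-normalizes
    W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1L], sd = 1 / sqrt(fan_in)),
                     fan_in, dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

forward_logits <- function(params, X, act) {
  H <- X
  L <- length(params$W)
  for (l in seq_len(L - 1L)) {
    Z <- H %*% params$W[[l]]
    Z <- sweep(Z, 2L, params$b[[l]], `+`)
    H <- act$f(Z)
  }
  drop(H %*% params$W[[L]] + params$b[[L]])
}

# forward with cached pre-activations, then backprop of mean log loss
grad_step <- function(params, X, y, act) {
  L <- length(params$W)
  Zs <- vector("list", L - 1L)
  Hs <- vector("list", L)
  Hs[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- Hs[[l]] %*% params$W[[l]]
    Z <- sweep(Z, 2L, params$b[[l]], `+`)
    Zs[[l]] <- Z
    Hs[[l + 1L]] <- act$f(Z)
  }
  logit <- drop(Hs[[L]] %*% params$W[[L]] + params$b[[L]])
  p <- sigmoid(logit)
  n <- length(y)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- matrix((p - y) / n, ncol = 1L)
  dW[[L]] <- crossprod(Hs[[L]], delta)
  db[[L]] <- colSums(delta)
  back <- delta %*% t(params$W[[L]])
  for (l in rev(seq_len(L - 1L))) {
    delta <- back * act$df(Zs[[l]])
    dW[[l]] <- crossprod(Hs[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) back <- delta %*% t(params$W[[l]])
  }
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(dW = dW, db = db, loss = loss)
}

#' Train the mortality classifier
#'
#' Minimizes log loss with Adam on shuffled mini-batches and performs
#' snapshot-based model selection: every `snapshot_interval` iterations (and
#' at the final iteration) the current weights are scored by average
#' precision on the validation set, and the best snapshot (earliest on ties)
#' becomes the returned model. No explicit regularization is applied.
#' Deterministic given `config$seed` on a fixed machine.
#'
#' @param train_fm,validation_fm `feature_matrix` objects over the same
#'   vocabulary (see [vectorize()]).
#' @param config A [model_config()]; its `input_dim` must match the matrices.
#' @return A `mortality_model`: weights, config, `ap_history` tibble
#'   (`iteration`, `validation_ap`), `selected_iteration`, and the feature
#'   names the model was trained on.
#' @export
train_mortality_model <- function(train_fm, validation_fm, config) {
  stopifnot(inherits(train_fm, "feature_matrix"),
            inherits(validation_fm, "feature_matrix"),
            inherits(config, "model_config"))
  if (ncol(train_fm$matrix) != config$input_dim ||
      ncol(validation_fm$matrix) != config$input_dim) {
    stop("feature matrices do not match config$input_dim", call. = FALSE)
  }
  if (nrow(train_fm$matrix) == 0) stop("empty training matrix", call. = FALSE)
  if (!all(train_fm$labels %in% 0:1) || !all(validation_fm$labels %in% 0:1)) {
    stop("labels must be 0/1", call. = FALSE)
  }

  act <- activation_fns(config$activation)
  Xval <- as.matrix(validation_fm$matrix)
  yval <- validation_fm$labels
  n <- nrow(train_fm$matrix)
  y <- train_fm$labels

  with_preserved_seed({
    set.seed(config$seed)
    params <- init_params(config)
    adam <- list(
      mW = lapply(params$W, function(w) w * 0),
      vW = lapply(params$W, function(w) w * 0),
      mb = lapply(params$b, function(b) b * 0),
      vb = lapply(params$b, function(b) b * 0)
    )
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate

    order_idx <- sample.int(n)
    cursor <- 1L
    best <- list(ap = -Inf, iteration = NA_integer_, params = NULL)
    history <- list()

    snapshot <- function(it, params) {
      scores <- sigmoid(forward_logits(params, Xval, act))
      ap <- if (any(yval == 1)) average_precision(scores, yval) else NA_real_
      history[[length(history) + 1L]] <<- tibble::tibble(
        iteration = it, validation_ap = ap)
      if (!is.na(ap) && ap > best$ap) {
        best <<- list(ap = ap, iteration = it,
                      params = list(W = lapply(params$W, identity),
                                    b = lapply(params$b, identity)))
      }
    }

    for (it in seq_len(config$max_iterations)) {
      if (cursor + config$batch_size - 1L > n) {
        order_idx <- sample.int(n)
        cursor <- 1L
      }
      take <- min(config$batch_size, n)
      idx <- order_idx[cursor:(cursor + take - 1L)]
      cursor <- cursor + take
      Xb <- as.matrix(train_fm$matrix[idx, , drop = FALSE])
      g <- grad_step(params, Xb, y[idx], act)
      bc1 <- 1 - beta1^it
      bc2 <- 1 - beta2^it
      for (l in seq_along(params$W)) {
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * g$dW[[l]]
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * g$dW[[l]]^2
        params$W[[l]] <- params$W[[l]] -
          lr * (adam$mW[[l]] / bc1) / (sqrt(adam$vW[[l]] / bc2) + eps)
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * g$db[[l]]
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * g$db[[l]]^2
        params$b[[l]] <- params$b[[l]] -
          lr * (adam$mb[[l]] / bc1) / (sqrt(adam$vb[[l]] / bc2) + eps)
      }
      if (it %% config$snapshot_interval == 0L || it == config$max_iterations) {
        snapshot(it, params)
      }
    }

    new_mortality_model(
      weights = best$params,
      config = config,
      ap_history = dplyr::bind_rows(history),
      selected_iteration = best$iteration,
      feature_names = colnames(train_fm$matrix)
    )
  })
}

new_mortality_model <- function(weights, config, ap_history = NULL,
                                selected_iteration = NA_integer_,
                                feature_names = NULL) {
  structure(list(weights = weights, config = config,
                 ap_history = ap_history,
                 selected_iteration = selected_iteration,
                 feature_names = feature_names),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cfg <- x$config
  cat("<mortality_model> ", cfg$hidden_layers, " x ", cfg$hidden_width,
      " ", cfg$activation,
      if (cfg$hidden_layers == 0) " (logistic baseline)",
      ", input dim ", cfg$input_dim, "\n", sep = "")
  if (!is.null(x$ap_history) && nrow(x$ap_history) > 0) {
    cat("  selected snapshot at iteration ", x$selected_iteration,
        " (validation AP ", sprintf("%.4f", max(x$ap_history$validation_ap)),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Predict 12-month death probabilities
#'
#' @param model A `mortality_model`.
#' @param newdata A `feature_matrix`, sparse or dense matrix with
#'   `input_dim` columns.
#' @return Numeric vector of probabilities in (0, 1), one per row, in row
#'   order.
#' @export
predict_probability <- function(model, newdata) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$matrix else newdata
  X <- as.matrix(X)
  if (ncol(X) != model$config$input_dim) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         model$config$input_dim, call. = FALSE)
  }
  act <- activation_fns(model$config$activation)
  unname(sigmoid(forward_logits(model$weights, X, act)))
}

#' @export
predict.mortality_model <- function(object, newdata, ...) {
  predict_probability(object, newdata)
}

#' Save / load a trained model
#'
#' Round-trip preserves predictions exactly.
#'
#' @param model A `mortality_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mortality_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  m <- tryCatch(readRDS(path), error = function(e) {
    stop("could not load model from ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!inherits(m, "mortality_model")) {
    stop("file ", path, " does not contain a mortality_model", call. = FALSE)
  }
  m
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Snapshot history of a trained model
#'
#' @param x A `mortality_model`.
#' @param ... Unused.
#' @return Tibble `iteration`, `validation_ap`, `selected`.
#' @export
tidy.mortality_model <- function(x, ...) {
  h <- x$ap_history
  if (is.null(h)) return(tibble::tibble(iteration = integer(),
                                        validation_ap = double(),
                                        selected = logical()))
  dplyr::mutate(h, selected = .data$iteration == x$selected_iteration)
}

#' One-row summary of a trained model
#'
#' @param x A `mortality_model`.
#' @param ... Unused.
#' @return Tibble with architecture, parameter count, snapshots and best
#'   validation AP.
#' @export
glance.mortality_model <- function(x, ...) {
  n_par <- sum(vapply(x$weights$W, length, 0)) +
    sum(vapply(x$weights$b, length, 0))
  tibble::tibble(
    hidden_layers = x$config$hidden_layers,
    hidden_width = x$config$hidden_width,
    activation = x$config$activation,
    n_parameters = n_par,
    n_snapshots = if (is.null(x$ap_history)) 0L else nrow(x$ap_history),
    selected_iteration = x$selected_iteration,
    best_validation_ap = if (is.null(x$ap_history) || nrow(x$ap_history) == 0)
      NA_real_ else max(x$ap_history$validation_ap)
  )
}

#' @export
autoplot.mortality_model <- function(object, ...) {
  h <- tidy(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$validation_ap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected)) +
    ggplot2::labs(x = "mini-batch iteration", y = "validation AP",
                  title = "Snapshot model selection") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
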