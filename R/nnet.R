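#' Network configuration
#'
#' Configuration of one feedforward classification network: one sigmoid hidden
#' layer (by default twice the input width) and three sigmoid output nodes,
#' one per ion class, trained by per-instance stochastic gradient descent
#' with momentum on the summed per-node binary cross-entropy.
#'
#' @param input_dim number of input features.
#' @param hidden_dim hidden layer width (default `2 * input_dim`).
#' @param learning_rate SGD step size (default 0.1).
#' @param momentum momentum coefficient in `[0, 1)` (default 0.9).
#' @param max_epochs upper bound on training epochs (default 50).
#' @param seed RNG seed for weight initialisation and epoch shuffling.
#' @return list of class `net_config`.
#' @export
net_config <- function(input_dim, hidden_dim = 2L * input_dim,
                       learning_rate = 0.1, momentum = 0.9,
                       max_epochs = 50L, seed = 1L) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1, max_epochs >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 output_dim = 3L,
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "net_config")
}

#' Initialise a network
#'
#' Seeded weight initialisation: uniform(-0.5, 0.5) scaled by `1/sqrt(fan-in)`
#' per layer; biases start at zero.
#'
#' @param config a [net_config].
#' @param feature_names optional input feature names, stored for provenance.
#' @param stage optional stage tag (`"net1"` or `"net2"`).
#' @return object of class `ffnet` with weight matrices `W1` (hidden x input),
#'   `W2` (3 x hidden), bias vectors `b1`, `b2`, and an empty training log.
#' @export
nn_init <- function(config, feature_names = NULL, stage = NA_character_) {
  d <- config$input_dim; h <- config$hidden_dim; o <- config$output_dim
  with_seed(config$seed, {
    W1 <- matrix(runif(h * d, -0.5, 0.5) / sqrt(d), h, d)
    W2 <- matrix(runif(o * h, -0.5, 0.5) / sqrt(h), o, h)
  })
  structure(list(W1 = W1, b1 = numeric(h), W2 = W2, b2 = numeric(o),
                 config = config, stage = stage,
                 feature_names = feature_names,
                 training_log = data.frame(epoch = integer(),
                                           train_error = numeric(),
                                           val_error = numeric()),
                 stopped_epoch = NA_integer_),
            class = "ffnet")
}

#' @export
print.ffnet <- function(x, ...) {
  cat(sprintf("feedforward net (%s): %d -> %d -> 3 sigmoid units\n",
              ifelse(is.na(x$stage), "unstaged", x$stage),
              x$config$input_dim, x$config$hidden_dim))
  if (nrow(x$training_log))
    cat(sprintf("  trained %d epoch(s), kept epoch %d (val error %.4f)\n",
                nrow(x$training_log), x$stopped_epoch,
                x$training_log$val_error[x$stopped_epoch]))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass
#'
#' Computes the three class-probability estimates for one or more feature
#' vectors. The outputs are independent sigmoids, so rows need not sum to 1;
#' renormalise at reporting time if probabilities summing to one are wanted.
#'
#' @param net an `ffnet`.
#' @param x numeric vector of length `input_dim` or an n x `input_dim`
#'   matrix.
#' @return n x 3 matrix of outputs in (0, 1), columns `b`, `y`, `u`.
#' @export
nn_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$config$input_dim)
    stop(sprintf("expected %d features, got %d", net$config$input_dim, ncol(x)))
  h <- sigmoid(sweep(x %*% t(net$W1), 2, net$b1, `+`))
  o <- sigmoid(sweep(h %*% t(net$W2), 2, net$b2, `+`))
  colnames(o) <- c("b", "y", "u")
  o
}

#' Cross-entropy network error
#'
#' The training objective: the sum over the three output nodes of the binary
#' cross-entropy `-(t log o + (1 - t) log(1 - o))`, with outputs clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param t binary target vector of length 3, or an n x 3 matrix.
#' @param o output vector/matrix of matching shape.
#' @return scalar error, or a vector of per-row errors for matrix input.
#' @export
cross_entropy <- function(t, o) {
  o <- pmin(pmax(o, 1e-12), 1 - 1e-12)
  if (is.null(dim(t))) return(-sum(t * log(o) + (1 - t) * log(1 - o)))
  -rowSums(t * log(o) + (1 - t) * log(1 - o))
}

#' Analytic gradients for a single instance
#'
#' Exact derivatives of [cross_entropy] with respect to every parameter, for
#' one feature/target pair. Used by the training loop (in compiled form) and
#' by the finite-difference correctness checks.
#'
#' @param net an `ffnet`.
#' @param x feature vector.
#' @param t binary target vector of length 3.
#' @return list with gradient arrays `W1`, `b1`, `W2`, `b2`.
#' @export
nn_gradients <- function(net, x, t) {
  x <- as.numeric(x)
  h <- as.numeric(sigmoid(net$W1 %*% x + net$b1))
  o <- as.numeric(sigmoid(net$W2 %*% h + net$b2))
  d2 <- o - t
  d1 <- as.numeric(t(net$W2) %*% d2) * h * (1 - h)
  list(W1 = d1 %o% x, b1 = d1, W2 = d2 %o% h, b2 = d2)
}

#' One training epoch
#'
#' Runs one pass of per-instance stochastic gradient descent with momentum
#' over the batch, visiting instances in a freshly shuffled order drawn from
#' the current RNG stream.
#'
#' @param net an `ffnet` (with momentum state in `velocity`, created on first
#'   use).
#' @param X n x `input_dim` feature matrix.
#' @param T n x 3 target matrix.
#' @return the updated `ffnet`, with the epoch's mean cross-entropy in
#'   attribute `"mean_error"`.
#' @export
backprop_epoch <- function(net, X, T) {
  stopifnot(nrow(X) > 0, nrow(X) == nrow(T))
  if (is.null(net$velocity))
    net$velocity <- list(W1 = net$W1 * 0, b1 = net$b1 * 0,
                         W2 = net$W2 * 0, b2 = net$b2 * 0)
  ord <- sample.int(nrow(X))
  upd <- cpp_backprop_epoch(net$W1, net$b1, net$W2, net$b2,
                            net$velocity$W1, net$velocity$b1,
                            net$velocity$W2, net$velocity$b2,
                            X, T, ord,
                            net$config$learning_rate, net$config$momentum)
  net$W1 <- upd$W1; net$b1 <- upd$b1; net$W2 <- upd$W2; net$b2 <- upd$b2
  net$velocity <- list(W1 = upd$vW1, b1 = upd$vb1, W2 = upd$vW2, b2 = upd$vb2)
  attr(net, "mean_error") <- upd$mean_error
  net
}

misclassification_rate <- function(net, X, T) {
  if (!nrow(X)) return(0)
  o <- nn_forward(net, X)
  mean(max.col(o, ties.method = "first") != max.col(T, ties.method = "first"))
}

#' Train a network with validation-based early stopping
#'
#' Trains by repeated [backprop_epoch] passes over the backpropagation set.
#' After each epoch the misclassification rate (argmax of output vs argmax of
#' target) on the validation set is computed; at the first epoch whose
#' validation error exceeds the previous epoch's, training stops and the
#' previous epoch's parameters are restored. Training also stops at
#' `max_epochs`. Fully deterministic given the config seed.
#'
#' @param config a [net_config].
#' @param X,T backpropagation feature/target matrices.
#' @param val_X,val_T validation feature/target matrices.
#' @param feature_names,stage passed to [nn_init].
#' @return trained `ffnet` with a per-epoch `training_log` and
#'   `stopped_epoch` set to the epoch whose parameters were kept.
#' @export
train_nn <- function(config, X, T, val_X, val_T,
                     feature_names = colnames(X), stage = NA_character_) {
  stopifnot(nrow(X) > 0, nrow(val_X) > 0)
  net <- nn_init(config, feature_names = feature_names, stage = stage)
  with_seed(config$seed + 1L, {
    prev <- net
    prev_val <- Inf
    for (epoch in seq_len(config$max_epochs)) {
      cand <- backprop_epoch(net, X, T)
      val_err <- misclassification_rate(cand, val_X, val_T)
      cand$training_log <- rbind(net$training_log,
                                 data.frame(epoch = epoch,
                                            train_error = attr(cand, "mean_error"),
                                            val_error = val_err))
      attr(cand, "mean_error") <- NULL
      if (val_err > prev_val) {
        net <- prev
        net$training_log <- cand$training_log
        net$stopped_epoch <- epoch - 1L
        break
      }
      prev <- cand
      prev_val <- val_err
      net <- cand
      net$stopped_epoch <- epoch
    }
  })
  net$velocity <- NULL
  net
}

#' Balance training classes
#'
#' The b-/y-/u class mix of the backpropagation set controls the classifier's
#' precision/recall balance; training uses an equal count of b and y
#' instances, with the (much more numerous) u instances downsampled to
#' `ratio` times that count. Sampling is seeded and without replacement.
#'
#' @param labels per-instance labels (`b`/`y`/`u` factor or character).
#' @param ratio u instances retained per b/y instance (default 1, i.e. equal
#'   counts).
#' @param seed RNG seed for the subsample.
#' @return sorted integer vector of retained instance indices.
#' @export
balance_classes <- function(labels, ratio = 1, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(factor(labels, levels = c("b", "y", "u")))
  absent <- names(counts)[counts == 0]
  if (length(absent))
    stop("class(es) absent from the training instances: ",
         paste(absent, collapse = ", "))
  m <- min(counts[["b"]], counts[["y"]])
  n_u <- min(round(ratio * m), counts[["u"]])
  with_seed(seed, {
    keep <- c(sample(which(labels == "b"), m),
              sample(which(labels == "y"), m),
              sample(which(labels == "u"), n_u))
  })
  sort(keep)
}

#' Save / load a trained network
#'
#' JSON serialisation at full numeric precision: a reloaded model reproduces
#' [nn_forward] outputs bit-identically. The file records a schema version,
#' the stage tag and the input feature ordering.
#'
#' @param net an `ffnet`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `ffnet`.
#' @export
save_model <- function(net, path) {
  payload <- list(schema = "peakstage-ffnet-1",
                  stage = net$stage,
                  feature_names = net$feature_names,
                  config = unclass(net$config),
                  W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
                  training_log = net$training_log,
                  stopped_epoch = net$stopped_epoch)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot read model file: ",
                                         conditionMessage(e)))
  if (!identical(x$schema, "peakstage-ffnet-1"))
    stop("unrecognised model schema in ", path)
  cfg <- do.call(net_config, x$config[c("input_dim", "hidden_dim",
                                        "learning_rate", "momentum",
                                        "max_epochs", "seed")])
  structure(list(W1 = matrix(x$W1, cfg$hidden_dim, cfg$input_dim, byrow = FALSE),
                 b1 = as.numeric(x$b1),
                 W2 = matrix(x$W2, 3, cfg$hidden_dim, byrow = FALSE),
                 b2 = as.numeric(x$b2),
                 config = cfg,
                 stage = if (is.null(x$stage)) NA_character_ else x$stage,
                 feature_names = x$feature_names,
                 training_log = as.data.frame(x$training_log),
                 stopped_epoch = x$stopped_epoch),
            class = "ffnet")
}
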