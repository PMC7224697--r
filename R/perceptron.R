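#' Train a linear perceptron
#'
#' Classic perceptron learning rule (the decoder used for the stimulus-pair
#' readout): cycle through the training samples in a seeded random order,
#' and on every misclassified sample add \code{lr * y * x} to the weights.
#' Training stops after an error-free pass or \code{max_epochs}.
#'
#' @param X samples x features matrix.
#' @param y labels in \code{{-1, +1}}.
#' @param lr learning rate.
#' @param max_epochs maximum passes over the data.
#' @param seed seed for the sample order.
#' @return List with \code{w}, \code{b}, and the function
#'   \code{predict(Xnew)} is available via \code{\link{perceptron_predict}}.
#' @export
perceptron_train <- function(X, y, lr = 0.1, max_epochs = 100, seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  w <- numeric(ncol(X)); b <- 0
  ord <- withr_seed(seed, sample.int(nrow(X)))
  for (ep in seq_len(max_epochs)) {
    errors <- 0L
    for (i in ord) {
      if (y[i] * (sum(w * X[i, ]) + b) <= 0) {
        w <- w + lr * y[i] * X[i, ]
        b <- b + lr * y[i]
        errors <- errors + 1L
      }
    }
    if (errors == 0L) break
  }
  list(w = w, b = b)
}

#' @rdname perceptron_train
#' @param model a fitted perceptron.
#' @param X samples x features matrix.
#' @return Predicted labels in \code{{-1, +1}}.
#' @export
perceptron_predict <- function(model, X) {
  ifelse(as.vector(X %*% model$w) + model$b >= 0, 1, -1)
}

# Train/test a pair decoder on alternating windows; returns test accuracy.
decode_pair <- function(X, y, seed = 1L) {
  idx <- seq_len(nrow(X))
  train <- idx %% 2 == 1
  m <- perceptron_train(X[train, , drop = FALSE], y[train], seed = seed)
  mean(perceptron_predict(m, X[!train, , drop = FALSE]) == y[!train])
}
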