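# Reference implementations of the network's primitive operations.
# These are the documented, testable building blocks; training uses
# compiled equivalents (src/) that are cross-checked against these.

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

apply_activation <- function(x, activation) {
  switch(activation,
    relu = relu(x),
    tanh = tanh(x),
    leaky_relu = leaky_relu(x),
    linear = x,
    stop("unknown activation '", activation, "'")
  )
}

#' 2-D valid convolution layer
#'
#' Valid (no padding) cross-correlation of a multi-channel spatial map
#' with a bank of kernels, plus bias and activation. With the default
#' geometry this realizes the published layer chain
#' 5x5x3 -> 2x2x20 -> 1x1x5 -> 1x1x1.
#'
#' @param input Numeric array `h x w x channels`.
#' @param kernel Numeric array `k x k x channels x filters`.
#' @param bias Numeric vector, one per filter.
#' @param stride Spatial stride (default 1).
#' @param activation One of `"relu"`, `"tanh"`, `"leaky_relu"`, `"linear"`.
#' @param layer Name used in error messages.
#' @return Numeric array `oh x ow x filters` with
#'   `oh = (h - k) / stride + 1`.
#' @export
conv_forward <- function(input, kernel, bias, stride = 1,
                         activation = "relu", layer = "conv") {
  di <- dim(input); dk <- dim(kernel)
  if (length(di) != 3L || length(dk) != 4L) {
    stop("dimension error in layer '", layer,
         "': input must be h x w x ch, kernel k x k x ch x filters")
  }
  if (di[3] != dk[3]) {
    stop("dimension error in layer '", layer, "': input has ", di[3],
         " channels but kernel expects ", dk[3])
  }
  k <- dk[1]
  if (di[1] < k || di[2] < k) {
    stop("dimension error in layer '", layer, "': spatial size ", di[1],
         "x", di[2], " smaller than kernel ", k, "x", k)
  }
  oh <- (di[1] - k) %/% stride + 1L
  ow <- (di[2] - k) %/% stride + 1L
  nf <- dk[4]
  out <- array(0, dim = c(oh, ow, nf))
  for (f in seq_len(nf)) {
    for (pr in seq_len(oh)) {
      for (pc in seq_len(ow)) {
        r0 <- (pr - 1L) * stride
        c0 <- (pc - 1L) * stride
        patch <- input[r0 + seq_len(k), c0 + seq_len(k), , drop = FALSE]
        out[pr, pc, f] <-
          sum(as.vector(patch) * as.vector(kernel[, , , f])) + bias[f]
      }
    }
  }
  apply_activation(out, activation)
}

#' Batch normalization
#'
#' Standardizes each feature over a mini-batch and rescales with the
#' learnable parameters gamma and beta: with batch mean `mu` and
#' (population) batch variance `v`, the output is
#' `gamma * (x - mu) / sqrt(v + eps) + beta`. In training mode the batch
#' statistics are used and exponential running statistics are updated; in
#' inference mode the running statistics are used instead.
#'
#' @param x Numeric matrix, one row per batch member, one column per
#'   feature.
#' @param gamma,beta Learnable per-feature scale and shift.
#' @param eps Stability constant added to the variance.
#' @param training Logical; training mode requires at least 2 rows.
#' @param running_mean,running_var Inference-time statistics (default
#'   zeros / ones).
#' @param momentum Running-statistic momentum (fraction of the old value
#'   kept at each update).
#' @return List with `y` (normalized matrix), `batch_mean`, `batch_var`,
#'   and the updated `running_mean`, `running_var`.
#' @export
batchnorm_forward <- function(x, gamma, beta, eps = 1e-5, training = TRUE,
                              running_mean = NULL, running_var = NULL,
                              momentum = 0.9) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(length(gamma) == p, length(beta) == p)
  if (is.null(running_mean)) running_mean <- rep(0, p)
  if (is.null(running_var)) running_var <- rep(1, p)
  if (training) {
    m <- nrow(x)
    if (m < 2) stop("batch normalization in training mode needs m >= 2")
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)  # population variance over the batch
    xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
    running_mean <- momentum * running_mean + (1 - momentum) * mu
    running_var <- momentum * running_var + (1 - momentum) * v
  } else {
    mu <- running_mean
    v <- running_var
    xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
  }
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, batch_mean = mu, batch_var = v,
       running_mean = running_mean, running_var = running_var)
}

#' LSTM forward pass over one sequence
#'
#' Standard LSTM recurrence with a forget-gate bias offset added to the
#' forget-gate pre-activation and a configurable cell activation
#' (default ReLU, as in the published configuration). Gate weights are
#' stored as one block matrix with column order (input, forget,
#' candidate, output).
#'
#' @param inputs Numeric matrix, one row per timestep.
#' @param params List with `Wx` (`d x 4*units`), `Wh`
#'   (`units x 4*units`) and `b` (length `4*units`).
#' @param units Hidden-state dimension (default 36).
#' @param forget_bias Constant added to the forget-gate pre-activation
#'   (default 0.7).
#' @param activation Cell activation, `"relu"` or `"tanh"`.
#' @param return_sequence If `TRUE`, return the full hidden-state matrix
#'   (timesteps x units) instead of only the final state.
#' @return Final hidden state (numeric vector of length `units`), or the
#'   full hidden sequence.
#' @export
lstm_forward <- function(inputs, params, units = 36, forget_bias = 0.7,
                         activation = "relu", return_sequence = FALSE) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) < 1) stop("LSTM requires a non-empty input sequence")
  stopifnot(ncol(params$Wx) == 4 * units, ncol(params$Wh) == 4 * units,
            length(params$b) == 4 * units)
  h <- rep(0, units)
  cc <- rep(0, units)
  hs <- matrix(0, nrow(inputs), units)
  gi <- seq_len(units)
  for (t in seq_len(nrow(inputs))) {
    g <- drop(inputs[t, ] %*% params$Wx) + drop(h %*% params$Wh) + params$b
    i_g <- sigmoid(g[gi])
    f_g <- sigmoid(g[units + gi] + forget_bias)
    c_g <- apply_activation(g[2 * units + gi], activation)
    o_g <- sigmoid(g[3 * units + gi])
    cc <- f_g * cc + i_g * c_g
    h <- o_g * apply_activation(cc, activation)
    hs[t, ] <- h
  }
  if (return_sequence) hs else h
}

#' Skip concatenation
#'
#' The network's skip connection: the input of the first fully connected
#' layer is the concatenation (not the sum) of the LSTM output vector and
#' the network's raw input vector, LSTM output first.
#'
#' @param olstm LSTM output vector.
#' @param x Raw flattened input vector of the network.
#' @return Numeric vector `c(olstm, x)`.
#' @export
skip_concat <- function(olstm, x) {
  if (!all(is.finite(olstm)) || !all(is.finite(x))) {
    stop("skip_concat requires finite inputs")
  }
  c(olstm, x)
}

#' Softmax
#'
#' Converts logits to a probability distribution,
#' `q_i = exp(q'_i) / sum_j exp(q'_j)`, stabilized by subtracting the row
#' maximum before exponentiation.
#'
#' @param q Numeric vector of logits, or a matrix with one logit row per
#'   example.
#' @return Probabilities of the same shape, each (row) summing to 1.
#' @export
softmax <- function(q) {
  if (is.matrix(q)) {
    z <- exp(q - apply(q, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(q - max(q))
    z / sum(z)
  }
}

#' Predicted class from probabilities
#'
#' Returns the phase code (0-3) with the largest probability; ties break
#' toward the lowest code.
#'
#' @param q Probability vector, or matrix with one row per example.
#' @return Integer class code(s) in `0 .. length(q) - 1`.
#' @export
predict_class <- function(q) {
  if (is.matrix(q)) {
    as.integer(max.col(q, ties.method = "first") - 1L)
  } else {
    as.integer(which.max(q) - 1L)
  }
}

#' Cross-entropy loss
#'
#' `l = -sum_i y_i log(q_i)`, which for a one-hot target reduces to
#' `-log` of the probability assigned to the true class. Probabilities
#' are clamped at `1e-12` so the loss is always finite.
#'
#' @param y True class as an integer code (0-based) or a one-hot vector.
#' @param q Predicted probability vector.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(y, q) {
  if (length(y) == 1L) {
    qt <- q[y + 1L]
  } else {
    stopifnot(length(y) == length(q))
    qt <- sum(y * q)
  }
  -log(max(qt, 1e-12))
}
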