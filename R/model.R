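# Model construction, training and prediction.

#' Network configuration
#'
#' Collects the architecture hyperparameters of the gait-phase networks.
#' Defaults reproduce the published configuration: a 4x4/20-filter valid
#' convolution taking each 5x5x3 sub-window map to 2x2x20, a second
#' convolution to 1x1x5, a 1x1 convolution to 1x1x1, a 36-unit LSTM with
#' forget-gate bias 0.7 and ReLU activation, and fully connected layers
#' of 160 and 60 units (leaky ReLU) ahead of the 4-class softmax. The
#' second convolution uses a 2x2 kernel, the only valid-geometry kernel
#' that maps 2x2 to 1x1.
#'
#' @param map_rows,map_cols Spatial shape of one sub-window map.
#' @param channels Input channels (3 acceleration axes).
#' @param n_sub Sub-windows per example (LSTM sequence length).
#' @param conv_filters Filters of the three convolution layers.
#' @param conv_kernels Kernel sizes of the three layers; defaults to
#'   `c(4, map_rows - 4 + 1, 1)` so the chain ends at 1x1.
#' @param lstm_units LSTM hidden size.
#' @param forget_bias Constant added to the forget-gate pre-activation.
#' @param lstm_activation `"relu"` (as published) or `"tanh"`.
#' @param fc_units Sizes of the two hidden fully connected layers.
#' @param n_classes Number of output classes.
#' @param bn_eps Batch-normalization stability constant.
#' @param bn_momentum Running-statistic momentum for inference-time BN.
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @return A list of class `"gaitnet_config"`.
#' @export
model_config <- function(map_rows = 5, map_cols = 5, channels = 3,
                         n_sub = 8, conv_filters = c(20, 5, 1),
                         conv_kernels = NULL, lstm_units = 36,
                         forget_bias = 0.7, lstm_activation = "relu",
                         fc_units = c(160, 60), n_classes = 4,
                         bn_eps = 1e-5, bn_momentum = 0.9,
                         leaky_slope = 0.01) {
  if (map_rows != map_cols) {
    stop("the convolutional front end requires square sub-window maps")
  }
  if (is.null(conv_kernels)) {
    conv_kernels <- c(4, map_rows - 4 + 1, 1)
  }
  if (length(conv_filters) != 3L || length(conv_kernels) != 3L) {
    stop("`conv_filters` and `conv_kernels` must each have length 3")
  }
  m1 <- map_rows - conv_kernels[1] + 1
  if (m1 < 1) stop("first conv kernel larger than the input map")
  if (conv_kernels[2] != m1) {
    stop("second conv kernel must equal the first feature-map size (",
         m1, ") so the chain reaches 1x1")
  }
  if (conv_kernels[3] != 1) stop("third conv layer must use a 1x1 kernel")
  if (!lstm_activation %in% c("relu", "tanh")) {
    stop("`lstm_activation` must be 'relu' or 'tanh'")
  }
  structure(
    list(map_rows = as.integer(map_rows), map_cols = as.integer(map_cols),
         channels = as.integer(channels), n_sub = as.integer(n_sub),
         conv_filters = as.integer(conv_filters),
         conv_kernels = as.integer(conv_kernels),
         lstm_units = as.integer(lstm_units),
         forget_bias = as.numeric(forget_bias),
         lstm_activation = lstm_activation,
         fc_units = as.integer(fc_units),
         n_classes = as.integer(n_classes),
         bn_eps = as.numeric(bn_eps), bn_momentum = as.numeric(bn_momentum),
         leaky_slope = as.numeric(leaky_slope),
         use_skip = TRUE, use_bn = TRUE),
    class = "gaitnet_config"
  )
}

gaitnet_variants <- function() c("fmsnet", "no_skip", "lstm_cnn", "lstm")

variant_flags <- function(variant) {
  switch(variant,
    fmsnet = list(use_skip = TRUE, use_bn = TRUE),
    no_skip = list(use_skip = FALSE, use_bn = TRUE),
    lstm_cnn = list(use_skip = FALSE, use_bn = FALSE),
    lstm = list(use_skip = FALSE, use_bn = FALSE),
    stop("unknown variant '", variant, "'; options are: ",
         paste(gaitnet_variants(), collapse = ", "))
  )
}

# derived dimensions used in several places
config_dims <- function(config) {
  m1 <- config$map_rows - config$conv_kernels[1] + 1
  span <- config$map_rows * config$map_cols * config$n_sub
  list(
    L = config$map_rows * config$map_cols,
    span = span,
    m1 = m1,
    P1n = m1 * m1,
    K1 = config$channels * config$conv_kernels[1]^2,
    K2 = m1 * m1 * config$conv_filters[1],
    Dl = config$conv_filters[2] + config$conv_filters[3],
    D1 = if (isTRUE(config$use_skip)) {
      config$lstm_units + config$channels * span
    } else {
      config$lstm_units
    }
  )
}

runif_mat <- function(nr, nc, fan_in) {
  a <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

# Initialize all learnable parameters (small uniform scaled by fan-in).
# RNG state is the caller's responsibility.
init_params <- function(variant, config) {
  H <- config$lstm_units
  d <- config_dims(config)
  fc1 <- config$fc_units[1]; fc2 <- config$fc_units[2]
  ncls <- config$n_classes
  if (variant == "lstm") {
    return(list(
      Wx = runif_mat(config$channels, 4 * H, config$channels),
      Wh = runif_mat(H, 4 * H, H),
      bl = rep(0, 4 * H),
      Wf2 = runif_mat(H, fc2, H), bf2 = rep(0, fc2),
      Wf3 = runif_mat(fc2, ncls, fc2), bf3 = rep(0, ncls)
    ))
  }
  F1 <- config$conv_filters[1]; F2 <- config$conv_filters[2]
  F3 <- config$conv_filters[3]
  p <- list(
    W1 = runif_mat(d$K1, F1, d$K1), b1 = rep(0, F1),
    W2 = runif_mat(d$K2, F2, d$K2), b2 = rep(0, F2),
    W3 = runif_mat(F2, F3, F2), b3 = rep(0, F3),
    Wx = runif_mat(d$Dl, 4 * H, d$Dl),
    Wh = runif_mat(H, 4 * H, H),
    bl = rep(0, 4 * H),
    Wf1 = runif_mat(d$D1, fc1, d$D1), bf1 = rep(0, fc1),
    Wf2 = runif_mat(fc1, fc2, fc1), bf2 = rep(0, fc2),
    Wf3 = runif_mat(fc2, ncls, fc2), bf3 = rep(0, ncls)
  )
  if (isTRUE(config$use_bn)) {
    p <- c(p, list(
      g1 = rep(1, F1), be1 = rep(0, F1),
      g2 = rep(1, F2), be2 = rep(0, F2),
      g3 = rep(1, F3), be3 = rep(0, F3),
      gf1 = rep(1, fc1), bef1 = rep(0, fc1),
      gf2 = rep(1, fc2), bef2 = rep(0, fc2)
    ))
  }
  p
}

init_running_stats <- function(config) {
  F1 <- config$conv_filters[1]; F2 <- config$conv_filters[2]
  F3 <- config$conv_filters[3]
  fc1 <- config$fc_units[1]; fc2 <- config$fc_units[2]
  list(m1 = rep(0, F1), v1 = rep(1, F1),
       m2 = rep(0, F2), v2 = rep(1, F2),
       m3 = rep(0, F3), v3 = rep(1, F3),
       mf1 = rep(0, fc1), vf1 = rep(1, fc1),
       mf2 = rep(0, fc2), vf2 = rep(1, fc2))
}

#' Build an untrained gait-phase network
#'
#' Instantiates one of the four model variants with freshly initialized
#' parameters:
#' * `"fmsnet"` -- CNN per sub-window, LSTM over the sub-window codes,
#'   skip concatenation of the raw input into FC1, batch normalization
#'   after every convolution and hidden FC pre-activation;
#' * `"no_skip"` -- FMS-Net with the skip concatenation removed (FC1 sees
#'   only the LSTM output);
#' * `"lstm_cnn"` -- the serial CNN+LSTM combination without skip and
#'   without batch normalization;
#' * `"lstm"` -- the raw triaxial sequence fed directly to the LSTM, then
#'   FC(60) and the softmax layer.
#'
#' @param variant One of `"fmsnet"`, `"no_skip"`, `"lstm_cnn"`, `"lstm"`.
#' @param config A [model_config()].
#' @param seed Seed for the parameter initialization.
#' @return An object of class `"gaitnet"` (untrained).
#' @export
build_model <- function(variant = "fmsnet", config = model_config(),
                        seed = 1L) {
  variant <- as.character(variant)[1]
  flags <- variant_flags(variant)
  config$use_skip <- flags$use_skip
  config$use_bn <- flags$use_bn
  params <- with_seed(seed, init_params(variant, config))
  structure(
    list(variant = variant, config = config, params = params,
         running_stats = if (variant == "lstm") NULL
                         else init_running_stats(config),
         loss_history = numeric(0), log_every = NA_integer_,
         n_train = 0L, trained = FALSE, levels = phase_levels(),
         call = match.call()),
    class = "gaitnet"
  )
}

#' Fit a gait-phase network
#'
#' Trains one of the four model variants on windowed examples by
#' mini-batch gradient descent on the mean cross-entropy, at the
#' published learning rate 0.05 for 10,000 iterations by default. The
#' full run is deterministic for a fixed `seed` (initialization and
#' batch draws both descend from it). Gradients are clipped to a global
#' norm of `clip` per step, which keeps the ReLU LSTM recurrence stable
#' at this learning rate; training aborts with a diagnostic if the loss
#' still becomes non-finite.
#'
#' @param examples A `"gait_examples"` object (see [build_examples()]).
#' @param variant Model variant; see [build_model()].
#' @param iterations Number of gradient-descent iterations.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size (training-mode batch normalization
#'   needs at least 2).
#' @param seed Master seed for initialization and batch sampling.
#' @param clip Global gradient-norm clip; `0` disables clipping.
#' @param log_every Record the batch loss every this many iterations.
#' @param config A [model_config()]; geometry defaults are taken from
#'   the examples' windowing spec.
#' @return An object of class `"gaitnet"` with elements `params`,
#'   `running_stats`, `loss_history`, `variant` and `config`. Use
#'   [predict.gaitnet()] for inference and [evaluate_model()] for the
#'   full metrics report.
#' @examples
#' \donttest{
#' rec <- synthesize_recording(gait_profile(speed = 1.0), 30)
#' ex <- build_examples(rec)
#' sp <- split_train_test(ex, seed = 1)
#' fit <- gaitnet(sp$train, variant = "fmsnet", iterations = 300)
#' mean(predict(fit, sp$test) == sp$test$y)
#' }
#' @export
gaitnet <- function(examples, variant = "fmsnet", iterations = 10000,
                    lr = 0.05, batch_size = 64, seed = 1L, clip = 5,
                    log_every = 50, config = NULL) {
  stopifnot(inherits(examples, "gait_examples"))
  if (nrow(examples$x) < 1) stop("empty training set")
  if (batch_size < 2) stop("`batch_size` must be >= 2")
  if (is.null(config)) {
    sp <- examples$spec
    config <- model_config(map_rows = sp$map_rows, map_cols = sp$map_cols,
                           n_sub = sp$n_sub)
  }
  d <- config_dims(config)
  if (ncol(examples$x) != config$channels * d$span) {
    stop("examples have ", ncol(examples$x), " raw features but the ",
         "configuration expects ", config$channels * d$span)
  }
  model <- with_seed(seed, {
    m0 <- build_model(variant, config, seed = derive_seed(seed, 1L))
    X <- examples$x
    y <- as.integer(examples$y)
    if (variant == "lstm") {
      fit <- cpp_train_lstm(m0$params, X, y, m0$config,
                            as.integer(iterations), as.integer(batch_size),
                            lr, clip, as.integer(log_every))
      m0$params <- fit$params
    } else {
      fit <- cpp_train_fms(m0$params, m0$running_stats, X, y, m0$config,
                           as.integer(iterations), as.integer(batch_size),
                           lr, clip, as.integer(log_every))
      m0$params <- fit$params
      m0$running_stats <- fit$running_stats
    }
    m0$loss_history <- as.numeric(fit$loss_history)
    m0
  })
  model$log_every <- as.integer(log_every)
  model$n_train <- nrow(examples$x)
  model$trained <- TRUE
  model$hyper <- list(iterations = iterations, lr = lr,
                      batch_size = batch_size, seed = seed, clip = clip)
  model$call <- match.call()
  model
}

#' Predict gait phases
#'
#' @param object A fitted `"gaitnet"` model.
#' @param newdata A `"gait_examples"` object or a raw feature matrix with
#'   one example per row.
#' @param type `"class"` for integer phase codes (0 = HS ... 3 = SW) or
#'   `"prob"` for the 4-column softmax probability matrix.
#' @param ... Unused.
#' @return Integer vector of phase codes, or a probability matrix with
#'   one row per example and the phase names as column names.
#' @export
predict.gaitnet <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "gait_examples")) newdata$x else as.matrix(newdata)
  probs <- if (object$variant == "lstm") {
    cpp_lstm_prob(object$params, X, object$config)
  } else {
    cpp_fms_prob(object$params, object$running_stats, X, object$config)
  }
  colnames(probs) <- object$levels
  if (type == "prob") probs else predict_class(probs)
}

#' Number of learnable parameters
#' @param model A `"gaitnet"` object.
#' @return Integer count over all weight matrices, biases and BN
#'   parameters.
#' @export
param_count <- function(model) {
  stopifnot(inherits(model, "gaitnet"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
coef.gaitnet <- function(object, ...) object$params

#' @export
print.gaitnet <- function(x, ...) {
  cat("Gait-phase network (variant '", x$variant, "')",
      if (x$trained) " - trained" else " - untrained", "\n", sep = "")
  cat("  ", param_count(x), " parameters; skip connection: ",
      x$config$use_skip, "; batch norm: ", x$config$use_bn, "\n", sep = "")
  if (x$trained) {
    cat("  trained on ", x$n_train, " examples; final batch loss ",
        format(utils::tail(x$loss_history, 1), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Architecture summary with the layer-shape ledger
#'
#' @param object A `"gaitnet"` model.
#' @param ... Unused.
#' @return A `"summary.gaitnet"` object whose `shapes` element lists each
#'   stage's output shape; for the default configuration the
#'   convolutional chain reads 5x5x3 -> 2x2x20 -> 1x1x5 -> 1x1x1.
#' @export
summary.gaitnet <- function(object, ...) {
  cfg <- object$config
  d <- config_dims(cfg)
  shapes <- if (object$variant == "lstm") {
    list(
      input = c(d$span, cfg$channels),
      lstm = cfg$lstm_units,
      fc2 = cfg$fc_units[2],
      output = cfg$n_classes
    )
  } else {
    list(
      input_map = c(cfg$map_rows, cfg$map_cols, cfg$channels),
      conv1 = c(d$m1, d$m1, cfg$conv_filters[1]),
      conv2 = c(1L, 1L, cfg$conv_filters[2]),
      conv3 = c(1L, 1L, cfg$conv_filters[3]),
      lstm = cfg$lstm_units,
      fc1_input = d$D1,
      fc1 = cfg$fc_units[1],
      fc2 = cfg$fc_units[2],
      output = cfg$n_classes
    )
  }
  structure(
    list(variant = object$variant, shapes = shapes,
         n_params = param_count(object), trained = object$trained,
         loss_history = object$loss_history, hyper = object$hyper),
    class = "summary.gaitnet"
  )
}

#' @export
print.summary.gaitnet <- function(x, ...) {
  cat("Variant:", x$variant, "-", x$n_params, "parameters\n")
  cat("Layer output shapes:\n")
  for (nm in names(x$shapes)) {
    cat(sprintf("  %-10s %s\n", nm, paste(x$shapes[[nm]], collapse = " x ")))
  }
  if (x$trained && length(x$loss_history) > 0) {
    cat("Final logged batch loss:",
        format(utils::tail(x$loss_history, 1), digits = 4), "\n")
  }
  invisible(x)
}

#' @export
plot.gaitnet <- function(x, ...) {
  if (length(x$loss_history) == 0) {
    stop("model has no recorded loss history")
  }
  iters <- (seq_along(x$loss_history) - 1L) * x$log_every
  graphics::plot(iters, x$loss_history, type = "l",
                 xlab = "iteration", ylab = "batch cross-entropy",
                 main = paste("Training loss -", x$variant), ...)
  invisible(x)
}

# ----------------------------------------------------------------------
# Reference forward pass in plain R, composed from the exported layer
# primitives. Used for layer-shape inspection and to cross-check the
# compiled path; inference-mode batch normalization throughout.

w_to_kernel1 <- function(W1, k, channels, filters) {
  kern <- array(0, dim = c(k, k, channels, filters))
  for (f in seq_len(filters)) {
    for (ch in seq_len(channels)) {
      for (kr in seq_len(k)) {
        for (kc in seq_len(k)) {
          kern[kr, kc, ch, f] <-
            W1[(ch - 1) * k * k + (kr - 1) * k + kc, f]
        }
      }
    }
  }
  kern
}

bn_infer_vec <- function(z, g, be, rm, rv, eps) {
  g * (z - rm) / sqrt(rv + eps) + be
}

#' Trace one example through the network
#'
#' Runs a single example through the reference R implementation of the
#' forward pass (composed from [conv_forward()], [batchnorm_forward()],
#' [lstm_forward()], [skip_concat()] and [softmax()]) and returns every
#' intermediate quantity. Intended for inspection and testing; batch
#' prediction goes through [predict.gaitnet()].
#'
#' @param model A `"gaitnet"` model of the convolutional family (not
#'   `"lstm"`).
#' @param x Raw flattened input vector of one example.
#' @return List with the sub-window `maps`, per-sub-window feature maps
#'   `conv1`, `conv2`, `conv3`, the LSTM inputs and output `olstm`, the
#'   concatenated `xFC1`, the `logits`, the softmax `probs` and the
#'   predicted `class`.
#' @export
forward_trace <- function(model, x) {
  stopifnot(inherits(model, "gaitnet"))
  if (model$variant == "lstm") {
    stop("forward_trace applies to the convolutional variants")
  }
  cfg <- model$config
  p <- model$params
  rs <- model$running_stats
  d <- config_dims(cfg)
  S <- cfg$n_sub; L <- d$L
  k1 <- cfg$conv_kernels[1]; m1 <- d$m1
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  F3 <- cfg$conv_filters[3]
  kern1 <- w_to_kernel1(p$W1, k1, cfg$channels, F1)
  kern2 <- array(0, dim = c(m1, m1, F1, F2))
  for (f2 in seq_len(F2)) {
    for (f1 in seq_len(F1)) {
      for (kr in seq_len(m1)) {
        for (kc in seq_len(m1)) {
          kern2[kr, kc, f1, f2] <-
            p$W2[(f1 - 1) * m1 * m1 + (kr - 1) * m1 + kc, f2]
        }
      }
    }
  }
  kern3 <- array(p$W3, dim = c(1, 1, F2, F3))
  maps <- vector("list", S)
  conv1 <- vector("list", S)
  conv2 <- vector("list", S)
  conv3 <- vector("list", S)
  lstm_in <- matrix(0, S, F2 + F3)
  for (s in seq_len(S)) {
    map <- array(0, dim = c(cfg$map_rows, cfg$map_cols, cfg$channels))
    for (a in seq_len(cfg$channels)) {
      block <- x[(a - 1) * L * S + (s - 1) * L + seq_len(L)]
      map[, , a] <- t(matrix(block, cfg$map_cols, cfg$map_rows))
    }
    maps[[s]] <- map
    z1 <- conv_forward(map, kern1, p$b1, activation = "linear",
                       layer = "conv1")
    if (cfg$use_bn) {
      z1m <- matrix(z1, m1 * m1, F1)
      z1m <- batchnorm_forward(z1m, p$g1, p$be1, eps = cfg$bn_eps,
                               training = FALSE, running_mean = rs$m1,
                               running_var = rs$v1)$y
      z1 <- array(z1m, dim = dim(z1))
    }
    h1 <- relu(z1)
    conv1[[s]] <- h1
    z2 <- conv_forward(h1, kern2, p$b2, activation = "linear",
                       layer = "conv2")
    if (cfg$use_bn) {
      z2[1, 1, ] <- bn_infer_vec(z2[1, 1, ], p$g2, p$be2, rs$m2, rs$v2,
                                 cfg$bn_eps)
    }
    h2 <- relu(z2)
    conv2[[s]] <- h2
    z3 <- conv_forward(h2, kern3, p$b3, activation = "linear",
                       layer = "conv3")
    if (cfg$use_bn) {
      z3[1, 1, ] <- bn_infer_vec(z3[1, 1, ], p$g3, p$be3, rs$m3, rs$v3,
                                 cfg$bn_eps)
    }
    h3 <- relu(z3)
    conv3[[s]] <- h3
    lstm_in[s, ] <- c(h2[1, 1, ], h3[1, 1, ])
  }
  olstm <- lstm_forward(lstm_in, list(Wx = p$Wx, Wh = p$Wh, b = p$bl),
                        units = cfg$lstm_units,
                        forget_bias = cfg$forget_bias,
                        activation = cfg$lstm_activation)
  xfc1 <- if (cfg$use_skip) skip_concat(olstm, x) else olstm
  zf1 <- drop(xfc1 %*% p$Wf1) + p$bf1
  if (cfg$use_bn) {
    zf1 <- bn_infer_vec(zf1, p$gf1, p$bef1, rs$mf1, rs$vf1, cfg$bn_eps)
  }
  a1 <- leaky_relu(zf1, cfg$leaky_slope)
  zf2 <- drop(a1 %*% p$Wf2) + p$bf2
  if (cfg$use_bn) {
    zf2 <- bn_infer_vec(zf2, p$gf2, p$bef2, rs$mf2, rs$vf2, cfg$bn_eps)
  }
  a2 <- leaky_relu(zf2, cfg$leaky_slope)
  logits <- drop(a2 %*% p$Wf3) + p$bf3
  probs <- softmax(logits)
  list(maps = maps, conv1 = conv1, conv2 = conv2, conv3 = conv3,
       lstm_inputs = lstm_in, olstm = olstm, xFC1 = xfc1,
       logits = logits, probs = probs, class = predict_class(probs))
}
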