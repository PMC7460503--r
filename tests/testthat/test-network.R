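test_that("model variants wire the head as specified", {
  cfg <- model_config()
  m <- build_model("fmsnet", cfg, seed = 1)
  # skip connection: FC1 sees LSTM output plus the raw 600-vector
  expect_equal(nrow(m$params$Wf1), 36 + 3 * 25 * 8)
  expect_equal(ncol(m$params$Wf1), 160)
  expect_equal(ncol(m$params$Wf3), 4)

  m2 <- build_model("no_skip", cfg, seed = 1)
  expect_equal(nrow(m2$params$Wf1), 36)

  m3 <- build_model("lstm_cnn", cfg, seed = 1)
  expect_false(m3$config$use_bn)
  expect_null(m3$params$g1)

  m4 <- build_model("lstm", cfg, seed = 1)
  expect_equal(nrow(m4$params$Wx), 3)       # raw triaxial features
  expect_equal(nrow(m4$params$Wf2), 36)
  expect_equal(ncol(m4$params$Wf2), 60)

  expect_error(build_model("dnn"), "fmsnet, no_skip, lstm_cnn, lstm")

  # parameter count is a pure function of the configuration
  expect_equal(param_count(build_model("fmsnet", cfg, seed = 7)),
               param_count(build_model("fmsnet", cfg, seed = 8)))
})

test_that("layer shapes reproduce the published feature-map chain", {
  m <- build_model("fmsnet", model_config(), seed = 1)
  s <- summary(m)
  expect_equal(s$shapes$input_map, c(5L, 5L, 3L))
  expect_equal(s$shapes$conv1, c(2L, 2L, 20L))
  expect_equal(s$shapes$conv2, c(1L, 1L, 5L))
  expect_equal(s$shapes$conv3, c(1L, 1L, 1L))
  expect_equal(s$shapes$lstm, 36L)
  expect_equal(s$shapes$fc1, 160L)
  expect_equal(s$shapes$fc2, 60L)
  expect_equal(s$shapes$output, 4L)
  # and the realized trace agrees
  tr <- forward_trace(m, rnorm(600))
  expect_equal(dim(tr$conv1[[1]]), c(2, 2, 20))
  expect_equal(dim(tr$conv2[[1]]), c(1, 1, 5))
  expect_equal(dim(tr$conv3[[1]]), c(1, 1, 1))
  expect_length(tr$olstm, 36)
  expect_length(tr$xFC1, 636)
  expect_identical(tr$xFC1[1:36], tr$olstm)
  expect_lt(abs(sum(tr$probs) - 1), 1e-9)
  expect_equal(tr$class, which.max(tr$probs) - 1L)
})

test_that("reference R forward agrees with the compiled forward", {
  set.seed(12)
  X <- matrix(rnorm(3 * 600), 3)
  for (variant in c("fmsnet", "no_skip", "lstm_cnn")) {
    m <- build_model(variant, model_config(), seed = 5)
    probs <- predict(m, X, type = "prob")
    for (i in 1:3) {
      tr <- forward_trace(m, X[i, ])
      expect_equal(unname(tr$probs), unname(probs[i, ]), tolerance = 1e-9)
    }
  }
})

test_that("compiled gradients match central finite differences", {
  set.seed(42)
  for (variant in c("fmsnet", "lstm")) {
    cfg <- tiny_config(variant)
    p <- gaitphase:::with_seed(7, gaitphase:::init_params(variant, cfg))
    d <- gaitphase:::config_dims(cfg)
    X <- matrix(rnorm(5 * 3 * d$span), 5)
    y <- sample(0:3, 5, replace = TRUE)
    grad_fn <- if (variant == "lstm") gaitphase:::cpp_lstm_grad else
      gaitphase:::cpp_fms_grad
    g <- grad_fn(p, X, y, cfg)
    for (nm in names(p)) {
      for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
        eps <- 1e-6
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (grad_fn(pp, X, y, cfg)$loss -
                 grad_fn(pm, X, y, cfg)$loss) / (2 * eps)
        an <- g$grads[[nm]][i]
        expect_lt(abs(fd - an) / max(1e-4, abs(fd) + abs(an)), 1e-4)
      }
    }
  }
})

test_that("training starts at chance, learns, and is seed-deterministic", {
  # two well-separated classes in a 4-class problem
  set.seed(3)
  n <- 120
  X <- matrix(rnorm(n * 600, sd = 0.1), n)
  y <- rep(0:3, length.out = n)
  for (k in 0:3) X[y == k, k + 1] <- X[y == k, k + 1] + 3
  ex <- structure(list(x = X, y = y, subject = rep("S1", n), speed = 1,
                       spec = windowing_spec()), class = "gait_examples")
  fit <- gaitnet(ex, variant = "fmsnet", iterations = 150, batch_size = 32,
                 seed = 1, log_every = 10)
  # initial batch loss on 4 balanced classes sits near ln 4
  expect_lt(abs(fit$loss_history[1] - log(4)), 0.15)
  expect_lt(utils::tail(fit$loss_history, 1), fit$loss_history[1])
  expect_gt(mean(predict(fit, ex) == y), 0.9)

  fit2 <- gaitnet(ex, variant = "fmsnet", iterations = 150, batch_size = 32,
                  seed = 1, log_every = 10)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$params, fit2$params)

  fit3 <- gaitnet(ex, variant = "fmsnet", iterations = 150, batch_size = 32,
                  seed = 2, log_every = 10)
  expect_false(identical(fit$loss_history, fit3$loss_history))
})

test_that("probability rows are normalized for every variant", {
  ex <- quick_examples(duration_s = 5)
  X <- ex$x[1:8, ]
  for (variant in gaitphase:::gaitnet_variants()) {
    m <- build_model(variant, model_config(), seed = 2)
    p <- predict(m, X, type = "prob")
    expect_equal(dim(p), c(8, 4))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    expect_true(all(p >= 0))
    cls <- predict(m, X)
    expect_true(all(cls %in% 0:3))
  }
})
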