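test_that("valid convolution matches hand-computable cases", {
  # all-ones 5x5x1 input, all-ones 4x4 kernel, zero bias: each output is
  # the sum of 16 ones
  input <- array(1, dim = c(5, 5, 1))
  kernel <- array(1, dim = c(4, 4, 1, 1))
  out <- conv_forward(input, kernel, bias = 0)
  expect_equal(dim(out), c(2, 2, 1))
  expect_true(all(out == 16))

  # 1x1 kernel with weight 1, bias 0 is the identity
  x <- array(rnorm(12), dim = c(2, 2, 3))
  k1 <- array(0, dim = c(1, 1, 3, 3))
  for (ch in 1:3) k1[1, 1, ch, ch] <- 1
  expect_equal(conv_forward(x, k1, bias = rep(0, 3),
                            activation = "linear"), x)

  # default first-layer geometry: 5x5x3 -> 2x2x20
  input <- array(rnorm(75), dim = c(5, 5, 3))
  kernel <- array(rnorm(4 * 4 * 3 * 20), dim = c(4, 4, 3, 20))
  out <- conv_forward(input, kernel, bias = rnorm(20))
  expect_equal(dim(out), c(2, 2, 20))
  expect_true(all(out >= 0))  # relu

  # one output checked against explicit sum
  lin <- conv_forward(input, kernel, bias = rep(0, 20),
                      activation = "linear")
  expect_equal(lin[2, 1, 7],
               sum(input[2:5, 1:4, ] * kernel[, , , 7]))
})

test_that("convolution dimension errors name the layer", {
  input <- array(1, dim = c(3, 3, 1))
  kernel <- array(1, dim = c(4, 4, 1, 1))
  expect_error(conv_forward(input, kernel, 0, layer = "conv1"),
               "conv1.*smaller than kernel")
  kernel2 <- array(1, dim = c(2, 2, 5, 1))
  expect_error(conv_forward(input, kernel2, 0, layer = "conv2"),
               "conv2.*channels")
})

test_that("batch normalization reproduces hand-computed values", {
  # {-1, 1} is already zero-mean; unit gamma leaves it (up to eps)
  out <- batchnorm_forward(matrix(c(-1, 1), 2, 1), gamma = 1, beta = 0,
                           eps = 0)
  expect_equal(drop(out$y), c(-1, 1))

  # gamma = 0 collapses everything to beta
  out <- batchnorm_forward(matrix(rnorm(10), 5, 2), gamma = c(0, 0),
                           beta = c(3, -2))
  expect_true(all(abs(sweep(out$y, 2, c(3, -2))) < 1e-12))

  # batch {0, 2, 4}: mu = 2, population var = 8/3
  out <- batchnorm_forward(matrix(c(0, 2, 4), 3, 1), gamma = 1, beta = 0,
                           eps = 0)
  expect_equal(drop(out$y), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # training mode needs at least two rows
  expect_error(batchnorm_forward(matrix(1, 1, 1), 1, 0), "m >= 2")
})

test_that("batch normalization output statistics match gamma and beta", {
  set.seed(31)
  x <- matrix(rnorm(200 * 6, mean = 5, sd = 3), 200, 6)
  g <- runif(6, 0.5, 2); b <- rnorm(6)
  out <- batchnorm_forward(x, g, b, eps = 0)
  expect_equal(colMeans(out$y), b, tolerance = 1e-6,
               ignore_attr = TRUE)
  v <- colMeans(sweep(out$y, 2, colMeans(out$y))^2)
  expect_equal(v, g^2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("batch normalization inference uses running statistics", {
  x <- matrix(rnorm(40), 20, 2)
  tr <- batchnorm_forward(x, c(1, 1), c(0, 0), momentum = 0)
  inf <- batchnorm_forward(x[1:2, ], c(1, 1), c(0, 0), training = FALSE,
                           running_mean = tr$running_mean,
                           running_var = tr$running_var)
  manual <- sweep(sweep(x[1:2, ], 2, tr$running_mean), 2,
                  sqrt(tr$running_var + 1e-5), "/")
  expect_equal(inf$y, manual, tolerance = 1e-12)
})

test_that("LSTM output has the configured dimension for any length", {
  units <- 36; d <- 6
  set.seed(4)
  params <- list(Wx = matrix(rnorm(d * 4 * units, sd = 0.1), d),
                 Wh = matrix(rnorm(units * 4 * units, sd = 0.1), units),
                 b = rep(0, 4 * units))
  for (len in c(1, 8, 30)) {
    h <- lstm_forward(matrix(rnorm(len * d), len, d), params)
    expect_length(h, 36)
  }
  expect_error(lstm_forward(matrix(numeric(0), 0, d), params),
               "non-empty")
})

test_that("LSTM single step matches the closed-form gate arithmetic", {
  # 1 unit, 1 input feature, zero recurrent weights and bias:
  # pre-activations are just Wx * x; forget bias 0.7 enters f's argument
  sig <- function(z) 1 / (1 + exp(-z))
  params <- list(Wx = matrix(c(1, 2, 0.5, -1), 1),  # gates i, f, g, o
                 Wh = matrix(0, 1, 4), b = rep(0, 4))
  h <- lstm_forward(matrix(1, 1, 1), params, units = 1,
                    forget_bias = 0.7, activation = "relu")
  c1 <- sig(2 + 0.7) * 0 + sig(1) * max(0.5, 0)
  expect_equal(h, sig(-1) * max(c1, 0), tolerance = 1e-12)

  # all-zero weights and inputs: every gate sits at its constant and the
  # state stays exactly zero
  z <- list(Wx = matrix(0, 1, 4), Wh = matrix(0, 1, 4), b = rep(0, 4))
  expect_equal(lstm_forward(matrix(0, 5, 1), z, units = 1), 0)

  # tanh cell: same arithmetic with tanh in place of relu
  h <- lstm_forward(matrix(1, 1, 1), params, units = 1,
                    forget_bias = 0.7, activation = "tanh")
  c1 <- sig(1) * tanh(0.5)
  expect_equal(h, sig(-1) * tanh(c1), tolerance = 1e-12)
})

test_that("skip concatenation is ordered concatenation, not addition", {
  olstm <- rnorm(36)
  x <- rnorm(600)
  z <- skip_concat(olstm, x)
  expect_length(z, 636)
  expect_identical(z[1:36], olstm)
  expect_identical(z[37:636], x)
  # same-dimension inputs: concatenation, never elementwise addition
  a <- c(1, 2); b <- c(3, 4)
  expect_identical(skip_concat(a, b), c(1, 2, 3, 4))
  expect_false(identical(skip_concat(a, b), a + b))
  expect_error(skip_concat(c(1, NA), b), "finite")
})

test_that("softmax normalizes, is shift-invariant and matches closed forms", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  # exponentials 1,2,3,4 normalized
  expect_equal(softmax(log(1:4)), c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:1000) {
    q <- rnorm(4, sd = 10)
    p <- softmax(q)
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_lt(max(abs(p - softmax(q + rnorm(1)))), 1e-9)
  }
  # extreme logits stay finite thanks to max subtraction
  expect_equal(sum(softmax(c(1000, 0, -1000, 500))), 1)
  # matrix form operates on rows
  m <- softmax(rbind(c(0, 0, 0, 0), log(1:4)))
  expect_equal(m[1, ], rep(0.25, 4))
  expect_equal(m[2, ], c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)
})

test_that("class decision takes the argmax with low-index ties", {
  expect_identical(predict_class(c(0.1, 0.2, 0.3, 0.4)), 3L)
  expect_identical(predict_class(rep(0.25, 4)), 0L)
  expect_identical(predict_class(c(0, 1, 0, 0)), 1L)
  expect_identical(predict_class(rbind(c(0.7, 0.1, 0.1, 0.1),
                                       c(0.1, 0.1, 0.4, 0.4))),
                   c(0L, 2L))
})

test_that("cross entropy matches its closed forms", {
  expect_equal(cross_entropy(2L, c(0, 0, 1, 0)), 0)
  expect_equal(cross_entropy(0L, rep(0.25, 4)), log(4))
  expect_equal(cross_entropy(1L, c(0.6, 0.1, 0.2, 0.1)), -log(0.1))
  # one-hot target form agrees
  expect_equal(cross_entropy(c(0, 1, 0, 0), c(0.6, 0.1, 0.2, 0.1)),
               -log(0.1))
  # clamped at 1e-12: finite even for a zero probability
  expect_equal(cross_entropy(0L, c(0, 0.5, 0.5, 0)), -log(1e-12))
})
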