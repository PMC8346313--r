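test_that("conv2d matches simple closed forms", {
  x <- matrix(runif(64, 0.1, 0.9), 8, 8)
  # 1x1 identity kernel, zero bias: output equals input
  id <- conv_layer(1, 1, 1, activation = "none",
                   weights = array(1, dim = c(1, 1, 1, 1)))
  expect_equal(conv2d(x, id), x)

  # 3x3 all-ones kernel on a constant image: every pixel 9c + b
  # (reflect padding makes the border behave like the interior)
  cst <- matrix(0.3, 6, 6)
  ones <- conv_layer(1, 1, 3, activation = "none",
                     weights = array(1, dim = c(3, 3, 1, 1)), bias = 0.5)
  expect_equal(conv2d(cst, ones), matrix(9 * 0.3 + 0.5, 6, 6))

  # channel mismatch is rejected
  expect_error(conv2d(x, conv_layer(2, 1, 3)), "channel")
  expect_error(conv_layer(1, 1, 4), "odd")
})

test_that("conv2d agrees with the direct-summation oracle", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      x <- matrix(rnorm(25), 5, 5)
      w <- array(rnorm(9), dim = c(3, 3, 1, 1))
      b <- rnorm(1)
      ly <- conv_layer(1, 1, 3, activation = "none", weights = w, bias = b)
      expect_lt(max(abs(conv2d(x, ly) - oracle_conv2d(x, w[, , 1, 1], b))),
                1e-10)
    }
    # multi-channel: sum of per-channel oracle correlations
    x2 <- array(rnorm(72), dim = c(6, 6, 2))
    ly2 <- conv_layer(2, 3, 3, activation = "none",
                      weights = array(rnorm(54), dim = c(3, 3, 2, 3)),
                      bias = rnorm(3))
    got <- conv2d(x2, ly2)
    for (co in 1:3) {
      want <- oracle_conv2d(x2[, , 1], ly2$weights[, , 1, co]) +
        oracle_conv2d(x2[, , 2], ly2$weights[, , 2, co], ly2$bias[co])
      expect_lt(max(abs(got[, , co] - want)), 1e-10)
    }
  })
})

test_that("activations match their definitions", {
  expect_identical(relu(-3), 0)
  expect_identical(relu(2), 2)
  expect_identical(relu_grad(0), 0)
  expect_identical(relu_grad(c(-1, 2)), c(0, 1))
  expect_identical(swish(0, 5), 0)
  # saturating gate: swish(x, 1) -> x; the gap at x = 20 is exactly
  # 20 * (1 - sigmoid(20)) ~ 4.1e-8
  expect_lt(abs(swish(20, 1) - 20), 1e-7)
  expect_equal(swish(20, 1), 20 / (1 + exp(-20)), tolerance = 1e-15)
  expect_equal(swish(1, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("forward preserves shape and composes the layer stages", {
  img <- generate_phantom(tiny_spec())
  # identity-initialised network is the identity on [0, 1] images
  netI <- enhancer_net(init = "identity")
  expect_equal(as.matrix(forward(netI, img)), as.matrix(img))

  net <- enhancer_net(kernel_sizes = c(3, 3, 3), channels = c(4, 3),
                      seed = 2)
  out <- forward(net, img)
  expect_identical(dim(as.matrix(out)), dim(as.matrix(img)))
  expect_true(min(out) >= 0 && max(out) <= 1)

  # stage-by-stage composition with the oracle: F3(F2(F1(x)))
  x <- matrix(runif(64, 0.2, 0.8), 8, 8)
  small <- enhancer_net(kernel_sizes = c(3, 3, 3), channels = c(2, 2),
                        seed = 5)
  stage <- function(x_stack, ly, act) {
    co <- ly$out_channels
    out <- array(0, dim = c(nrow(x), ncol(x), co))
    for (o in seq_len(co)) {
      acc <- matrix(0, nrow(x), ncol(x))
      for (ci in seq_len(ly$in_channels)) {
        acc <- acc + oracle_conv2d(x_stack[, , ci], ly$weights[, , ci, o])
      }
      acc <- acc + ly$bias[o]
      out[, , o] <- if (act) swish(acc, ly$alpha) else acc
    }
    out
  }
  s1 <- stage(array(x, dim = c(8, 8, 1)), small$layers[[1]], TRUE)
  s2 <- stage(s1, small$layers[[2]], TRUE)
  s3 <- stage(s2, small$layers[[3]], FALSE)
  expect_lt(max(abs(as.matrix(forward(small, x)) -
                      pmin(pmax(s3[, , 1], 0), 1))), 1e-10)
})
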