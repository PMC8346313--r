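test_that("lse is exact and shift-equivariant", {
  expect_identical(lse(3.7), 3.7)
  expect_equal(lse(rep(0, 4)), log(4), tolerance = 1e-12)
  expect_error(lse(numeric(0)), "non-empty")
  withr::with_seed(2, {
    for (rep in 1:20) {
      l <- rnorm(5, sd = 3)
      c <- rnorm(1, sd = 10)
      expect_equal(lse(l + c), lse(l) + c, tolerance = 1e-10)
      # direct summation agrees where it does not overflow
      expect_equal(lse(l), log(sum(exp(l))), tolerance = 1e-10)
    }
  })
  # stability where naive summation overflows
  expect_equal(lse(c(1000, 1000)), 1000 + log(2), tolerance = 1e-9)
})

test_that("loss_label is the real-class cross-entropy", {
  expect_equal(loss_label(c(0, 0), 1), log(2), tolerance = 1e-12)
  expect_lt(loss_label(c(50, 0), 1), 1e-8)
  expect_error(loss_label(c(0, 0), 3), "index")
  withr::with_seed(5, {
    for (rep in 1:100) {
      l <- rnorm(4, sd = 2)
      y <- sample(4, 1)
      expect_lt(abs(loss_label(l, y) - oracle_softmax_ce(l, y)), 1e-10)
    }
  })
  # invariant to a common shift of the real-class scores
  l <- c(0.3, -1.2, 2.0)
  expect_equal(loss_label(l + 7, 2), loss_label(l, 2), tolerance = 1e-10)
})

test_that("unlabelled and fake losses follow the pinned-logit forms", {
  # t = 0: both equal log 2 (softplus(0))
  expect_equal(loss_unlabel(0), log(2), tolerance = 1e-12)
  expect_equal(loss_fake(0), log(2), tolerance = 1e-12)
  expect_lt(loss_unlabel(50), 1e-8)     # confidently real
  expect_lt(loss_fake(-50), 1e-8)       # confidently fake
  # algebraic identity: -log(e^t / (1 + e^t)) for t in -5..5
  for (t in -5:5) {
    expect_equal(loss_unlabel(t), -log(exp(t) / (1 + exp(t))),
                 tolerance = 1e-10)
  }
  # softplus identity: loss_unlabel(l) + lse(l) = loss_fake(l)
  withr::with_seed(8, {
    for (rep in 1:50) {
      l <- rnorm(3, sd = 4)
      expect_equal(loss_unlabel(l) + lse(l), loss_fake(l),
                   tolerance = 1e-10)
    }
  })
})

test_that("the total discriminator loss weighs its terms correctly", {
  expect_identical(total_discriminator_loss(1.0, 0.6, 0.8, v = 0),
                   1.0)
  expect_equal(total_discriminator_loss(1.0, 0.6, 0.8, v = 1), 1.7,
               tolerance = 1e-12)
  expect_equal(total_discriminator_loss(log(2), log(2), log(2), v = 2),
               3 * log(2), tolerance = 1e-12)
  expect_error(total_discriminator_loss(1, 1, 1, v = -0.5), ">= 0")
})

test_that("losses are finite, non-negative where required, and stable", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      l <- discriminator_logits(rnorm(4, sd = 8))
      vals <- c(loss_label(l, 1), loss_unlabel(l), loss_fake(l))
      expect_true(all(is.finite(vals)))
      expect_gte(loss_label(l, 1), 0)
      expect_gte(loss_fake(l), 0)
    }
  })
  # softplus(t) = t + softplus(-t) across a wide range
  sp <- echoenhance:::softplus
  t <- seq(-30, 30, by = 0.5)
  expect_lt(max(abs(sp(t) - (t + sp(-t)))), 1e-10)
  expect_error(discriminator_logits(c(1, Inf)), "finite")
})

test_that("semisup_report and the training side-channel log all terms", {
  rep0 <- semisup_report(discriminator_logits(c(1, 2)), 2,
                         discriminator_logits(c(0.5, 0)),
                         discriminator_logits(c(-1, 1)), v = 0.5)
  expect_equal(rep0$L_D,
               rep0$L_label + 0.5 * (rep0$L_unlabel + rep0$L_fake) / 2,
               tolerance = 1e-12)

  pairs <- tiny_pairs(3, size = 24)
  net <- enhancer_net(kernel_sizes = c(3, 3, 3), channels = c(2, 2),
                      seed = 2)
  fit <- train_enhancer(net, pairs,
                        train_config(learning_rate = 0.05, batch_size = 3,
                                     epochs = 3, seed = 1,
                                     semisup = TRUE, semisup_weight = 0.5))
  expect_true(all(c("L_label", "L_unlabel", "L_fake", "L_D") %in%
                    names(fit$trace)))
  expect_equal(fit$trace$L_D,
               fit$trace$L_label +
                 0.5 * (fit$trace$L_unlabel + fit$trace$L_fake) / 2,
               tolerance = 1e-12)
})
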