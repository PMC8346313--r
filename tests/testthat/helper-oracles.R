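# Independent brute-force oracles used by the unit and acceptance
# tests. These deliberately share no code with the package internals:
# nested loops and direct arithmetic only.

# Direct-summation single-channel correlation with reflect padding.
oracle_conv2d <- function(x, w, bias = 0) {
  w <- as.matrix(w)   # a 1 x 1 kernel arrives as a bare scalar
  f <- nrow(w)
  p <- (f - 1L) %/% 2L
  h <- nrow(x); wd <- ncol(x)
  ri <- c(rev(seq_len(p) + 1L), seq_len(h), h - seq_len(p))
  cj <- c(rev(seq_len(p) + 1L), seq_len(wd), wd - seq_len(p))
  xp <- x[ri, cj, drop = FALSE]
  out <- matrix(0, h, wd)
  for (i in seq_len(h)) {
    for (j in seq_len(wd)) {
      s <- 0
      for (di in seq_len(f)) {
        for (dj in seq_len(f)) {
          s <- s + w[di, dj] * xp[i + di - 1L, j + dj - 1L]
        }
      }
      out[i, j] <- s + bias
    }
  }
  out
}

# Explicit double-loop mean squared difference.
oracle_mse <- function(x, y) {
  s <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      s <- s + (x[i, j] - y[i, j])^2
    }
  }
  s / (nrow(x) * ncol(x))
}

# Cross-entropy by direct exponentiation (safe for moderate logits).
oracle_softmax_ce <- function(l, y) {
  -log(exp(l[y]) / sum(exp(l)))
}

# Count of pixels inside an ellipse by testing the inequality at every
# grid point.
oracle_ellipse_count <- function(h, w, r0, c0, a, b) {
  n <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (((i - r0) / a)^2 + ((j - c0) / b)^2 <= 1) n <- n + 1L
    }
  }
  n
}

# Small degradation-free fixtures shared across files.
tiny_spec <- function(size = 32L) phantom_spec(size, size)

tiny_pairs <- function(n, size = 32L, speckle = 0.2, blur = 1.0,
                       seed = 100L, jitter_seed = 7L) {
  make_paired_dataset(n, tiny_spec(size),
                      degradation_spec(speckle, blur, 0.01, seed = seed),
                      jitter_seed = jitter_seed)
}

# Tiny two-layer network for gradient checks.
toy_net <- function(seed = 1L) {
  withr::with_seed(seed, {
    structure(list(layers = list(
      conv_layer(1L, 3L, 3L, activation = "swish"),
      conv_layer(3L, 1L, 3L, activation = "none", init = "mean")
    )), class = "enhancer_net")
  })
}

# Finite-difference gradient of net_loss wrt every parameter (central
# differences), returned in the net_params structure.
fd_gradients <- function(net, x, y, eps = 1e-5) {
  params <- echoenhance:::net_params(net)
  g <- params
  for (q in seq_along(params)) {
    for (nm in names(params[[q]])) {
      p <- params[[q]][[nm]]
      gg <- p
      for (k in seq_along(p)) {
        p1 <- params; p1[[q]][[nm]][k] <- p1[[q]][[nm]][k] + eps
        p2 <- params; p2[[q]][[nm]][k] <- p2[[q]][[nm]][k] - eps
        f1 <- echoenhance:::net_loss(
          echoenhance:::set_net_params(net, p1), x, y)
        f2 <- echoenhance:::net_loss(
          echoenhance:::set_net_params(net, p2), x, y)
        gg[k] <- (f1 - f2) / (2 * eps)
      }
      g[[q]][[nm]] <- gg
    }
  }
  g
}
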