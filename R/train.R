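#' Pixel mean-squared-error loss
#'
#' Mean over all pixels of the squared difference between prediction
#' and target, computed on the `[0, 1]` intensity scale (the training
#' objective; the file-scale variant used for quality reporting is
#' [image_mse()]).
#'
#' @param pred,target same-shape [echo_image]s or matrices.
#' @return A scalar loss.
#' @export
mse_loss <- function(pred, target) {
  p <- as_pixel_matrix(pred, "pred")
  t <- as_pixel_matrix(target, "target")
  if (!identical(dim(p), dim(t))) {
    stop("`pred` and `target` must have the same shape", call. = FALSE)
  }
  mean((p - t)^2)
}

#' One gradient-descent step
#'
#' Updates every parameter `p` to `p - beta * g`. `params` and `grads`
#' are matching (possibly nested) lists of numeric arrays; mini-batch
#' training averages per-example gradients over the batch before
#' calling this.
#'
#' @param params list (or nested list) of numeric arrays.
#' @param grads matching structure of gradients.
#' @param beta step size (learning rate), `> 0`.
#' @return The updated parameter structure.
#' @export
sgd_step <- function(params, grads, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  step <- function(p, g) {
    if (is.list(p)) {
      if (!is.list(g) || length(g) != length(p)) {
        stop("`grads` does not match the structure of `params`",
             call. = FALSE)
      }
      return(mapply(step, p, g, SIMPLIFY = FALSE))
    }
    if (!identical(dim(p), dim(g)) || length(p) != length(g)) {
      stop("`grads` does not match the shape of `params`", call. = FALSE)
    }
    p - beta * g
  }
  step(params, grads)
}

#' Training configuration
#'
#' @param learning_rate step size `beta > 0`.
#' @param batch_size mini-batch size `z >= 1`.
#' @param epochs number of full passes over the training pairs.
#' @param seed seed controlling batch shuffling (training is
#'   deterministic given the seed).
#' @param semisup_weight weight `v >= 0` of the unsupervised terms in
#'   the discriminator objective when semi-supervised monitoring is
#'   enabled.
#' @param semisup enable the semi-supervised discriminator side-channel
#'   (see [semisup_epoch()]); the enhancer itself always trains on the
#'   pixel MSE.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.1, batch_size = 4L,
                         epochs = 50L, seed = 1L,
                         semisup_weight = 0.5, semisup = FALSE) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (semisup_weight < 0) stop("`semisup_weight` must be >= 0",
                               call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 semisup_weight = semisup_weight,
                 semisup = isTRUE(semisup)),
            class = "train_config")
}

# ---- parameter plumbing ---------------------------------------------------

# Trainable parameters of a network as a nested list (per layer:
# weights, bias, and alpha for swish layers).
net_params <- function(net) {
  lapply(net$layers, function(ly) {
    p <- list(weights = ly$weights, bias = ly$bias)
    if (ly$activation == "swish") p$alpha <- ly$alpha
    p
  })
}

set_net_params <- function(net, params) {
  for (q in seq_along(net$layers)) {
    net$layers[[q]]$weights <- params[[q]]$weights
    net$layers[[q]]$bias <- params[[q]]$bias
    if (!is.null(params[[q]]$alpha)) {
      net$layers[[q]]$alpha <- params[[q]]$alpha
    }
  }
  net
}

# Unclipped forward pass keeping the intermediates needed by backprop.
net_forward_cache <- function(net, x) {
  nl <- length(net$layers)
  caches <- vector("list", nl)
  h <- nrow(x); w <- ncol(x)
  cur <- array(x, dim = c(h, w, 1L))
  for (q in seq_len(nl)) {
    ly <- net$layers[[q]]
    f <- ly$kernel_size
    cols <- im2col(cur, f)
    wmat <- matrix(ly$weights, nrow = f * f * ly$in_channels)
    pre <- sweep(cols %*% wmat, 2L, ly$bias, "+")
    act <- if (q < nl) apply_activation(pre, ly) else pre
    caches[[q]] <- list(cols = cols, pre = pre)
    cur <- array(act, dim = c(h, w, ly$out_channels))
  }
  list(out = matrix(cur, h, w), caches = caches)
}

# Loss of the (unclipped) network output against a target image.
net_loss <- function(net, x, y) {
  mean((net_forward_cache(net, as_pixel_matrix(x))$out -
          as_pixel_matrix(y))^2)
}

# Backpropagation of the pixel-MSE loss through every layer.
# Returns list(loss =, grads =) with grads matching net_params(net).
net_gradients <- function(net, x, y) {
  x <- as_pixel_matrix(x); y <- as_pixel_matrix(y)
  h <- nrow(x); w <- ncol(x)
  fw <- net_forward_cache(net, x)
  nl <- length(net$layers)
  loss <- mean((fw$out - y)^2)
  grads <- vector("list", nl)
  # upstream gradient, as an [n_pix x C] matrix
  dact <- matrix(2 * (fw$out - y) / (h * w), ncol = 1L)
  for (q in rev(seq_len(nl))) {
    ly <- net$layers[[q]]
    f <- ly$kernel_size
    cache <- fw$caches[[q]]
    if (q < nl) {
      dpre <- switch(ly$activation,
                     relu = dact * relu_grad(cache$pre),
                     swish = dact * swish_grad(cache$pre, ly$alpha),
                     none = dact)
    } else {
      dpre <- dact  # reconstruction layer is linear
    }
    g <- list(
      weights = array(crossprod(cache$cols, dpre),
                      dim = dim(ly$weights)),
      bias = colSums(dpre)
    )
    if (ly$activation == "swish") {
      g$alpha <- sum(dact * swish_grad_alpha(cache$pre, ly$alpha))
    }
    grads[[q]] <- g
    if (q > 1L) {
      wmat <- matrix(ly$weights, nrow = f * f * ly$in_channels)
      dcols <- dpre %*% t(wmat)
      dx <- col2im(dcols, h, w, ly$in_channels, f)
      dact <- matrix(dx, h * w, ly$in_channels)
    }
  }
  list(loss = loss, grads = grads)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

add_grads <- function(a, b) {
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) return(lapply(a, scale_grads, s = s))
  a * s
}

#' Train the enhancement network
#'
#' Minimises the mean pixel MSE over clean/noisy pairs by mini-batch
#' stochastic gradient descent: per-example gradients are averaged
#' over each mini-batch of size `z = batch_size` before the descent
#' step `p <- p - beta * g`. Training is deterministic given
#' `config$seed` (which drives the epoch shuffles). The loss traced
#' per epoch is the mean training loss over that epoch's batches.
#'
#' When `config$semisup` is set, a small linear discriminator is
#' trained alongside on (clean = labelled real, noisy = unlabelled,
#' enhancer output = generated) and its four losses are appended to the
#' trace; see [semisup_epoch()] for the reading adopted.
#'
#' @param net an [enhancer_net].
#' @param pairs a non-empty list of `list(clean =, noisy =)` pairs as
#'   from [make_paired_dataset()].
#' @param config a [train_config].
#' @return A list with elements `net` (the trained network) and
#'   `trace` (a data frame with one row per epoch: `epoch`, `loss`,
#'   plus the discriminator losses when enabled).
#' @export
train_enhancer <- function(net, pairs, config = train_config()) {
  stopifnot(inherits(net, "enhancer_net"), inherits(config, "train_config"))
  n <- length(pairs)
  if (n < 1L) stop("`pairs` must contain at least one pair", call. = FALSE)
  xs <- lapply(pairs, function(p) as_pixel_matrix(p$noisy, "noisy"))
  ys <- lapply(pairs, function(p) as_pixel_matrix(p$clean, "clean"))
  beta <- config$learning_rate
  z <- min(config$batch_size, n)
  trace_loss <- numeric(config$epochs)
  semisup_rows <- if (config$semisup) vector("list", config$epochs)
  disc <- if (config$semisup) new_discriminator()
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = z)) {
        idx <- ord[start:min(start + z - 1L, n)]
        batch_grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          bg <- net_gradients(net, xs[[i]], ys[[i]])
          batch_loss <- batch_loss + bg$loss
          batch_grads <- if (is.null(batch_grads)) bg$grads else
            add_grads(batch_grads, bg$grads)
        }
        batch_grads <- scale_grads(batch_grads, 1 / length(idx))
        net <- set_net_params(net,
                              sgd_step(net_params(net), batch_grads, beta))
        ep_loss <- ep_loss + batch_loss / length(idx)
        nb <- nb + 1L
      }
      trace_loss[ep] <- ep_loss / nb
      if (config$semisup) {
        ss <- semisup_epoch(disc, net, xs, ys, config$semisup_weight)
        disc <- ss$disc
        semisup_rows[[ep]] <- ss$report
      }
    }
  })
  trace <- data.frame(epoch = seq_len(config$epochs), loss = trace_loss)
  if (config$semisup) {
    trace <- cbind(trace, do.call(rbind, lapply(semisup_rows, as.data.frame)))
  }
  list(net = net, trace = trace)
}
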