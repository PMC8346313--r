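#' Activation functions
#'
#' `relu(x)` is the rectifier `max(0, x)`; `relu_grad(x)` its
#' conventional derivative, 1 for `x > 0` and 0 otherwise (the value at
#' exactly 0 is taken as 0). `swish(x, alpha)` is the self-gated
#' activation `x * sigmoid(alpha * x)` with a trainable gate sharpness
#' `alpha`; it avoids the dead-neuron failure mode of the rectifier
#' because its gradient never vanishes identically on a half-line.
#'
#' @param x numeric vector.
#' @param alpha gate sharpness (scalar).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' relu(c(-3, 2))      # 0 2
#' swish(1, 1)         # 1 / (1 + exp(-1))
#' @export
relu <- function(x) pmax(0, x)

#' @rdname relu
#' @export
relu_grad <- function(x) as.numeric(x > 0)

#' @rdname relu
#' @export
swish <- function(x, alpha = 1) x * sigmoid(alpha * x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# d/dx [x * sigmoid(alpha x)] = s + alpha x s (1 - s), s = sigmoid(alpha x)
swish_grad <- function(x, alpha = 1) {
  s <- sigmoid(alpha * x)
  s + alpha * x * s * (1 - s)
}

# d/dalpha [x * sigmoid(alpha x)] = x^2 s (1 - s)
swish_grad_alpha <- function(x, alpha = 1) {
  s <- sigmoid(alpha * x)
  x^2 * s * (1 - s)
}

#' Convolutional layer
#'
#' One layer of the enhancement network: a stack of odd-sized square
#' kernels (one `f x f` grid per input-channel / output-channel pair),
#' one bias per output channel, and an activation setting. Weights are
#' stored as a 4-D array `[f, f, in_channels, out_channels]`.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size odd kernel side length `f`.
#' @param activation one of `"swish"`, `"relu"`, `"none"`.
#' @param alpha initial gate sharpness for the swish activation
#'   (trainable during [train_enhancer()]).
#' @param init weight initialisation: `"he"` (zero-mean Gaussian with
#'   variance `2 / (f^2 * in_channels)`), `"identity"` (centre-tap
#'   pass-through of channel 1), or `"mean"` (uniform averaging filter
#'   over all taps and input channels, the conventional start for a
#'   reconstruction layer).
#' @param weights,bias optional explicit parameters overriding `init`.
#' @return A `conv_layer` object.
#' @export
conv_layer <- function(in_channels, out_channels, kernel_size,
                       activation = c("swish", "relu", "none"),
                       alpha = 1.0,
                       init = c("he", "identity", "mean"),
                       weights = NULL, bias = NULL) {
  activation <- match.arg(activation)
  init <- match.arg(init)
  f <- as.integer(kernel_size)
  if (f %% 2L == 0L) stop("`kernel_size` must be odd", call. = FALSE)
  ci <- as.integer(in_channels); co <- as.integer(out_channels)
  if (is.null(weights)) {
    weights <- switch(init,
      he = array(stats::rnorm(f * f * ci * co,
                              sd = sqrt(2 / (f * f * ci))),
                 dim = c(f, f, ci, co)),
      identity = {
        w <- array(0, dim = c(f, f, ci, co))
        mid <- (f + 1L) %/% 2L
        for (o in seq_len(co)) w[mid, mid, 1L, o] <- 1
        w
      },
      mean = array(1 / (f * f * ci), dim = c(f, f, ci, co)))
  }
  if (!identical(dim(weights), c(f, f, ci, co))) {
    stop("`weights` must be an [f, f, in, out] array consistent with ",
         "the declared sizes", call. = FALSE)
  }
  if (is.null(bias)) bias <- rep(0, co)
  if (length(bias) != co) {
    stop("`bias` must have one entry per output channel", call. = FALSE)
  }
  structure(list(weights = weights, bias = as.numeric(bias),
                 in_channels = ci, out_channels = co, kernel_size = f,
                 activation = activation, alpha = alpha),
            class = "conv_layer")
}

#' Three-stage enhancement network
#'
#' An ordered stack of [conv_layer]s: the first layer extracts feature
#' maps from the input image, the middle layer(s) apply a nonlinear
#' mapping in feature space, and the final reconstruction layer
#' collapses the features back to a single intensity channel. The
#' reconstruction layer starts as a uniform averaging ("mean") filter
#' but all its weights remain trainable; the earlier layers use He
#' initialisation with one centre-tap pass-through channel in layer 1
#' so the untrained network already behaves like a gentle local
#' smoother of its input.
#'
#' @param kernel_sizes odd kernel side length per layer (default
#'   `c(9, 5, 5)`).
#' @param channels output channel count per hidden layer (default
#'   `c(16, 8)`); the reconstruction layer always outputs 1 channel.
#' @param activation activation for all layers but the last (`"swish"`
#'   or `"relu"`); the reconstruction layer is always linear.
#' @param alpha initial swish gate sharpness.
#' @param seed seed for the random weight initialisation.
#' @param init `"default"` for the trainable initialisation above, or
#'   `"identity"` for a network that is exactly the identity map on
#'   `[0, 1]` images (all layers linear centre-tap pass-throughs).
#' @return An `enhancer_net` object (list of layers).
#' @examples
#' net <- enhancer_net(seed = 1)
#' img <- generate_phantom(phantom_spec(32, 32))
#' out <- enhance(net, img)
#' @export
enhancer_net <- function(kernel_sizes = c(9L, 5L, 5L),
                         channels = c(16L, 8L),
                         activation = c("swish", "relu"),
                         alpha = 1.0, seed = 1L,
                         init = c("default", "identity")) {
  activation <- match.arg(activation)
  init <- match.arg(init)
  nl <- length(kernel_sizes)
  if (nl < 3L) stop("the network needs at least 3 layers", call. = FALSE)
  if (length(channels) != nl - 1L) {
    stop("`channels` must have one entry per hidden layer ",
         "(length(kernel_sizes) - 1)", call. = FALSE)
  }
  chain <- c(1L, as.integer(channels), 1L)
  layers <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nl), function(q) {
      last <- q == nl
      if (init == "identity") {
        conv_layer(chain[q], chain[q + 1L], kernel_sizes[q],
                   activation = "none", init = "identity")
      } else if (last) {
        conv_layer(chain[q], chain[q + 1L], kernel_sizes[q],
                   activation = "none", init = "mean")
      } else {
        ly <- conv_layer(chain[q], chain[q + 1L], kernel_sizes[q],
                         activation = activation, alpha = alpha,
                         init = "he")
        if (q == 1L) {  # centre-tap pass-through feature channel
          mid <- (ly$kernel_size + 1L) %/% 2L
          ly$weights[, , 1L, 1L] <- 0
          ly$weights[mid, mid, 1L, 1L] <- 1
        }
        ly
      }
    })
  })
  structure(list(layers = layers), class = "enhancer_net")
}

#' @export
print.enhancer_net <- function(x, ...) {
  cat(sprintf("<enhancer_net> %d layers\n", length(x$layers)))
  for (q in seq_along(x$layers)) {
    ly <- x$layers[[q]]
    cat(sprintf("  [%d] %dx%d conv, %d -> %d channels, activation %s\n",
                q, ly$kernel_size, ly$kernel_size, ly$in_channels,
                ly$out_channels, ly$activation))
  }
  invisible(x)
}

# ---- same-size convolution via reflect padding and im2col -----------------

pad_reflect_idx <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  if (n <= p) stop("image too small for this kernel size", call. = FALSE)
  c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
}

# Index bookkeeping for one (height, width, kernel) geometry, memoised:
# the same maps are reused for every image of a training set.
conv_geometry_cache <- new.env(parent = emptyenv())

conv_geometry <- function(h, w, f) {
  key <- paste(h, w, f, sep = "x")
  g <- conv_geometry_cache[[key]]
  if (!is.null(g)) return(g)
  p <- (f - 1L) %/% 2L
  hp <- h + 2L * p
  # linear index into the padded matrix for every (output pixel, tap)
  # pair, both in column-major order
  base <- as.vector(outer(seq_len(h), (seq_len(w) - 1L) * hp, "+"))
  offs <- as.vector(outer(seq_len(f) - 1L, (seq_len(f) - 1L) * hp, "+"))
  g <- list(p = p, hp = hp, wp = w + 2L * p,
            idx = outer(base, offs, "+"),
            ri = pad_reflect_idx(h, p), cj = pad_reflect_idx(w, p))
  conv_geometry_cache[[key]] <- g
  g
}

# Stack input [h, w, C] into the im2col matrix [h*w, f*f*C].
im2col <- function(x, f) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; ci <- if (length(d) == 3L) d[3] else 1L
  g <- conv_geometry(h, w, f)
  cols <- matrix(0, h * w, f * f * ci)
  x <- array(x, dim = c(h, w, ci))
  for (c in seq_len(ci)) {
    xp <- x[g$ri, g$cj, c]
    cols[, (c - 1L) * f * f + seq_len(f * f)] <- xp[g$idx]
  }
  cols
}

# Adjoint of im2col + reflect padding: scatter the column gradients
# back onto the unpadded input. Vectorised across channels; the border
# fold adds each reflected padded row/column back onto its source.
col2im <- function(dcols, h, w, ci, f) {
  g <- conv_geometry(h, w, f)
  f2 <- f * f
  dpad <- matrix(0, g$hp * g$wp, ci)
  chan_off <- (seq_len(ci) - 1L) * f2
  for (k in seq_len(f2)) {
    # for a fixed tap the target positions are distinct: plain add
    rows <- g$idx[, k]
    dpad[rows, ] <- dpad[rows, ] + dcols[, chan_off + k]
  }
  dm <- rowsum(matrix(dpad, g$hp), group = g$ri)        # fold rows
  dm <- array(dm, dim = c(h, g$wp, ci))
  dm <- aperm(dm, c(2L, 1L, 3L))
  dm <- rowsum(matrix(dm, g$wp), group = g$cj)          # fold columns
  aperm(array(dm, dim = c(w, h, ci)), c(2L, 1L, 3L))
}

#' 2-D convolution of a feature-map stack
#'
#' Computes, for every output channel, the sum over input channels of
#' the 2-D correlation of the input with that channel's kernel, plus
#' the channel bias. Output has the same spatial size as the input
#' (reflect padding). The layer's activation is *not* applied here;
#' [forward()] composes convolution and activation.
#'
#' @param input a matrix (single channel) or `[h, w, C]` array of
#'   feature maps.
#' @param layer a [conv_layer] with `in_channels == C`.
#' @return An `[h, w, out_channels]` array (dropped to a matrix when
#'   `out_channels == 1`).
#' @export
conv2d <- function(input, layer) {
  stopifnot(inherits(layer, "conv_layer"))
  if (inherits(input, "echo_image")) input <- as.matrix(input)
  if (is.matrix(input)) input <- array(input, dim = c(dim(input), 1L))
  d <- dim(input)
  if (length(d) != 3L || d[3] != layer$in_channels) {
    stop(sprintf("input has %d channel(s) but the layer expects %d",
                 if (length(d) == 3L) d[3] else 1L, layer$in_channels),
         call. = FALSE)
  }
  f <- layer$kernel_size
  cols <- im2col(input, f)
  wmat <- matrix(layer$weights, nrow = f * f * layer$in_channels)
  pre <- cols %*% wmat
  pre <- sweep(pre, 2L, layer$bias, "+")
  out <- array(pre, dim = c(d[1], d[2], layer$out_channels))
  if (layer$out_channels == 1L) out <- out[, , 1L] else out
}

apply_activation <- function(x, layer) {
  switch(layer$activation,
         relu = relu(x),
         swish = swish(x, layer$alpha),
         none = x)
}

#' Run the network on an image
#'
#' Applies convolution plus activation for every layer except the
#' last, then the linear reconstruction layer, and clips the result to
#' `[0, 1]`. Output has the same size as the input.
#'
#' `enhance()` is an alias for `forward()`.
#'
#' @param net an [enhancer_net].
#' @param image a single-channel [echo_image] or matrix.
#' @return An [echo_image] of the same size and bit depth.
#' @export
forward <- function(net, image) {
  stopifnot(inherits(net, "enhancer_net"))
  x <- as_pixel_matrix(image)
  nl <- length(net$layers)
  for (q in seq_len(nl)) {
    ly <- net$layers[[q]]
    x <- conv2d(x, ly)
    if (q < nl) x <- apply_activation(x, ly)
  }
  echo_image(clip01(x), bit_depth = bit_depth(image))
}

#' @rdname forward
#' @export
enhance <- forward
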