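#' Discriminator score vector
#'
#' Scores produced by a semi-supervised discriminator over `K` real
#' classes plus one generated ("fake") class. The fake-class score is
#' pinned to 0: a `(K+1)`-way softmax is invariant to a common shift of
#' all scores, so one score may be fixed without loss of generality,
#' and with that convention the fake-class probability is
#' `1 / (1 + exp(t))` where `t` is the log-sum-exp of the real-class
#' scores.
#'
#' @param real numeric vector of real-class scores (length `>= 1`, all
#'   finite).
#' @return A `discriminator_logits` object: `c(real, 0)`, the last
#'   entry being the pinned generated-class score.
#' @export
discriminator_logits <- function(real) {
  if (!is.numeric(real) || length(real) < 1L) {
    stop("`real` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(real))) {
    stop("all scores must be finite", call. = FALSE)
  }
  structure(c(as.numeric(real), 0), class = "discriminator_logits")
}

real_logits <- function(l) {
  if (inherits(l, "discriminator_logits")) {
    return(unclass(l)[-length(l)])
  }
  if (!is.numeric(l) || length(l) < 1L) {
    stop("logits must be a non-empty numeric vector or a ",
         "discriminator_logits object", call. = FALSE)
  }
  as.numeric(l)
}

#' Numerically stable log-sum-exp
#'
#' `lse(l) = max(l) + log(sum(exp(l - max(l))))`, the backbone of the
#' discriminator losses: naive `log(sum(exp(l)))` overflows for scores
#' beyond ~700.
#'
#' @param l non-empty numeric vector.
#' @return A scalar.
#' @examples
#' lse(c(0, 0, 0, 0))  # log(4)
#' @export
lse <- function(l) {
  if (length(l) < 1L) stop("`l` must be non-empty", call. = FALSE)
  m <- max(l)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(l - m)))
}

softplus <- function(t) {
  # log(1 + exp(t)), stable for large |t|
  ifelse(t > 0, t + log1p(exp(-t)), log1p(exp(t)))
}

#' Semi-supervised discriminator losses
#'
#' The three per-example losses of a `K+1`-class discriminator with
#' the fake-class score pinned to 0 (see [discriminator_logits]), and
#' their weighted total. Writing `t = lse(l)` for the log-sum-exp of
#' the real-class scores `l`:
#'
#' * `loss_label(l, y)`: cross-entropy of the real-class softmax for a
#'   labelled real example of class `y`, `-l[y] + lse(l)`.
#' * `loss_unlabel(l)`: negative log-probability that an unlabelled
#'   example is real, `-t + softplus(t)`.
#' * `loss_fake(l)`: negative log-probability that a generated example
#'   is assigned the fake class, `softplus(t)`.
#' * `total_discriminator_loss(L_label, L_unlabel, L_fake, v)`:
#'   `L_label + v * (L_unlabel + L_fake) / 2`, the supervised term plus
#'   a `v`-weighted symmetric average of the two unsupervised terms.
#'
#' @param l a [discriminator_logits] object, or a plain numeric vector
#'   of real-class scores.
#' @param y real-class index, `1 <= y <= K`.
#' @param L_label,L_unlabel,L_fake scalar loss values.
#' @param v unsupervised weight, `>= 0` (default 0.5).
#' @return A scalar loss.
#' @examples
#' loss_label(c(0, 0), 1)  # log(2): uniform two-class softmax
#' loss_fake(c(-50))       # ~0: confidently fake
#' @export
loss_label <- function(l, y) {
  l <- real_logits(l)
  y <- as.integer(y)
  if (length(y) != 1L || is.na(y) || y < 1L || y > length(l)) {
    stop(sprintf("`y` must be a real-class index in 1..%d", length(l)),
         call. = FALSE)
  }
  -l[y] + lse(l)
}

#' @rdname loss_label
#' @export
loss_unlabel <- function(l) {
  t <- lse(real_logits(l))
  -t + softplus(t)
}

#' @rdname loss_label
#' @export
loss_fake <- function(l) {
  softplus(lse(real_logits(l)))
}

#' @rdname loss_label
#' @export
total_discriminator_loss <- function(L_label, L_unlabel, L_fake, v = 0.5) {
  if (!is.numeric(v) || length(v) != 1L || v < 0) {
    stop("`v` must be a single number >= 0", call. = FALSE)
  }
  L_label + v * (L_unlabel + L_fake) / 2
}

#' Full discriminator loss report
#'
#' Evaluates all three losses and their weighted total for one
#' labelled example, one unlabelled example and one generated example.
#'
#' @param labelled a [discriminator_logits] for the labelled example.
#' @param y its real-class index.
#' @param unlabelled,generated [discriminator_logits] for the other two
#'   example kinds.
#' @param v unsupervised weight.
#' @return A list with `L_label`, `L_unlabel`, `L_fake`, `L_D`, `v`.
#' @export
semisup_report <- function(labelled, y, unlabelled, generated, v = 0.5) {
  Ll <- loss_label(labelled, y)
  Lu <- loss_unlabel(unlabelled)
  Lf <- loss_fake(generated)
  list(L_label = Ll, L_unlabel = Lu, L_fake = Lf,
       L_D = total_discriminator_loss(Ll, Lu, Lf, v), v = v)
}

# ---- optional training-side discriminator ---------------------------------

# A deliberately small discriminator: a linear map from three image
# summary statistics (mean, SD, mean absolute horizontal gradient) to
# a single real-class score, fake score pinned at 0. With one real
# class the labelled loss is identically 0 (softmax over one class),
# so the discriminator is driven by the real-vs-fake terms.
new_discriminator <- function() {
  list(w = c(0, 0, 0), b = 0, lr = 0.05)
}

disc_features <- function(x) {
  c(mean(x), stats::sd(x), mean(abs(diff(t(x)))))
}

disc_score <- function(disc, x) {
  sum(disc$w * disc_features(x)) + disc$b
}

# One epoch of discriminator updates plus the loss report logged into
# the training trace. Clean images act as labelled real data, noisy
# images as unlabelled data, and the enhancer outputs as generated
# data; the enhancer itself is *not* driven by this objective (the
# default pipeline trains on pixel MSE alone), the discriminator is a
# monitoring side-channel.
semisup_epoch <- function(disc, net, xs, ys, v) {
  n <- length(xs)
  Ll <- Lu <- Lf <- 0
  for (i in seq_len(n)) {
    gen <- net_forward_cache(net, xs[[i]])$out
    t_real <- disc_score(disc, ys[[i]])
    t_unl <- disc_score(disc, xs[[i]])
    t_gen <- disc_score(disc, gen)
    Ll <- Ll + loss_label(t_real, 1L)
    Lu <- Lu + loss_unlabel(t_unl)
    Lf <- Lf + loss_fake(t_gen)
    # gradient of -t + softplus(t) is sigmoid(t) - 1; of softplus(t),
    # sigmoid(t); scores are linear in (w, b)
    gu <- (sigmoid(t_unl) - 1)
    gf <- sigmoid(t_gen)
    gw <- v * (gu * disc_features(xs[[i]]) + gf * disc_features(gen)) / 2
    gb <- v * (gu + gf) / 2
    disc$w <- disc$w - disc$lr * gw
    disc$b <- disc$b - disc$lr * gb
  }
  report <- list(L_label = Ll / n, L_unlabel = Lu / n, L_fake = Lf / n)
  report$L_D <- total_discriminator_loss(report$L_label,
                                         report$L_unlabel,
                                         report$L_fake, v)
  list(disc = disc, report = report)
}
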