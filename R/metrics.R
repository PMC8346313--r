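check_same_shape <- function(x, y) {
  xm <- as_pixel_matrix(x, "x"); ym <- as_pixel_matrix(y, "y")
  if (!identical(dim(xm), dim(ym))) {
    stop("images must have the same shape", call. = FALSE)
  }
  if (bit_depth(x) != bit_depth(y)) {
    stop("images must have the same bit depth", call. = FALSE)
  }
  list(x = xm, y = ym, n = bit_depth(x))
}

#' Image quality metrics: MSE, PSNR, SSIM
#'
#' All three scores are computed on the integer file scale
#' `0 .. 2^n - 1` implied by the images' bit depth `n` (stored
#' intensities in `[0, 1]` are multiplied by `2^n - 1`; no
#' re-quantisation is applied).
#'
#' * `image_mse(x, y)`: mean over all `K x H` pixels of the squared
#'   difference.
#' * `psnr(x, y)`: `10 * log10((2^n - 1)^2 / MSE)` in dB; `Inf` when
#'   the images are identical. Higher PSNR means less distortion.
#' * `ssim(x, y)`: structural similarity from the global means
#'   `a_x, a_y`, variances `b_x^2, b_y^2` and covariance `b_xy`:
#'   \deqn{\frac{(2 a_x a_y + e_1)(2 b_{xy} + e_2)}
#'              {(a_x^2 + a_y^2 + e_1)(b_x^2 + b_y^2 + e_2)}}
#'   with stabilisers `e1 = (0.01 L)^2`, `e2 = (0.03 L)^2`,
#'   `L = 2^n - 1` by default. Variances are population moments
#'   (divide by the pixel count). `ssim(x, x)` is exactly 1; values
#'   near 1 mean the images are structurally similar. The default is
#'   the single global-moment score; `mode = "window"` averages the
#'   same formula over sliding 8 x 8 windows, the common practice in
#'   image-processing toolboxes.
#'
#' @param x,y same-shape, same-bit-depth [echo_image]s (or matrices,
#'   taken as 8-bit).
#' @param e1,e2 stabiliser constants on the squared integer scale.
#' @param mode `"global"` (single whole-image score) or `"window"`
#'   (mean over sliding 8 x 8 windows).
#' @param window_size window side for `mode = "window"`.
#' @return A scalar.
#' @examples
#' a <- echo_image(matrix(runif(256), 16, 16))
#' psnr(a, a)  # Inf
#' ssim(a, a)  # 1
#' @export
image_mse <- function(x, y) {
  s <- check_same_shape(x, y)
  L <- 2^s$n - 1
  mean((L * s$x - L * s$y)^2)
}

#' @rdname image_mse
#' @export
psnr <- function(x, y) {
  s <- check_same_shape(x, y)
  mse <- image_mse(x, y)
  L <- 2^s$n - 1
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

#' @rdname image_mse
#' @export
ssim <- function(x, y, e1 = NULL, e2 = NULL,
                 mode = c("global", "window"), window_size = 8L) {
  mode <- match.arg(mode)
  s <- check_same_shape(x, y)
  L <- 2^s$n - 1
  if (is.null(e1)) e1 <- (0.01 * L)^2
  if (is.null(e2)) e2 <- (0.03 * L)^2
  xm <- L * s$x; ym <- L * s$y
  if (mode == "global") {
    return(ssim_moments(xm, ym, e1, e2))
  }
  h <- nrow(xm); w <- ncol(xm); ws <- as.integer(window_size)
  if (h < ws || w < ws) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  vals <- numeric((h - ws + 1L) * (w - ws + 1L))
  k <- 0L
  for (j in seq_len(w - ws + 1L)) {
    for (i in seq_len(h - ws + 1L)) {
      k <- k + 1L
      ii <- i:(i + ws - 1L); jj <- j:(j + ws - 1L)
      vals[k] <- ssim_moments(xm[ii, jj], ym[ii, jj], e1, e2)
    }
  }
  mean(vals)
}

ssim_moments <- function(xm, ym, e1, e2) {
  n <- length(xm)
  ax <- mean(xm); ay <- mean(ym)
  bx2 <- mean((xm - ax)^2)           # population variance
  by2 <- mean((ym - ay)^2)
  bxy <- mean((xm - ax) * (ym - ay))
  ((2 * ax * ay + e1) * (2 * bxy + e2)) /
    ((ax^2 + ay^2 + e1) * (bx2 + by2 + e2))
}

#' One-shot quality report
#'
#' @param x reference image, `y` test image (same shape, bit depth).
#' @inheritParams image_mse
#' @param ssim_mode passed to [ssim()].
#' @return A one-row data frame with columns `mse`, `psnr_db`, `ssim`.
#' @export
quality_report <- function(x, y, ssim_mode = "global") {
  data.frame(mse = image_mse(x, y), psnr_db = psnr(x, y),
             ssim = ssim(x, y, mode = ssim_mode))
}
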