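#' Specification of a synthetic cardiac phantom
#'
#' Describes a clean, noise-free phantom image: a uniform background, an
#' echogenic myocardium ring around each chamber, and hypoechoic
#' (blood-pool) chamber interiors drawn as ellipses. The default
#' geometry is a stylised apical "four-chamber view": two larger
#' ventricular and two smaller atrial ellipses. This is a test fixture,
#' not a physical B-mode simulation (no beamforming, no scan
#' conversion).
#'
#' @param height,width image size in pixels (each at least 16).
#' @param background_level background intensity in `[0, 1]`.
#' @param chambers list of chamber descriptors; each a numeric vector
#'   `c(center_row, center_col, semi_axis_a, semi_axis_b, intensity)`
#'   with semi-axes in pixels (`a` vertical, `b` horizontal) and
#'   intensity in `[0, 1]`. `NULL` selects the default four-chamber
#'   layout for the given size.
#' @param myocardium_ring_width ring thickness in pixels around each
#'   chamber.
#' @param myocardium_intensity ring intensity in `[0, 1]`.
#' @return A `phantom_spec` object (a validated list).
#' @examples
#' spec <- phantom_spec(64, 64)
#' img <- generate_phantom(spec)
#' @export
phantom_spec <- function(height = 64L, width = 64L,
                         background_level = 0.15,
                         chambers = NULL,
                         myocardium_ring_width = 3L,
                         myocardium_intensity = 0.85) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 16L || width < 16L) {
    stop("phantom images must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (is.null(chambers)) {
    chambers <- default_four_chamber(height, width)
  }
  spec <- structure(
    list(height = height, width = width,
         background_level = background_level,
         chambers = chambers,
         myocardium_ring_width = as.integer(myocardium_ring_width),
         myocardium_intensity = myocardium_intensity),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# Stylised four-chamber layout scaled to the image size.
default_four_chamber <- function(height, width) {
  h <- height; w <- width
  list(
    c(0.38 * h, 0.32 * w, 0.20 * h, 0.14 * w, 0.05),  # left ventricle
    c(0.38 * h, 0.68 * w, 0.18 * h, 0.12 * w, 0.05),  # right ventricle
    c(0.74 * h, 0.34 * w, 0.10 * h, 0.10 * w, 0.08),  # left atrium
    c(0.74 * h, 0.66 * w, 0.09 * h, 0.09 * w, 0.08)   # right atrium
  )
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    ints <- c(background_level, myocardium_intensity,
              vapply(chambers, function(ch) ch[[5]], numeric(1)))
    if (length(ints) && (min(ints) < 0 || max(ints) > 1)) {
      stop("all phantom intensities must lie in [0, 1]", call. = FALSE)
    }
    if (myocardium_ring_width < 0L) {
      stop("`myocardium_ring_width` must be >= 0", call. = FALSE)
    }
    for (ch in chambers) {
      if (length(ch) != 5L) {
        stop("each chamber must be c(row, col, a, b, intensity)",
             call. = FALSE)
      }
      r <- ch[[1]]; c <- ch[[2]]; a <- ch[[3]]; b <- ch[[4]]
      rw <- myocardium_ring_width
      if (a <= 0 || b <= 0) stop("ellipse semi-axes must be > 0",
                                 call. = FALSE)
      if (r - a - rw < 1 || r + a + rw > height ||
          c - b - rw < 1 || c + b + rw > width) {
        stop("ellipse (including its myocardium ring) extends outside ",
             "the image bounds", call. = FALSE)
      }
    }
  })
  invisible(spec)
}

#' Render a clean phantom image
#'
#' Paints the background everywhere, then every myocardium ring
#' (chamber ellipse dilated by the ring width), then every chamber
#' interior, in that order. Purely deterministic.
#'
#' @param spec a [phantom_spec].
#' @return An [echo_image] of size `spec$height` x `spec$width`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background_level, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rw <- spec$myocardium_ring_width
  for (ch in spec$chambers) {  # rings first
    inside <- ellipse_mask(rows, cols, ch[[1]], ch[[2]],
                           ch[[3]] + rw, ch[[4]] + rw)
    img[inside] <- spec$myocardium_intensity
  }
  for (ch in spec$chambers) {  # then blood-pool interiors
    inside <- ellipse_mask(rows, cols, ch[[1]], ch[[2]], ch[[3]], ch[[4]])
    img[inside] <- ch[[5]]
  }
  echo_image(img)
}

ellipse_mask <- function(rows, cols, r0, c0, a, b) {
  ((rows - r0) / a)^2 + ((cols - c0) / b)^2 <= 1
}

#' Specification of image degradation
#'
#' The degradation chain applied to a clean phantom, in the order of
#' the physical imaging chain: Gaussian blur of the reflectivity (point
#' spread function), multiplicative unit-mean speckle, additive
#' zero-mean Gaussian electronic noise, then clipping to `[0, 1]`.
#'
#' The speckle factor is the squared-Gaussian idealisation
#' \eqn{S = G^2 + \epsilon} with \eqn{G \sim N(0, \sigma_g)} and
#' \eqn{\sigma_g^2, \epsilon} chosen so that \eqn{E[S] = 1} and
#' \eqn{sd(S) = } `speckle_sigma`; this keeps `S > 0` for any
#' `speckle_sigma` below `sqrt(2)`.
#'
#' @param speckle_sigma standard deviation of the multiplicative
#'   speckle factor (unitless, in `[0, sqrt(2))`).
#' @param blur_sigma Gaussian point-spread-function width in pixels
#'   (`>= 0`; 0 disables blur).
#' @param additive_sigma standard deviation of the additive Gaussian
#'   noise, in intensity units (`>= 0`).
#' @param seed integer seed; identical seed and spec give identical
#'   output.
#' @return A `degradation_spec` object.
#' @export
degradation_spec <- function(speckle_sigma = 0.2, blur_sigma = 1.0,
                             additive_sigma = 0.01, seed = 1L) {
  if (speckle_sigma < 0 || blur_sigma < 0 || additive_sigma < 0) {
    stop("all degradation sigmas must be >= 0", call. = FALSE)
  }
  if (speckle_sigma >= sqrt(2)) {
    stop("`speckle_sigma` must be < sqrt(2) for a positive ",
         "squared-Gaussian speckle factor", call. = FALSE)
  }
  structure(list(speckle_sigma = speckle_sigma, blur_sigma = blur_sigma,
                 additive_sigma = additive_sigma, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a clean image
#'
#' Applies the blur / speckle / additive-noise chain of a
#' [degradation_spec], seeded and reproducible. With all sigmas zero it
#' is the identity map.
#'
#' @param image an [echo_image] or matrix with intensities in `[0, 1]`.
#' @param deg a [degradation_spec].
#' @param seed optional seed overriding `deg$seed` (used to vary noise
#'   across the pairs of a dataset while keeping one spec object).
#' @return A degraded [echo_image] of the same size.
#' @export
degrade <- function(image, deg, seed = deg$seed) {
  stopifnot(inherits(deg, "degradation_spec"))
  x <- as_pixel_matrix(image)
  if (min(x) < 0 || max(x) > 1) {
    stop("input intensities must lie in [0, 1]", call. = FALSE)
  }
  x <- gaussian_blur(x, deg$blur_sigma)
  withr::with_seed(as.integer(seed), {
    if (deg$speckle_sigma > 0) {
      sg2 <- deg$speckle_sigma / sqrt(2)      # variance of G
      eps <- 1 - sg2                          # unit-mean offset
      g <- matrix(stats::rnorm(length(x), sd = sqrt(sg2)),
                  nrow(x), ncol(x))
      x <- x * (g^2 + eps)
    }
    if (deg$additive_sigma > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = deg$additive_sigma),
                      nrow(x), ncol(x))
    }
  })
  echo_image(clip01(x), bit_depth = bit_depth(image))
}

# Separable Gaussian blur with reflect borders; sigma = 0 is identity.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  idx_reflect <- function(n) {
    # reflect-without-edge-repeat index map for a pad of r on each side
    c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  }
  conv_rows <- function(m) {
    mp <- m[idx_reflect(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[seq_len(nrow(m)) + (i - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(x))))
}

#' Build a paired clean/noisy training set
#'
#' Draws `n` phantoms whose chamber geometry is randomly jittered
#' around `spec` (centres by up to 5% of the image size, semi-axes by
#' up to 10%, multiplicatively), then degrades each with an independent
#' noise realisation. Pair `i`'s noisy member is `degrade()` of its
#' clean member with seed `deg$seed + i - 1`.
#'
#' @param n number of pairs (`>= 0`).
#' @param spec a [phantom_spec] template.
#' @param deg a [degradation_spec].
#' @param jitter_seed seed for the geometry jitter.
#' @return A list of `n` elements, each `list(clean =, noisy =)`.
#' @export
make_paired_dataset <- function(n, spec, deg, jitter_seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(deg, "degradation_spec"))
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be >= 0", call. = FALSE)
  if (n == 0L) return(list())
  jittered <- withr::with_seed(as.integer(jitter_seed), {
    lapply(seq_len(n), function(i) jitter_spec(spec))
  })
  lapply(seq_len(n), function(i) {
    clean <- generate_phantom(jittered[[i]])
    list(clean = clean,
         noisy = degrade(clean, deg, seed = deg$seed + i - 1L))
  })
}

# Randomly perturb chamber geometry; retry until the jittered ellipses
# still fit inside the bounds (the default layout leaves ample margin).
jitter_spec <- function(spec, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    chambers <- lapply(spec$chambers, function(ch) {
      ch[1] <- ch[1] + stats::runif(1, -0.05, 0.05) * spec$height
      ch[2] <- ch[2] + stats::runif(1, -0.05, 0.05) * spec$width
      ch[3] <- ch[3] * stats::runif(1, 0.9, 1.1)
      ch[4] <- ch[4] * stats::runif(1, 0.9, 1.1)
      ch
    })
    cand <- spec
    cand$chambers <- chambers
    ok <- tryCatch({ validate_phantom_spec(cand); TRUE },
                   error = function(e) FALSE)
    if (ok) return(cand)
  }
  spec
}
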