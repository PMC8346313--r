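#' Read and write grayscale images
#'
#' Supported formats, chosen by file extension: PNG (8-bit grayscale,
#' via libpng) and portable graymap PGM (`.pgm`, both the ASCII `P2`
#' and binary `P5` encodings, 8- or 16-bit by `maxval`). On reading,
#' integer levels are mapped to `[0, 1]` by division by `2^n - 1`; on
#' writing, intensities are quantised back by the exact inverse
#' (`round(x * (2^n - 1))`), so a write/read round trip moves no pixel
#' by more than `1 / (2^n - 1)`. Colour (RGB) and palette inputs are
#' rejected with an error naming the offending mode.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @param image an [echo_image] or matrix in `[0, 1]`.
#' @param bit_depth bit depth to write (8 for PNG; 8 or 16 for PGM);
#'   defaults to the image's own depth.
#' @param ascii for PGM, write the plain-text `P2` encoding instead of
#'   binary `P5` (default `TRUE`: text files diff cleanly).
#' @return `read_image()` returns an [echo_image] with `bit_depth` set
#'   from the file; `write_image()` returns `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = read_png_gray(path),
         pgm = read_pgm(path),
         stop("unsupported image format '.", ext,
              "' (use .png or .pgm)", call. = FALSE))
}

#' @rdname read_image
#' @export
write_image <- function(image, path, bit_depth = NULL, ascii = TRUE) {
  x <- as_pixel_matrix(image)
  if (min(x) < 0 || max(x) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(bit_depth)) bit_depth <- bit_depth(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = {
           if (bit_depth != 8L) {
             stop("PNG output is 8-bit only; use .pgm for 16-bit",
                  call. = FALSE)
           }
           # quantise explicitly so the round trip is the exact inverse
           png::writePNG(round(x * 255) / 255, path)
         },
         pgm = write_pgm(x, path, bit_depth, ascii),
         stop("unsupported image format '.", ext,
              "' (use .png or .pgm)", call. = FALSE))
  invisible(path)
}

read_png_gray <- function(path) {
  # inspect the IHDR chunk for bit depth and colour type before decoding
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("truncated PNG: ", path, call. = FALSE)
  depth <- as.integer(hdr[25])
  color_type <- as.integer(hdr[26])
  mode <- switch(as.character(color_type),
                 "0" = "grayscale", "2" = "RGB", "3" = "palette",
                 "4" = "grayscale+alpha", "6" = "RGBA", "unknown")
  if (color_type != 0L) {
    stop(sprintf("unsupported PNG mode '%s' in %s: only plain grayscale ",
                 mode, path),
         "is supported; convert the image first", call. = FALSE)
  }
  px <- png::readPNG(path)
  if (length(dim(px)) != 2L) {
    stop("unsupported PNG layout (expected a single gray channel)",
         call. = FALSE)
  }
  echo_image(px, bit_depth = depth)
}

write_pgm <- function(x, path, bit_depth, ascii = TRUE) {
  if (!bit_depth %in% c(8L, 16L)) {
    stop("PGM bit depth must be 8 or 16", call. = FALSE)
  }
  maxval <- 2L^bit_depth - 1L
  lv <- round(x * maxval)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(x), nrow(x)),
                 sprintf("%d", maxval)), con)
    # raster order: one image row per line
    writeLines(apply(lv, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", sprintf("%d %d", ncol(x), nrow(x)),
                 sprintf("%d", maxval)), con)
    v <- as.integer(t(lv))  # row-major raster
    if (maxval > 255L) {
      writeBin(v, con, size = 2L, endian = "big")
    } else {
      writeBin(as.raw(v), con)
    }
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("unsupported PGM magic '", magic, "' in ", path,
         " (PPM colour images are not supported)", call. = FALSE)
  }
  # header tokens: width, height, maxval (comments allowed)
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (!length(ch) || !nzchar(ch)) stop("truncated PGM header",
                                         call. = FALSE)
    if (ch == "#") {  # comment to end of line
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1L))
        if (!nzchar(c2) || c2 == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  depth <- if (maxval > 255L) 16L else 8L
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (maxval > 255L) {
    vals <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
                    endian = "big")
  } else {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data",
                                  call. = FALSE)
  echo_image(matrix(vals, h, w, byrow = TRUE) / maxval,
             bit_depth = depth)
}

#' Save / load a model checkpoint
#'
#' Model checkpoints are a single human-readable JSON file holding the
#' layer shapes, all weights and biases, the swish gate parameters and
#' any training metadata, at full double precision.
#'
#' @param net an [enhancer_net].
#' @param path file path (`.json`).
#' @param meta optional named list of metadata (training config, seed,
#'   final loss) stored verbatim.
#' @return `load_model()` returns a list with `net` and `meta`;
#'   `save_model()` returns `path` invisibly.
#' @export
save_model <- function(net, path, meta = list()) {
  stopifnot(inherits(net, "enhancer_net"))
  payload <- list(
    format = "echoenhance-model-v1",
    layers = lapply(net$layers, function(ly) {
      list(kernel_size = ly$kernel_size,
           in_channels = ly$in_channels,
           out_channels = ly$out_channels,
           activation = ly$activation,
           alpha = ly$alpha,
           bias = ly$bias,
           weights = as.numeric(ly$weights))
    }),
    meta = meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "echoenhance-model-v1")) {
    stop("not an echoenhance model checkpoint: ", path, call. = FALSE)
  }
  ls <- payload$layers
  layers <- lapply(seq_len(nrow(ls)), function(i) {
    f <- ls$kernel_size[i]; ci <- ls$in_channels[i]; co <- ls$out_channels[i]
    conv_layer(ci, co, f, activation = ls$activation[i],
               alpha = ls$alpha[i],
               weights = array(ls$weights[[i]], dim = c(f, f, ci, co)),
               bias = ls$bias[[i]])
  })
  list(net = structure(list(layers = layers), class = "enhancer_net"),
       meta = payload$meta)
}
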