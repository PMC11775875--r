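#' Generate a synthetic neutral face and its expression morphs
#'
#' Stand-in for photographic morph stimuli: an 8-bit grayscale "face"
#' (smooth oval with schematic features on a uniform background) plus a
#' morph at each requested intensity level. Morphing is linear by
#' construction: the pixel-wise difference between the neutral image and
#' the level-L morph is `round(L / 100 * delta)` inside the face oval and
#' exactly zero outside it, where `delta` is a fixed expression-difference
#' field whose values are multiples of 5 (so 20% steps quantize exactly).
#'
#' @param size image side length in pixels (square images).
#' @param levels intensity levels in percent, each in (0, 100]; level 0
#'   returns a copy of the neutral image.
#' @param seed seed for the random texture of the synthetic face.
#' @param background background gray value (0-255).
#' @return list with `neutral` (integer matrix 0-255), `morphs` (named
#'   list of integer matrices, one per level), `mask` (logical matrix,
#'   TRUE inside the face oval), `delta` (the difference field).
#' @export
generate_morph_images <- function(size = 128,
                                  levels = c(20, 40, 60, 80, 100),
                                  seed = 1L, background = 100L) {
  stopifnot(all(levels >= 0), all(levels <= 100), size >= 16)
  set.seed(seed)
  xs <- seq(-1, 1, length.out = size)
  gx <- matrix(xs, size, size, byrow = TRUE)
  gy <- matrix(xs, size, size)
  # face oval: height 1.5 x width (portrait aspect, like trimmed stimuli)
  mask <- (gx / 0.55)^2 + (gy / 0.8)^2 <= 1
  face <- 160 - 50 * (gx^2 + gy^2)                      # smooth shading
  eyes <- 60 * (exp(-((gx + 0.22)^2 + (gy + 0.28)^2) / 0.004) +
                  exp(-((gx - 0.22)^2 + (gy + 0.28)^2) / 0.004))
  mouth <- 50 * exp(-((gx / 0.28)^2 + ((gy - 0.38) / 0.06)^2))
  neutral <- round(face - eyes - mouth)
  neutral[!mask] <- background
  neutral <- pmax(0L, pmin(255L, as.integer(neutral)))
  neutral <- matrix(neutral, size, size)
  # expression difference field: mouth-corner raise + brow change,
  # quantized to multiples of 5 so that 20% intensity steps are exact
  dfield <- 40 * exp(-(((abs(gx) - 0.22) / 0.1)^2 +
                         ((gy - 0.34) / 0.09)^2)) -
    25 * exp(-((gx / 0.3)^2 + ((gy + 0.42) / 0.08)^2))
  delta <- 5L * as.integer(round(dfield / 5))
  delta[!mask] <- 0L
  delta <- matrix(delta, size, size)
  morphs <- lapply(levels, function(L) {
    if (L == 0) return(neutral)
    img <- neutral + as.integer(round(L / 100 * delta))
    matrix(pmax(0L, pmin(255L, img)), size, size)
  })
  names(morphs) <- as.character(levels)
  list(neutral = neutral, morphs = morphs, mask = mask, delta = delta)
}

#' Read/write 8-bit grayscale images
#'
#' PNG via the `png` package; values are integer 0-255 matrices.
#'
#' @param img integer matrix (0-255).
#' @param path file path.
#' @return `read_gray_image`: integer matrix; writer returns the path.
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_gray_image
#' @export
read_gray_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}
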