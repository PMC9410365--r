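# Low-level image representation and geometry.
#
# Pixel arrays are H x W x 3 integer arrays with 8-bit channel values in
# [0, 255] (row = image row, matching how most annotation tools report
# coordinates). EBImage handles file I/O and Gaussian blur; the geometric
# transforms (resize, rotate, scale, crop) share a single bilinear sampler
# with reflection padding so that interpolation semantics are identical
# across the augmentation bank.

#' @keywords internal
assert_pixel_array <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L) {
    stop(what, " must be an H x W x C array, got dimensions [",
         paste(dim(img), collapse = " x "), "]", call. = FALSE)
  }
  if (dim(img)[3L] != 3L) {
    stop(what, " must have exactly 3 channels, got ", dim(img)[3L],
         call. = FALSE)
  }
  invisible(img)
}

# clamp and round a numeric array back to 8-bit integer storage
quantize_pixels <- function(img) {
  img <- round(img)
  img[img < 0] <- 0L
  img[img > 255] <- 255L
  storage.mode(img) <- "integer"
  img
}

# reflect index vector onto 1..n (half-sample symmetric reflection)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1, length(i)))
  period <- 2 * n
  i <- (i - 1) %% period
  i <- ifelse(i >= n, period - 1 - i, i)
  i + 1
}

# Sample img at fractional (row, col) coordinate grids by bilinear
# interpolation; out-of-range coordinates are reflected. `rows`, `cols`
# are equal-length vectors; returns a matrix-shaped value per channel
# assembled into an out_h x out_w x 3 array.
bilinear_sample <- function(img, rows, cols, out_h, out_w) {
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  n <- dim(img)[1L]; m <- dim(img)[2L]
  r0i <- reflect_index(r0, n); r1i <- reflect_index(r0 + 1, n)
  c0i <- reflect_index(c0, m); c1i <- reflect_index(c0 + 1, m)
  out <- array(0, dim = c(out_h, out_w, 3L))
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  for (ch in seq_len(3L)) {
    plane <- img[, , ch]
    v <- w00 * plane[cbind(r0i, c0i)] + w01 * plane[cbind(r0i, c1i)] +
         w10 * plane[cbind(r1i, c0i)] + w11 * plane[cbind(r1i, c1i)]
    out[, , ch] <- v
  }
  out
}

# Bilinear resize to out_h x out_w (aspect ratio not preserved).
resize_pixels <- function(img, out_h, out_w) {
  assert_pixel_array(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (h == out_h && w == out_w) return(quantize_pixels(img))
  # align pixel centers: output center u maps to input center scale*(u-.5)+.5
  rows <- (seq_len(out_h) - 0.5) * (h / out_h) + 0.5
  cols <- (seq_len(out_w) - 0.5) * (w / out_w) + 0.5
  grid_r <- rep(rows, times = out_w)
  grid_c <- rep(cols, each = out_h)
  quantize_pixels(bilinear_sample(img, grid_r, grid_c, out_h, out_w))
}

# Horizontal mirror (exact, integer-preserving).
flip_pixels_h <- function(img) {
  assert_pixel_array(img)
  img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
}

# Rotate about the image center by `angle_deg` (counter-clockwise),
# reflection padding for exposed corners, output size unchanged.
rotate_pixels <- function(img, angle_deg) {
  assert_pixel_array(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- rep(seq_len(h), times = w) - cy
  c <- rep(seq_len(w), each = h) - cx
  # inverse mapping: output coord rotated by -theta gives source coord
  src_r <- cos(th) * r + sin(th) * c + cy
  src_c <- -sin(th) * r + cos(th) * c + cx
  quantize_pixels(bilinear_sample(img, src_r, src_c, h, w))
}

# Central crop keeping [frac, 1-frac] of each dimension.
crop_pixels <- function(img, frac_per_side) {
  assert_pixel_array(img)
  if (frac_per_side <= 0 || frac_per_side >= 0.5) {
    stop("crop fraction per side must lie in (0, 0.5), got ", frac_per_side,
         call. = FALSE)
  }
  h <- dim(img)[1L]; w <- dim(img)[2L]
  r0 <- floor(h * frac_per_side) + 1L; r1 <- ceiling(h * (1 - frac_per_side))
  c0 <- floor(w * frac_per_side) + 1L; c1 <- ceiling(w * (1 - frac_per_side))
  if (r1 < r0 || c1 < c0) stop("degenerate crop: empty region", call. = FALSE)
  img[r0:r1, c0:c1, , drop = FALSE]
}

# EBImage bridge ------------------------------------------------------------

to_ebimage <- function(img) {
  assert_pixel_array(img)
  EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)), colormode = "Color")
}

from_ebimage <- function(ebi) {
  a <- as.array(ebi)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  quantize_pixels(aperm(a, c(2L, 1L, 3L)) * 255)
}

#' Read an image file into an 8-bit pixel array
#'
#' @param path path to a PNG or JPEG file.
#' @return an H x W x 3 integer array with values in \[0, 255\].
#' @export
read_image_file <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  from_ebimage(EBImage::readImage(path))
}

#' Write an 8-bit pixel array to an image file
#'
#' @param img H x W x 3 integer pixel array.
#' @param path output path; format chosen from the extension (png/jpg).
#' @return `path`, invisibly.
#' @export
write_image_file <- function(img, path) {
  assert_pixel_array(img)
  EBImage::writeImage(to_ebimage(img), path)
  invisible(path)
}

# Gaussian blur via EBImage (sigma in pixels); no-op for sigma <= 0.
blur_pixels <- function(img, sigma) {
  if (sigma <= 0) return(quantize_pixels(img))
  from_ebimage(EBImage::gblur(to_ebimage(img), sigma = sigma))
}
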