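#' Read an 8-bit grayscale image (PNG or BMP)
#'
#' EUS capture stations typically export Windows bitmap (BMP) stills; PNG is
#' supported as the lossless interchange format. Color inputs are converted
#' to luminance (Rec. 601 weights) with a warning.
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return An integer brightness matrix in \[0, 255\] (see [gray_image()]).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_validation("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      nch <- dim(arr)[3]
      if (nch >= 3L) {
        warning("color image converted to luminance", call. = FALSE)
        arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      } else {
        arr <- arr[, , 1]
      }
    }
    gray_image(round_half_up(arr * 255))
  } else if (ext == "bmp") {
    read_bmp_gray(path)
  } else {
    stop_validation("unsupported image format '.%s' (use PNG or BMP)", ext)
  }
}

#' Write an 8-bit grayscale image (PNG or BMP)
#'
#' @param image Brightness matrix in \[0, 255\].
#' @param path Output path ending in `.png` or `.bmp`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- gray_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, path)
  } else if (ext == "bmp") {
    write_bmp_gray(image, path)
  } else {
    stop_validation("unsupported image format '.%s' (use PNG or BMP)", ext)
  }
  invisible(path)
}

# --- Minimal Windows bitmap support ----------------------------------------
# Uncompressed BI_RGB bitmaps only: 8-bit paletted (read as palette luminance)
# and 24-bit BGR (converted to luminance). Rows are bottom-up and padded to
# 4-byte boundaries per the BMP format.

read_u16 <- function(raw, off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
read_u32 <- function(raw, off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop_validation("not a BMP file: %s", path)
  }
  data_off <- read_u32(raw, 10)
  header_size <- read_u32(raw, 14)
  if (header_size < 40) stop_validation("unsupported BMP header in %s", path)
  width <- read_u32(raw, 18)
  height <- read_u32(raw, 22)
  bottom_up <- TRUE
  if (height > 2^31) { # negative int32: top-down row order
    height <- 2^32 - height
    bottom_up <- FALSE
  }
  bpp <- read_u16(raw, 28)
  compression <- read_u32(raw, 30)
  if (compression != 0) stop_validation("compressed BMP not supported: %s", path)
  if (!bpp %in% c(8, 24)) {
    stop_validation("only 8-bit and 24-bit BMP supported (got %d-bit)", bpp)
  }
  row_bytes <- ((width * bpp / 8 + 3) %/% 4) * 4
  img <- matrix(0L, nrow = height, ncol = width)
  if (bpp == 8) {
    # palette: 4 bytes per entry (B,G,R,0) following the info header
    pal_off <- 14 + header_size
    n_pal <- (data_off - pal_off) / 4
    if (n_pal < 1) stop_validation("8-bit BMP without palette: %s", path)
    pal <- matrix(as.integer(raw[pal_off + seq_len(n_pal * 4)]), nrow = 4)
    pal_lum <- round_half_up(0.299 * pal[3, ] + 0.587 * pal[2, ] + 0.114 * pal[1, ])
    for (r in seq_len(height)) {
      off <- data_off + (r - 1) * row_bytes
      idx <- as.integer(raw[off + seq_len(width)])
      row_vals <- pal_lum[idx + 1L]
      img[if (bottom_up) height - r + 1L else r, ] <- row_vals
    }
  } else {
    for (r in seq_len(height)) {
      off <- data_off + (r - 1) * row_bytes
      trip <- matrix(as.integer(raw[off + seq_len(width * 3)]), nrow = 3)
      row_vals <- round_half_up(0.299 * trip[3, ] + 0.587 * trip[2, ] + 0.114 * trip[1, ])
      if (!all(trip[1, ] == trip[2, ] & trip[2, ] == trip[3, ])) {
        warning("color image converted to luminance", call. = FALSE)
      }
      img[if (bottom_up) height - r + 1L else r, ] <- row_vals
    }
  }
  gray_image(img)
}

write_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
write_u32 <- function(x) as.raw((x %/% 256^(0:3)) %% 256)

write_bmp_gray <- function(image, path) {
  h <- nrow(image)
  w <- ncol(image)
  row_bytes <- ((w + 3) %/% 4) * 4
  data_off <- 14 + 40 + 256 * 4
  file_size <- data_off + row_bytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(c(write_u32(file_size), write_u32(0), write_u32(data_off)), con)
  writeBin(c(write_u32(40), write_u32(w), write_u32(h), write_u16(1),
             write_u16(8), write_u32(0), write_u32(row_bytes * h),
             write_u32(2835), write_u32(2835), write_u32(256), write_u32(0)), con)
  # grayscale palette: entry i = (i, i, i, 0)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))
  writeBin(pal, con)
  pad <- as.raw(rep(0L, row_bytes - w))
  for (r in seq(h, 1)) { # bottom-up
    writeBin(c(as.raw(image[r, ]), pad), con)
  }
  invisible(path)
}
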