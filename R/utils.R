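# Internal numeric helpers shared across the pipeline.

# Round half away from zero (base round() is banker's rounding; 8-bit image
# pipelines conventionally round .5 up).
round_half_up <- function(x) floor(x + 0.5)

# Clip to the 8-bit brightness range.
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Offsets of the 8- and 4-neighborhoods.
neighbor_offsets <- function(connectivity = 8) {
  if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
         c(0L, -1L),               c(0L, 1L),
         c(1L, -1L),  c(1L, 0L),  c(1L, 1L))
  }
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Validate an 8-bit grayscale image matrix
#'
#' Images throughout the package are plain integer matrices with values in
#' \[0, 255\] (0 = black, 255 = white), indexed \[row, column\].
#'
#' @param pixels A numeric matrix.
#' @param min_dim Minimum number of rows and columns required.
#' @return The validated matrix, in integer storage mode.
#' @export
gray_image <- function(pixels, min_dim = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_validation("image must be a numeric matrix")
  }
  if (nrow(pixels) < min_dim || ncol(pixels) < min_dim) {
    stop_validation("image must be at least %dx%d", min_dim, min_dim)
  }
  if (anyNA(pixels)) stop_validation("image contains NA pixels")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("image brightness values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  pixels
}
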