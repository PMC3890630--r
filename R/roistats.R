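# First-order brightness statistics of a manually delineated region of
# interest (ROI) on the standardized frame. T_mean quantifies echogenicity,
# T_SD heterogeneity.

#' Construct/validate an ROI mask
#'
#' An ROI is a logical matrix matching the image shape. It can also be
#' given as a polygon (matrix of `(row, col)` vertices), rasterized with
#' the even-odd rule: a pixel center is inside when a ray from it crosses
#' the polygon boundary an odd number of times.
#'
#' @param x Logical/0-1 matrix, or an n x 2 vertex matrix when
#'   `shape` is supplied.
#' @param shape `(rows, cols)` of the target image, required for polygon
#'   input.
#' @param min_pixels Minimum ROI size for stable statistics; default 25.
#' @return A logical mask matrix with attribute `n_pixels`.
#' @export
roi_mask <- function(x, shape = NULL, min_pixels = 25) {
  if (!is.null(shape)) {
    mask <- rasterize_polygon(x, shape)
  } else {
    if (!is.matrix(x)) stop_validation("ROI must be a matrix")
    mask <- x != 0
  }
  n <- sum(mask)
  if (n < min_pixels) {
    stop_validation("ROI has %d pixels; at least %d required", n, min_pixels)
  }
  attr(mask, "n_pixels") <- n
  mask
}

# Even-odd polygon fill over pixel centers (integer grid).
rasterize_polygon <- function(vertices, shape) {
  if (!is.matrix(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop_validation("polygon must be an n x 2 matrix of (row, col) vertices, n >= 3")
  }
  nr <- shape[1]
  nc <- shape[2]
  vr <- vertices[, 1]
  vc <- vertices[, 2]
  n <- length(vr)
  jj <- c(n, seq_len(n - 1))
  mask <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # horizontal ray crossing count per pixel center
  cross <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    r1 <- vr[k]; r2 <- vr[jj[k]]
    c1 <- vc[k]; c2 <- vc[jj[k]]
    if (r1 == r2) next
    hit <- (rows < r1) != (rows < r2)
    xc <- c1 + (rows - r1) * (c2 - c1) / (r2 - r1)
    cross <- cross + (hit & cols < xc)
  }
  mask[cross %% 2L == 1L] <- TRUE
  mask
}

#' Brightness statistics of an ROI
#'
#' Computes minimum, maximum, mean (`T_mean`), standard deviation (`T_SD`),
#' median, and quartiles over the brightness values under the mask. The SD
#' is the population standard deviation (divisor `n`); quartiles use linear
#' interpolation between order statistics. `mean` and `sd` are reported to
#' 2 decimals.
#'
#' @param image Brightness matrix in \[0, 255\].
#' @param roi Logical ROI mask, same shape as `image` (see [roi_mask()]).
#' @param min_pixels Minimum ROI size; default 25.
#' @return An object of class `brightness_stats` with fields `minimum`,
#'   `maximum`, `mean`, `sd`, `median`, `q1`, `q3`, `n_pixels`.
#' @export
compute_roi_stats <- function(image, roi, min_pixels = 25) {
  image <- gray_image(image)
  if (!identical(dim(roi), dim(image))) {
    stop_validation("ROI mask shape %s does not match image shape %s",
                    paste(dim(roi), collapse = "x"),
                    paste(dim(image), collapse = "x"))
  }
  roi <- roi_mask(roi, min_pixels = min_pixels)
  v <- as.numeric(image[roi])
  n <- length(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(
    minimum = min(v), maximum = max(v),
    mean = round(mean(v), 2),
    sd = round(sqrt(sum((v - mean(v))^2) / n), 2),
    median = q[2], q1 = q[1], q3 = q[3],
    n_pixels = n
  ), class = "brightness_stats")
}

#' @export
print.brightness_stats <- function(x, ...) {
  cat(sprintf("ROI brightness statistics (n = %d pixels)\n", x$n_pixels))
  cat(sprintf("  T_mean (echogenicity):  %.2f\n", x$mean))
  cat(sprintf("  T_SD (heterogeneity):   %.2f\n", x$sd))
  cat(sprintf("  min/median/max:         %g / %g / %g\n",
              x$minimum, x$median, x$maximum))
  cat(sprintf("  quartiles (Q1, Q3):     %g, %g\n", x$q1, x$q3))
  invisible(x)
}

#' ROI brightness histogram
#'
#' @param image Brightness matrix in \[0, 255\].
#' @param roi Logical ROI mask, same shape as `image`.
#' @param min_pixels Minimum ROI size; default 25.
#' @return Integer vector of length 256: pixel counts per gray level 0..255;
#'   counts sum to the mask size.
#' @export
roi_histogram <- function(image, roi, min_pixels = 25) {
  image <- gray_image(image)
  if (!identical(dim(roi), dim(image))) {
    stop_validation("ROI mask shape does not match image shape")
  }
  roi <- roi_mask(roi, min_pixels = min_pixels)
  tabulate(as.vector(image[roi]) + 1L, nbins = 256L)
}
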