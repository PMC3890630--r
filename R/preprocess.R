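# Anchor-extraction chain: contrast smoothing, gradients, edge linking,
# binarization, grassfire labeling and morphological noise removal.

#' Histogram smoothing (global histogram equalization)
#'
#' Remaps gray levels through the cumulative distribution of the 256-bin
#' histogram so the output occupies the full \[0, 255\] range. The mapping
#' `f(v) = round(255 * cdf(v))` is monotone non-decreasing, so relative
#' pixel ordering is preserved. A constant image maps to the constant 255
#' (its single level has cdf 1).
#'
#' @param image Brightness matrix in \[0, 255\].
#' @return The equalized image.
#' @export
smooth_histogram <- function(image) {
  image <- gray_image(image)
  counts <- tabulate(as.vector(image) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(image)
  lut <- as.integer(round_half_up(255 * cdf))
  out <- matrix(lut[image + 1L], nrow(image), ncol(image))
  gray_image(out)
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel horizontal/vertical derivative pair with symmetric (reflective)
#' border padding; returns `sqrt(gx^2 + gy^2)` per pixel. Zero everywhere
#' for a constant image.
#'
#' @param image Brightness matrix in \[0, 255\].
#' @return A non-negative numeric matrix of gradient magnitudes, same shape.
#' @export
gradient_magnitude <- function(image) {
  image <- gray_image(image)
  m <- rbind(image[1, , drop = FALSE], image, image[nrow(image), , drop = FALSE])
  m <- cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  nr <- nrow(image)
  nc <- ncol(image)
  win <- function(dr, dc) m[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # gx: column derivative; gy: row derivative
  gx <- (win(-1, 1) + 2 * win(0, 1) + win(1, 1)) -
        (win(-1, -1) + 2 * win(0, -1) + win(1, -1))
  gy <- (win(1, -1) + 2 * win(1, 0) + win(1, 1)) -
        (win(-1, -1) + 2 * win(-1, 0) + win(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Edge linking over a gradient map
#'
#' Produces an edge mask by region-growing on the gradient magnitude:
#' seed pixels are those whose rescaled magnitude reaches the
#' `seed_quantile` quantile of the nonzero magnitudes; a pixel joins the
#' mask when it has an 8-neighbor already in the mask whose magnitude
#' differs from its own by at most `th`, iterated to a fixed point. Growth
#' is the closure of a symmetric relation, so the result does not depend on
#' visiting order. Magnitudes are linearly rescaled to \[0, 255\] before
#' thresholding so `th` is on the brightness scale.
#'
#' @param grad Gradient magnitude matrix (non-negative), e.g. from
#'   [gradient_magnitude()].
#' @param th Maximum absolute magnitude difference for linking; default 130.
#' @param seed_quantile Quantile of nonzero rescaled magnitudes used as the
#'   seed level (inclusive).
#' @return A logical edge mask, same shape as `grad`.
#' @export
link_edges <- function(grad, th = 130, seed_quantile = 0.9) {
  if (!is.matrix(grad) || min(grad) < 0) {
    stop_validation("grad must be a non-negative matrix")
  }
  if (th < 0) stop_validation("th must be >= 0")
  g <- grad
  mx <- max(g)
  if (mx > 0) g <- g * (255 / mx)
  nz <- g[g > 0]
  if (length(nz) == 0) return(matrix(FALSE, nrow(g), ncol(g)))
  seed_level <- stats::quantile(nz, seed_quantile, names = FALSE)
  mask <- g >= seed_level
  offs <- neighbor_offsets(8)
  repeat {
    grown <- mask
    for (o in offs) {
      nb_in <- shift_mat(mask, o[1], o[2], fill = FALSE)
      nb_g <- shift_mat(g, o[1], o[2], fill = -Inf)
      grown <- grown | (nb_in & abs(g - nb_g) <= th)
    }
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

#' Otsu threshold of a 256-bin brightness histogram
#'
#' Returns the threshold `t` in 1..255 maximizing the between-class variance
#' of the split into pixels `< t` and `>= t`; ties break toward the lower
#' threshold. Returns `NA` for a degenerate (single-level) histogram.
#'
#' @param image Brightness matrix in \[0, 255\].
#' @return Integer threshold, or `NA_integer_`.
#' @export
otsu_threshold <- function(image) {
  image <- gray_image(image)
  counts <- tabulate(as.vector(image) + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  w0 <- cumsum(p)            # weight of class {<= level}
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # candidate thresholds t = level + 1 (class0 = values < t)
  w0 <- w0[-256]
  mu0 <- mu[-256]
  valid <- w0 > 0 & w0 < 1
  if (!any(valid)) return(NA_integer_)
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  as.integer(which.max(sigma_b))  # first max -> lowest threshold
}

#' Binarize an image
#'
#' Foreground is `pixel >= threshold` (inclusive). With `method = "otsu"`
#' the threshold maximizes between-class variance ([otsu_threshold()]); a
#' constant image yields all background by convention.
#'
#' @param image Brightness matrix in \[0, 255\].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold in \[0, 255\], required for
#'   `method = "fixed"`.
#' @return A logical foreground mask.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), fixed_threshold = NULL) {
  image <- gray_image(image)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop_validation("fixed_threshold is required when method = 'fixed'")
    }
    if (fixed_threshold < 0 || fixed_threshold > 255) {
      stop_validation("fixed_threshold must lie in [0, 255]")
    }
    t <- fixed_threshold
  } else {
    t <- otsu_threshold(image)
    if (is.na(t)) return(matrix(FALSE, nrow(image), ncol(image)))
  }
  image >= t
}

#' Connected-component (grassfire) labeling
#'
#' Labels each connected set of foreground pixels with a positive integer
#' (background = 0), equivalent to grassfire/flood-fill propagation.
#' Implemented as iterated minimum-label propagation over the chosen
#' neighborhood until a fixed point; labels are then renumbered 1..n in
#' raster-scan order of first appearance.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return A list with `labels` (integer matrix) and `n_components`.
#' @export
label_components <- function(binary, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_validation("connectivity must be 4 or 8")
  fg <- binary != 0
  nr <- nrow(fg)
  nc <- ncol(fg)
  lab <- matrix(0, nr, nc)
  lab[fg] <- which(fg)  # column-major linear index as provisional label
  offs <- neighbor_offsets(connectivity)
  repeat {
    new_lab <- lab
    for (o in offs) {
      nb <- shift_mat(lab, o[1], o[2], fill = Inf)
      nb[nb == 0] <- Inf
      new_lab <- pmin(new_lab, ifelse(fg, nb, 0))
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  relabel_consecutive(lab)
}

# Renumber positive labels 1..n by raster-scan (row-major) first appearance.
relabel_consecutive <- function(lab) {
  vals <- as.vector(t(lab))          # row-major traversal
  first <- vals[vals > 0 & !duplicated(vals)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(first)) {
    out[lab > 0] <- match(lab[lab > 0], first)
  }
  list(labels = out, n_components = length(first))
}

# Per-component area, edge-count perimeter, circularity 4*pi*A/P^2 and
# centroid. Perimeter counts pixel edges shared with background or the
# image border (4-neighborhood), the standard digital edge-count measure.
component_stats <- function(labelmap) {
  lab <- labelmap$labels
  n <- labelmap$n_components
  if (n == 0) {
    return(data.frame(label = integer(), area = integer(), perimeter = integer(),
                      circularity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  }
  area <- tabulate(lab[lab > 0], nbins = n)
  perim <- integer(n)
  for (o in neighbor_offsets(4)) {
    nb <- shift_mat(lab, o[1], o[2], fill = 0L)
    exposed <- lab > 0 & nb != lab
    perim <- perim + tabulate(lab[exposed], nbins = n)
  }
  rr <- matrix(seq_len(nrow(lab)), nrow(lab), ncol(lab))
  cc <- matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE)
  cr <- vapply(seq_len(n), function(i) mean(rr[lab == i]), numeric(1))
  ccol <- vapply(seq_len(n), function(i) mean(cc[lab == i]), numeric(1))
  data.frame(label = seq_len(n), area = area, perimeter = perim,
             circularity = 4 * pi * area / pmax(perim, 1)^2,
             centroid_row = cr, centroid_col = ccol)
}

#' Morphological noise removal
#'
#' Drops labeled components whose area falls below `min_area`, or whose
#' circularity `4*pi*A/P^2` (edge-count perimeter) falls below
#' `min_circularity` when given; survivors are relabeled consecutively.
#'
#' @param labelmap A label map from [label_components()].
#' @param min_area Minimum component area in pixels.
#' @param min_circularity Optional circularity floor in \[0, 1\].
#' @return A filtered label map (same structure as [label_components()]).
#' @export
remove_noise <- function(labelmap, min_area = 30, min_circularity = NULL) {
  if (min_area < 0) stop_validation("min_area must be >= 0")
  if (!is.null(min_circularity) &&
      (min_circularity < 0 || min_circularity > 1)) {
    stop_validation("min_circularity must lie in [0, 1]")
  }
  st <- component_stats(labelmap)
  ok <- st$area >= min_area
  if (!is.null(min_circularity)) ok <- ok & st$circularity >= min_circularity
  keep <- st$label[ok]
  lab <- labelmap$labels
  lab[!(lab %in% keep)] <- 0L
  relabel_consecutive(lab)
}
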