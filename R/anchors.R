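# Scope brightness anchors: the anechoic (dark) transducer center and the
# hyperechoic (bright) rim around it have the least acquisition-to-
# acquisition variability in a radial EUS frame, so their mean brightness
# values anchor the gray-level standardization.

#' Construct a scope-anchors object
#'
#' @param center_gray Mean brightness of the anechoic center.
#' @param rim_gray Mean brightness of the hyperechoic rim; must exceed
#'   `center_gray`.
#' @param standard_gray Optional intermediate anchor; computed with
#'   [compute_standard_gray()] when `NULL`.
#' @param center_mask,rim_mask Optional logical masks of the two regions.
#' @return An object of class `scope_anchors`.
#' @export
scope_anchors <- function(center_gray, rim_gray, standard_gray = NULL,
                          center_mask = NULL, rim_mask = NULL) {
  if (center_gray < 0 || rim_gray > 255 || center_gray >= rim_gray) {
    stop_validation("anchors must satisfy 0 <= center_gray < rim_gray <= 255")
  }
  if (is.null(standard_gray)) {
    standard_gray <- compute_standard_gray(center_gray, rim_gray)
  }
  if (standard_gray <= center_gray || standard_gray >= rim_gray) {
    stop_validation("standard_gray must lie strictly between center_gray and rim_gray")
  }
  structure(list(center_gray = center_gray, rim_gray = rim_gray,
                 standard_gray = standard_gray,
                 center_mask = center_mask, rim_mask = rim_mask),
            class = "scope_anchors")
}

#' @export
print.scope_anchors <- function(x, ...) {
  cat("Scope brightness anchors\n")
  cat(sprintf("  center (anechoic):   %.2f\n", x$center_gray))
  cat(sprintf("  standard:            %.2f\n", x$standard_gray))
  cat(sprintf("  rim (hyperechoic):   %.2f\n", x$rim_gray))
  if (!is.null(x$center_mask)) {
    cat(sprintf("  center mask: %d px; rim mask: %d px\n",
                sum(x$center_mask), sum(x$rim_mask)))
  }
  invisible(x)
}

#' Intermediate standardization anchor
#'
#' Computes `StandardGray`, the brightness level separating the anechoic
#' center from the hyperechoic rim in the piecewise standardization, as
#' `(255 - rim_gray) * (1 + (255 - rim_gray) / center_gray)`, clamped into
#' `[center_gray + 1, rim_gray - 1]`. With `center_gray = 0` the ratio is
#' undefined and the midpoint `(center_gray + rim_gray) / 2` is used with a
#' warning. An explicit `override` bypasses the formula entirely.
#'
#' @param center_gray,rim_gray Anchor brightness values with
#'   `0 <= center_gray < rim_gray <= 255`.
#' @param override Optional fixed `StandardGray` value.
#' @return The `StandardGray` brightness value.
#' @export
compute_standard_gray <- function(center_gray, rim_gray, override = NULL) {
  if (!is.null(override)) return(override)
  if (center_gray < 0 || rim_gray > 255 || center_gray >= rim_gray) {
    stop_validation("anchors must satisfy 0 <= center_gray < rim_gray <= 255")
  }
  if (center_gray == 0) {
    warning("center_gray is 0; using midpoint StandardGray", call. = FALSE)
    return((center_gray + rim_gray) / 2)
  }
  s <- (255 - rim_gray) * (1 + (255 - rim_gray) / center_gray)
  min(max(s, center_gray + 1), rim_gray - 1)
}

default_anchor_config <- function() {
  list(
    transducer_position = NULL,  # (row, col); NULL = image center
    th = 130,                    # edge-linking brightness-difference threshold
    seed_quantile = 0.9,
    min_area = 30,               # center-candidate noise removal
    min_circularity = 0.3,
    dark_margin = 5,             # candidate must be this much darker than frame mean
    max_refine = 3,              # coarse-to-fine Otsu refinement rounds
    rim_width_factor = 1.2,      # rim search ring width, x center radius
    radial_tol = 5,              # slack for the radial local-maximum test, ~speckle scale
    standard_gray = NULL         # override for compute_standard_gray()
  )
}

#' Extract the scope's brightness anchors from an EUS frame
#'
#' Runs the extraction chain — histogram smoothing, Sobel gradients, edge
#' linking, binarization, grassfire labeling, morphological noise removal —
#' then locates the anechoic center as the surviving dark component nearest
#' the configured transducer position and the hyperechoic rim as the ring of
#' adjacent pixels that are bright and radially locally maximal. Anchor
#' brightness values are means of the *source* image under the masks,
#' rounded to 2 decimals.
#'
#' The dark binarization threshold starts at the frame's Otsu level and is
#' refined by re-applying Otsu within an oversized candidate component (up
#' to `max_refine` rounds), so a dark-ish background does not swallow the
#' transducer core. A candidate must be at least `dark_margin` gray levels
#' darker than the frame mean, otherwise the center is declared not found.
#'
#' @param image Brightness matrix in \[0, 255\], at least 16x16.
#' @param config Named list overriding the defaults: `transducer_position`
#'   (row, col; default image center), `th` (130), `seed_quantile` (0.9),
#'   `min_area` (30), `min_circularity` (0.3), `dark_margin` (5),
#'   `max_refine` (3), `rim_width_factor` (1.2), `radial_tol` (5),
#'   `standard_gray` (override).
#' @return A [scope_anchors()] object; `$intermediates` carries the
#'   equalized image, gradient map, edge mask and the final dark threshold
#'   for inspection.
#' @export
extract_scope_anchors <- function(image, config = list()) {
  image <- gray_image(image, min_dim = 16L)
  cfg <- utils::modifyList(default_anchor_config(), config)
  pos <- cfg$transducer_position
  if (is.null(pos)) pos <- c((nrow(image) + 1) / 2, (ncol(image) + 1) / 2)

  eq <- smooth_histogram(image)
  grad <- gradient_magnitude(eq)
  edges <- link_edges(grad, th = cfg$th, seed_quantile = cfg$seed_quantile)

  frame_mean <- mean(image)
  t_dark <- otsu_threshold(image)
  if (is.na(t_dark)) stop_validation("scope center not found")
  center_mask <- NULL
  for (round_i in seq_len(cfg$max_refine)) {
    dark <- !binarize(image, method = "fixed", fixed_threshold = t_dark)
    lm <- remove_noise(label_components(dark, connectivity = 8),
                       min_area = cfg$min_area,
                       min_circularity = cfg$min_circularity)
    if (lm$n_components == 0) stop_validation("scope center not found")
    st <- component_stats(lm)
    st$dist <- sqrt((st$centroid_row - pos[1])^2 + (st$centroid_col - pos[2])^2)
    st$mean_gray <- vapply(st$label, function(l) mean(image[lm$labels == l]),
                           numeric(1))
    # nearest to the transducer; ties: larger area, then lower mean gray
    st <- st[order(st$dist, -st$area, st$mean_gray), ]
    cand <- st[1, ]
    center_mask <- lm$labels == cand$label
    if (cand$area <= 0.4 * length(image)) break
    t_new <- otsu_threshold(matrix(image[center_mask], ncol = 1))
    if (is.na(t_new) || t_new >= t_dark) break
    t_dark <- t_new
  }
  if (mean(image[center_mask]) > frame_mean - cfg$dark_margin) {
    stop_validation("scope center not found")
  }

  rim_mask <- extract_rim_mask(image, center_mask, pos, cfg)
  if (!any(rim_mask)) stop_validation("scope rim not found")

  anchors <- scope_anchors(
    center_gray = round(mean(image[center_mask]), 2),
    rim_gray = round(mean(image[rim_mask]), 2),
    standard_gray = compute_standard_gray(
      round(mean(image[center_mask]), 2), round(mean(image[rim_mask]), 2),
      override = cfg$standard_gray),
    center_mask = center_mask, rim_mask = rim_mask
  )
  anchors$intermediates <- list(equalized = eq, gradient = grad, edges = edges,
                                dark_threshold = t_dark)
  anchors
}

# Rim = pixels in a ring just outside the center component that are bright
# (above the ring's own Otsu split) and at least as bright as both of their
# neighbors along the radial direction from the center centroid (within
# radial_tol gray levels).
extract_rim_mask <- function(image, center_mask, pos, cfg) {
  nr <- nrow(image)
  nc <- ncol(image)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ctr <- c(mean(rr[center_mask]), mean(cc[center_mask]))
  d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  r_edge <- max(d[center_mask])
  r_eq <- sqrt(sum(center_mask) / pi)
  width <- max(5, cfg$rim_width_factor * r_eq)
  ring <- !center_mask & d > r_edge - 1 & d <= r_edge + width
  if (!any(ring)) return(ring)

  t_bright <- otsu_threshold(matrix(image[ring], ncol = 1))
  if (is.na(t_bright)) return(ring & FALSE)
  bright <- image >= t_bright

  ur <- (rr - ctr[1]) / pmax(d, 1e-9)
  uc <- (cc - ctr[2]) / pmax(d, 1e-9)
  at <- function(r, c) {
    r <- pmin(pmax(round_half_up(r), 1), nr)
    c <- pmin(pmax(round_half_up(c), 1), nc)
    matrix(image[cbind(as.vector(r), as.vector(c))], nr, nc)
  }
  inner <- at(rr - ur, cc - uc)
  outer <- at(rr + ur, cc + uc)
  radial_max <- image >= pmax(inner, outer) - cfg$radial_tol
  ring & bright & radial_max
}
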