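# Gray-level standardization anchored at the scope's center and rim
# brightness. Different gain/contrast settings shift the whole gray scale;
# mapping the anechoic center toward 0 and the hyperechoic rim to 255, with
# StandardGray as the fixed point separating the two linear stretches,
# makes brightness statistics comparable across acquisitions.

#' Standardization lookup table
#'
#' Builds the piecewise-linear brightness remap for a set of anchors:
#' \itemize{
#'   \item `X <= center_gray` maps to 0;
#'   \item `center_gray < X <= standard_gray` maps to
#'     `standard_gray * (X - center_gray) / (standard_gray - center_gray)`;
#'   \item `standard_gray < X <= rim_gray` maps to
#'     `standard_gray + (255 - standard_gray) * (X - standard_gray) / (rim_gray - standard_gray)`;
#'   \item `X > rim_gray` maps to 255.
#' }
#' Outputs are rounded half-up to integers and clipped to \[0, 255\]. The
#' map is monotone non-decreasing, fixes `standard_gray`, and with anchors
#' `(0, s, 255)` reduces to the identity.
#'
#' @param anchors A [scope_anchors()] object (or list with `center_gray`,
#'   `standard_gray`, `rim_gray`).
#' @return Integer vector of length 256: the output level for each input
#'   level 0..255.
#' @export
standardization_map <- function(anchors) {
  ctr <- anchors$center_gray
  s <- anchors$standard_gray
  rim <- anchors$rim_gray
  if (is.null(s)) stop_validation("anchors must include standard_gray")
  if (!(ctr < s && s < rim)) {
    stop_validation("degenerate anchors: need center_gray < standard_gray < rim_gray")
  }
  x <- 0:255
  y <- numeric(256)
  lo <- x > ctr & x <= s
  hi <- x > s & x <= rim
  y[x <= ctr] <- 0
  y[lo] <- s * (x[lo] - ctr) / (s - ctr)
  y[hi] <- s + (255 - s) * (x[hi] - s) / (rim - s)
  y[x > rim] <- 255
  as.integer(clip255(round_half_up(y)))
}

#' Standardize an image's gray levels
#'
#' Applies the piecewise-linear anchor remap of [standardization_map()] to
#' every pixel.
#'
#' @param image Brightness matrix in \[0, 255\].
#' @param anchors A [scope_anchors()] object.
#' @return The standardized image (integer matrix in \[0, 255\]).
#' @export
standardize_image <- function(image, anchors) {
  image <- gray_image(image)
  lut <- standardization_map(anchors)
  gray_image(matrix(lut[image + 1L], nrow(image), ncol(image)))
}

#' Export a standardization lookup table as CSV
#'
#' Writes 256 rows (`input,output`) for audit of the remap.
#'
#' @param anchors A [scope_anchors()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_standardization_lut <- function(anchors, path) {
  lut <- standardization_map(anchors)
  utils::write.csv(data.frame(input = 0:255, output = lut), path,
                   row.names = FALSE)
  invisible(path)
}
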