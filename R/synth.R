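#' Specify a synthetic EUS phantom frame
#'
#' A phantom emulates the geometry of a radial EUS still frame: the dark
#' (anechoic) transducer core, the bright (hyperechoic) rim ring around it,
#' a speckled mid-gray background, and one elliptical hypoechoic tumor. Each
#' region receives independent Gaussian per-pixel noise, clipped to \[0, 255\]
#' and then rounded, so programmed region moments are directly recoverable.
#'
#' Default brightness values follow the typical appearance of a 7.5 MHz
#' radial frame: a near-black center, a near-white rim, and a tumor darker
#' than the surrounding background.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param scope_center `(row, col)` of the transducer core.
#' @param center_radius Radius of the anechoic center disk, pixels.
#' @param center_gray Programmed center brightness, 0--255.
#' @param rim_inner_radius,rim_outer_radius Radii bounding the hyperechoic
#'   rim annulus; must satisfy `center_radius < rim_inner < rim_outer`.
#' @param rim_gray Programmed rim brightness.
#' @param background_gray_mean Programmed background brightness.
#' @param speckle_sd Per-pixel Gaussian noise SD for center, rim and
#'   background (brightness units).
#' @param tumor_center `(row, col)` of the tumor ellipse.
#' @param tumor_axes `(a, b)` semi-axes in pixels.
#' @param tumor_angle Ellipse rotation, degrees counter-clockwise.
#' @param tumor_gray_mean,tumor_gray_sd Programmed tumor brightness mean and
#'   per-pixel SD.
#' @param seed Integer RNG seed; identical specs and seeds give bit-identical
#'   phantoms.
#' @return A `phantom_spec` list.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_width = 200, image_height = 200,
                         scope_center = c(100, 100),
                         center_radius = 14, center_gray = 10,
                         rim_inner_radius = 16, rim_outer_radius = 24,
                         rim_gray = 240,
                         background_gray_mean = 120, speckle_sd = 8,
                         tumor_center = c(140, 140), tumor_axes = c(30, 22),
                         tumor_angle = 20, tumor_gray_mean = 80,
                         tumor_gray_sd = 15, seed = 1L) {
  spec <- list(
    image_width = image_width, image_height = image_height,
    scope_center = scope_center, center_radius = center_radius,
    center_gray = center_gray, rim_inner_radius = rim_inner_radius,
    rim_outer_radius = rim_outer_radius, rim_gray = rim_gray,
    background_gray_mean = background_gray_mean, speckle_sd = speckle_sd,
    tumor_center = tumor_center, tumor_axes = tumor_axes,
    tumor_angle = tumor_angle, tumor_gray_mean = tumor_gray_mean,
    tumor_gray_sd = tumor_gray_sd, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  grays <- c(center_gray = spec$center_gray, rim_gray = spec$rim_gray,
             background_gray_mean = spec$background_gray_mean,
             tumor_gray_mean = spec$tumor_gray_mean)
  for (nm in names(grays)) {
    if (grays[[nm]] < 0 || grays[[nm]] > 255) {
      stop_validation("%s must lie in [0, 255]", nm)
    }
  }
  if (spec$speckle_sd < 0) stop_validation("speckle_sd must be >= 0")
  if (spec$tumor_gray_sd < 0) stop_validation("tumor_gray_sd must be >= 0")
  if (!(spec$center_radius < spec$rim_inner_radius &&
        spec$rim_inner_radius < spec$rim_outer_radius)) {
    stop_validation("radii must satisfy center_radius < rim_inner_radius < rim_outer_radius")
  }
  if (spec$image_width < 16 || spec$image_height < 16) {
    stop_validation("image_width/image_height must be >= 16")
  }
  masks <- phantom_masks(spec)
  if (any(masks$tumor_raw & (masks$rim | masks$center))) {
    stop_validation("tumor_center/tumor_axes: tumor ellipse overlaps the scope center/rim")
  }
  spec
}

# Region masks implied by the geometry; tumor takes precedence over
# background but never touches center/rim (enforced by the validator).
phantom_masks <- function(spec) {
  h <- spec$image_height
  w <- spec$image_width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (rr - spec$scope_center[1])^2 + (cc - spec$scope_center[2])^2
  center <- d2 <= spec$center_radius^2
  rim <- d2 >= spec$rim_inner_radius^2 & d2 <= spec$rim_outer_radius^2
  th <- spec$tumor_angle * pi / 180
  dr <- rr - spec$tumor_center[1]
  dc <- cc - spec$tumor_center[2]
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  tumor_raw <- (u / spec$tumor_axes[1])^2 + (v / spec$tumor_axes[2])^2 <= 1
  list(center = center, rim = rim,
       tumor = tumor_raw & !center & !rim, tumor_raw = tumor_raw)
}

#' Generate a phantom EUS frame with ground-truth masks
#'
#' Pixels are drawn independently per region as
#' `Normal(region mean, region SD)`, clipped to \[0, 255\], then rounded.
#' With zero noise every pixel equals its programmed region brightness
#' exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (integer brightness matrix) and `truth`, a
#'   list of disjoint binary masks `center_mask`, `rim_mask`, `tumor_mask`
#'   plus the programmed `tumor_gray_mean`/`tumor_gray_sd`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' mean(ph$image[ph$truth$tumor_mask])
#' @export
generate_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  masks <- phantom_masks(spec)
  h <- spec$image_height
  w <- spec$image_width
  set.seed(spec$seed)
  img <- matrix(stats::rnorm(h * w, spec$background_gray_mean, spec$speckle_sd), h, w)
  draw <- function(mask, mu, sd) {
    n <- sum(mask)
    if (n > 0) img[mask] <<- stats::rnorm(n, mu, sd)
  }
  draw(masks$center, spec$center_gray, spec$speckle_sd)
  draw(masks$rim, spec$rim_gray, spec$speckle_sd)
  draw(masks$tumor, spec$tumor_gray_mean, spec$tumor_gray_sd)
  img <- gray_image(round_half_up(clip255(img)))
  list(image = img,
       truth = list(center_mask = masks$center, rim_mask = masks$rim,
                    tumor_mask = masks$tumor,
                    tumor_gray_mean = spec$tumor_gray_mean,
                    tumor_gray_sd = spec$tumor_gray_sd))
}

#' Specify a simulated lesion cohort
#'
#' Per-lesion echogenicity (`T_mean`) and heterogeneity (`T_SD`) are drawn
#' independently from per-group Gaussians. Defaults are the group summary
#' statistics observed for gastric mesenchymal tumors on standardized
#' 7.5 MHz EUS frames: GIST 82.8 +/- 22.5 / 83.5 +/- 14.4, leiomyoma
#' 39.8 +/- 18.9 / 54.3 +/- 21.7, schwannoma 47.0 +/- 12.0 / 58.3 +/- 17.5
#' (brightness units), with group sizes 50/6/9.
#'
#' @param n_gist,n_leiomyoma,n_schwannoma Lesions per histology group.
#' @param gist,leiomyoma,schwannoma Numeric vectors
#'   `c(t_mean_mu, t_mean_sd, t_sd_mu, t_sd_sd)`.
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_gist = 50, n_leiomyoma = 6, n_schwannoma = 9,
                        gist = c(82.8, 22.5, 83.5, 14.4),
                        leiomyoma = c(39.8, 18.9, 54.3, 21.7),
                        schwannoma = c(47.0, 12.0, 58.3, 17.5),
                        seed = 1L) {
  spec <- list(n = c(GIST = n_gist, leiomyoma = n_leiomyoma,
                     schwannoma = n_schwannoma),
               params = list(GIST = gist, leiomyoma = leiomyoma,
                             schwannoma = schwannoma),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  for (g in names(spec$n)) {
    if (is.na(spec$n[[g]]) || spec$n[[g]] < 0) {
      stop_validation("group size n for %s must be >= 0", g)
    }
    p <- spec$params[[g]]
    if (length(p) != 4) stop_validation("%s parameters must be length 4", g)
    if (p[2] < 0 || p[4] < 0) stop_validation("%s SD parameters must be >= 0", g)
  }
  spec
}

#' Simulate a lesion cohort
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per lesion: `id`, `group`, `t_mean`,
#'   `t_sd` (continuous brightness values, clipped to \[0, 255\]), and
#'   `truth_label` (`"GIST"` for the GIST group, `"non-GIST"` otherwise).
#' @examples
#' head(generate_cohort(cohort_spec(seed = 42)))
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  rows <- lapply(names(spec$n), function(g) {
    n <- spec$n[[g]]
    if (n == 0) return(NULL)
    p <- spec$params[[g]]
    data.frame(
      group = g,
      t_mean = clip255(stats::rnorm(n, p[1], p[2])),
      t_sd = clip255(stats::rnorm(n, p[3], p[4])),
      truth_label = if (g == "GIST") "GIST" else "non-GIST",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), t_mean = numeric(),
                      t_sd = numeric(), truth_label = character(),
                      stringsAsFactors = FALSE)
  }
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write / read a lesion cohort as CSV
#'
#' Columns: `id, group, t_mean, t_sd, truth_label`.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param path CSV file path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "t_mean", "t_sd", "truth_label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_validation("cohort CSV missing columns: %s", paste(missing, collapse = ", "))
  }
  df
}
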