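test_that("histogram smoothing matches the brute-force CDF table and is monotone", {
  const <- matrix(77L, 10, 10)
  expect_true(all(smooth_histogram(const) == 255))

  img <- matrix(c(rep(50L, 75), rep(200L, 25)), 10, 10)
  expect_identical(smooth_histogram(img), gray_image(cdf_equalize_oracle(img)))

  set.seed(11)
  rimg <- random_image()
  out <- smooth_histogram(rimg)
  expect_identical(out, gray_image(cdf_equalize_oracle(rimg)))
  ord <- order(as.vector(rimg))
  expect_true(all(diff(as.vector(out)[ord]) >= 0))
})

test_that("Sobel gradient is zero on constants, exact on a step edge, and mirror-symmetric", {
  expect_true(all(gradient_magnitude(matrix(42L, 8, 8)) == 0))

  h <- 60
  img <- cbind(matrix(0L, 5, 3), matrix(h, 5, 3))
  g <- gradient_magnitude(img)
  # hand-applied 3x3 Sobel at an interior pixel adjacent to the step:
  # gx = (h + 2h + h) - 0 = 4h, gy = 0
  expect_equal(g[3, 3], 4 * h)
  expect_equal(g[3, 4], 4 * h)
  expect_equal(g[3, 1], 0)

  set.seed(2)
  rimg <- random_image()
  expect_equal(gradient_magnitude(rimg[, ncol(rimg):1]),
               gradient_magnitude(rimg)[, ncol(rimg):1])
})

test_that("edge linking matches the brute-force closure of the <=th relation", {
  # constant positive map: every pixel is a seed, all linked
  expect_true(all(link_edges(matrix(5, 6, 6), th = 130)))

  # th = 0 where all 8-neighbor values differ: nothing beyond the seeds
  g <- matrix(seq(1, 100, length.out = 25), 5, 5)
  seeds_only <- link_edges(g, th = 0)
  expect_identical(seeds_only, edge_closure_oracle(g, th = 0))

  # two plateaus separated by a moat of zeros, difference > th
  g2 <- matrix(0, 16, 16)
  g2[2:6, 2:6] <- 250
  g2[10:15, 10:15] <- 40
  got <- link_edges(g2, th = 100)
  expect_identical(got, edge_closure_oracle(g2, th = 100))

  set.seed(8)
  for (i in 1:5) {
    g3 <- matrix(stats::runif(144, 0, 300), 12, 12)
    expect_identical(link_edges(g3, th = 60), edge_closure_oracle(g3, th = 60))
  }
  expect_error(link_edges(matrix(1, 4, 4), th = -1), "th")
})

test_that("Otsu threshold equals the exhaustive 256-candidate scan", {
  expect_true(is.na(otsu_threshold(matrix(100L, 6, 6))))
  expect_false(any(binarize(matrix(100L, 6, 6), "otsu")))

  two <- matrix(c(rep(40L, 60), rep(200L, 40)), 10, 10)
  t2 <- otsu_threshold(two)
  expect_gt(t2, 40)
  expect_lte(t2, 200)
  expect_equal(t2, otsu_exhaustive_oracle(as.vector(two)))

  set.seed(21)
  for (i in 1:20) {
    img <- random_image(16, 16)
    expect_equal(otsu_threshold(img), otsu_exhaustive_oracle(as.vector(img)))
  }
})

test_that("fixed binarization is inclusive at the threshold", {
  img <- matrix(c(99L, 100L, 101L, 0L), 2, 2)
  fg <- binarize(img, "fixed", fixed_threshold = 100)
  expect_identical(as.vector(fg), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(binarize(img, "fixed"), "fixed_threshold")
})

test_that("grassfire labeling agrees with the BFS flood-fill oracle", {
  empty <- label_components(matrix(FALSE, 5, 5))
  expect_equal(empty$n_components, 0)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(label_components(diag2, connectivity = 8)$n_components, 1)
  expect_equal(label_components(diag2, connectivity = 4)$n_components, 2)

  set.seed(33)
  for (i in 1:30) {
    b <- random_raster(20, 20, p = stats::runif(1, 0.2, 0.7))
    conn <- sample(c(4, 8), 1)
    got <- label_components(b, conn)
    ref <- bfs_label_oracle(b, conn)
    expect_equal(got$n_components, ref$n_components)
    expect_identical(got$labels > 0, ref$labels > 0)
    # same partition: label pairs over foreground form a bijection
    pairs <- unique(cbind(got$labels[b], ref$labels[b]))
    expect_equal(nrow(pairs), got$n_components)
    expect_equal(length(unique(pairs[, 1])), got$n_components)
    expect_equal(length(unique(pairs[, 2])), got$n_components)
  }
})

test_that("noise removal filters by area and circularity like the oracle", {
  b <- matrix(FALSE, 20, 20)
  b[2:11, 2:6] <- TRUE      # 50-pixel block
  b[15, 10:12] <- TRUE      # 3-pixel line
  lm <- label_components(b)
  expect_equal(lm$n_components, 2)
  kept <- remove_noise(lm, min_area = 10)
  expect_equal(kept$n_components, 1)
  expect_equal(sum(kept$labels > 0), 50)

  same <- remove_noise(lm, min_area = 0)
  expect_equal(same$n_components, lm$n_components)
  expect_identical(same$labels > 0, lm$labels > 0)

  set.seed(44)
  for (i in 1:10) {
    b <- random_raster(24, 24, 0.35)
    min_area <- sample(1:8, 1)
    got <- remove_noise(label_components(b), min_area = min_area)
    ref <- bfs_label_oracle(b)
    ref_areas <- tabulate(ref$labels[ref$labels > 0], nbins = ref$n_components)
    expect_setequal(tabulate(got$labels[got$labels > 0], nbins = got$n_components),
                    ref_areas[ref_areas >= min_area])
  }
})

test_that("a thin line fails the circularity filter while a disk passes", {
  b <- matrix(FALSE, 40, 40)
  rr <- row(b); cc <- col(b)
  b[(rr - 12)^2 + (cc - 12)^2 <= 64] <- TRUE  # disk r=8
  b[35, 3:38] <- TRUE                         # 36-px line
  lm <- label_components(b)
  expect_equal(lm$n_components, 2)
  kept <- remove_noise(lm, min_area = 10, min_circularity = 0.3)
  expect_equal(kept$n_components, 1)
})

test_that("scope anchors are recovered exactly from a noiseless phantom", {
  sp <- phantom_spec(speckle_sd = 0, tumor_gray_sd = 0, seed = 1)
  ph <- generate_phantom(sp)
  a <- extract_scope_anchors(ph$image)
  expect_equal(a$center_gray, sp$center_gray)
  expect_equal(a$rim_gray, sp$rim_gray)
  expect_gte(iou(a$center_mask, ph$truth$center_mask), 0.9)
  expect_gte(iou(a$rim_mask, ph$truth$rim_mask), 0.9)
  expect_true(a$center_gray < a$standard_gray & a$standard_gray < a$rim_gray)
})

test_that("anchor extraction fails cleanly on a uniform frame", {
  expect_error(extract_scope_anchors(matrix(128L, 64, 64)),
               "scope center not found")
})

test_that("the dark blob at the transducer position wins over a distractor", {
  sp <- phantom_spec(speckle_sd = 0, tumor_gray_sd = 0,
                     tumor_gray_mean = 10, seed = 1)  # distractor as dark as the center
  ph <- generate_phantom(sp)
  a <- extract_scope_anchors(ph$image)
  expect_gte(iou(a$center_mask, ph$truth$center_mask), 0.9)
  expect_lt(iou(a$center_mask, ph$truth$tumor_mask), 0.1)
})
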