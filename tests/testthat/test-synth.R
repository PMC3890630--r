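test_that("zero-noise phantoms reproduce programmed region brightness exactly", {
  sp <- phantom_spec(speckle_sd = 0, tumor_gray_sd = 0, seed = 1)
  ph <- generate_phantom(sp)
  expect_true(all(ph$image[ph$truth$center_mask] == sp$center_gray))
  expect_true(all(ph$image[ph$truth$rim_mask] == sp$rim_gray))
  expect_true(all(ph$image[ph$truth$tumor_mask] == sp$tumor_gray_mean))
  bg <- !(ph$truth$center_mask | ph$truth$rim_mask | ph$truth$tumor_mask)
  expect_true(all(ph$image[bg] == sp$background_gray_mean))
})

test_that("phantom generation is deterministic and in range", {
  sp <- phantom_spec(seed = 99)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_true(all(a$image >= 0 & a$image <= 255))
  m <- a$truth
  expect_false(any(m$center_mask & m$rim_mask))
  expect_false(any(m$center_mask & m$tumor_mask))
  expect_false(any(m$rim_mask & m$tumor_mask))
})

test_that("phantom tumor moments match programmed parameters for a large tumor", {
  sp <- phantom_spec(tumor_gray_mean = 80, tumor_gray_sd = 15,
                     tumor_axes = c(32, 24), seed = 42)
  ph <- generate_phantom(sp)
  v <- ph$image[ph$truth$tumor_mask]
  expect_gte(length(v), 2000)
  expect_lt(abs(mean(v) - 80), 2)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 15), 2)
})

test_that("phantom spec invariants are enforced with named errors", {
  expect_error(phantom_spec(center_radius = 20, rim_inner_radius = 18),
               "rim_inner_radius")
  expect_error(phantom_spec(center_gray = 300), "center_gray")
  expect_error(phantom_spec(tumor_gray_sd = -1), "tumor_gray_sd")
  expect_error(phantom_spec(tumor_center = c(100, 125)), "tumor")
})

test_that("cohort generation honors group sizes, labels, clipping and seed", {
  expect_equal(nrow(generate_cohort(cohort_spec(0, 0, 0))), 0)
  coh <- generate_cohort(cohort_spec(seed = 5))
  expect_equal(nrow(coh), 65)
  expect_equal(sum(coh$truth_label == "GIST"), 50)
  expect_setequal(unique(coh$group[coh$truth_label == "non-GIST"]),
                  c("leiomyoma", "schwannoma"))
  expect_true(all(coh$t_mean >= 0 & coh$t_mean <= 255))
  expect_true(all(coh$t_sd >= 0 & coh$t_sd <= 255))
  expect_identical(coh, generate_cohort(cohort_spec(seed = 5)))
  expect_error(cohort_spec(n_gist = -1), "GIST")
})

test_that("cohort sample moments converge to the group parameters", {
  coh <- generate_cohort(cohort_spec(n_gist = 10000, n_leiomyoma = 0,
                                     n_schwannoma = 0, seed = 7))
  expect_lt(abs(mean(coh$t_mean) - 82.8), 1)
  expect_lt(abs(mean(coh$t_sd) - 83.5), 1)
})

test_that("cohort CSV round-trips", {
  coh <- generate_cohort(cohort_spec(n_gist = 5, n_leiomyoma = 2,
                                     n_schwannoma = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$t_mean, coh$t_mean, tolerance = 1e-12)
  expect_equal(back$group, coh$group)
})
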