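# phantom builders for segmentation checks
two_level_image <- function(dims = c(4L, 20L, 20L), lo = 10, hi = 100) {
  img <- array(lo, dims)
  obj <- array(FALSE, dims)
  obj[2:3, 6:15, 6:15] <- TRUE
  img[obj] <- hi
  list(img = img, obj = obj)
}

test_that("perfectly separable images are segmented exactly by every method", {
  tl <- two_level_image()
  st <- marker_stack(tl$img, voxel_size = c(1, 1, 1))
  for (method in c("li", "otsu", "multi_otsu")) {
    rec <- segmentation_recipe(smooth_sigma_um = 0, method = method)
    expect_equal(segment_marker(st, rec), tl$obj, info = method)
  }
})

test_that("largest-component filtering keeps only the biggest object", {
  dims <- c(3L, 20L, 20L)
  img <- array(0, dims)
  img[2, 2:6, 2:11] <- 100     # 50 voxels
  img[1:3, 9:18, 8:18] <- 100  # larger block, disjoint from the first
  big <- array(FALSE, dims); big[1:3, 9:18, 8:18] <- TRUE
  st <- marker_stack(img, voxel_size = c(1, 1, 1))
  rec <- segmentation_recipe(0, "otsu", keep_largest_component = TRUE)
  expect_equal(segment_marker(st, rec), big)
})

test_that("connected components use 26-connectivity and size ordering", {
  m <- array(FALSE, c(2L, 4L, 4L))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # touch only diagonally
  lab <- label_components(m)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])  # one component under 26-conn
  m[1, 4, 4] <- TRUE                        # isolated voxel: second component
  lab2 <- label_components(m)
  expect_equal(sort(unique(as.vector(lab2))), 0:2)
  expect_equal(lab2[1, 1, 1], 1L)           # bigger component numbered first
  expect_equal(lab2[1, 4, 4], 2L)
  expect_true(all(largest_component(m) == (lab2 == 1L)))
})

test_that("the nuclear two-step recipe keeps spheres and rejects haze", {
  set.seed(19)
  dims <- c(6L, 24L, 24L)
  vox <- c(1, 0.5, 0.5)
  img <- array(0, dims)
  centers <- list(c(2, 6, 6), c(3, 16, 8), c(4, 10, 18))
  truth <- array(FALSE, dims)
  idx <- expand.grid(z = 1:dims[1], y = 1:dims[2], x = 1:dims[3])
  for (cc in centers) {
    d2 <- ((idx$z - cc[1]) * vox[1])^2 + ((idx$y - cc[2]) * vox[2])^2 +
      ((idx$x - cc[3]) * vox[3])^2
    truth[as.matrix(idx)[d2 <= 1.5^2, , drop = FALSE]] <- TRUE  # 1.5 um radius
  }
  img[truth] <- 200
  img <- img + array(abs(rnorm(prod(dims), 20, 8)), dims)  # dim haze
  st <- marker_stack(img, vox, "nuclear")
  mask <- segment_marker(st, segmentation_preset("nuclear_subtype"))
  # retained volume close to the true sphere volume, and mostly inside it
  expect_lt(abs(sum(mask) - sum(truth)) / sum(truth), 0.2)
  expect_gt(sum(mask & truth) / sum(mask), 0.8)
})

test_that("Otsu-family thresholds are invariant to affine intensity rescaling", {
  set.seed(4)
  dims <- c(3L, 12L, 12L)
  img <- array(c(rnorm(216, 20, 5), rnorm(216, 80, 10)), dims)
  st1 <- marker_stack(img, c(1, 1, 1))
  st2 <- marker_stack(3.7 * img + 11, c(1, 1, 1))
  for (method in c("otsu", "multi_otsu")) {
    rec <- segmentation_recipe(0, method)
    expect_equal(segment_marker(st1, rec), segment_marker(st2, rec),
                 info = method)
  }
})

test_that("empty or constant foregrounds warn instead of erroring", {
  st <- marker_stack(array(5, c(2, 4, 4)), c(1, 1, 1))
  expect_warning(mask <- segment_marker(st, segmentation_recipe(0, "li")),
                 "empty|constant")
  expect_false(any(mask))
})

test_that("named presets carry the documented smoothing scales and methods", {
  expect_equal(segmentation_preset("mb_cytosolic")$smooth_sigma_um, 2)
  expect_true(segmentation_preset("mb_cytosolic")$keep_largest_component)
  expect_equal(segmentation_preset("nuclear_subtype")$method, "two_step_li")
  expect_equal(segmentation_preset("nuclear_subtype")$smooth_sigma_um, 0.5)
  expect_equal(segmentation_preset("somata_mask")$smooth_sigma_um, 3)
  expect_equal(segmentation_preset("somata_mask")$method, "multi_otsu")
  expect_equal(segmentation_preset("calyx_mask")$smooth_sigma_um, 5)
})

test_that("smoothing converts sigma to voxels per axis", {
  dims <- c(5L, 21L, 21L)
  img <- array(0, dims); img[3, 11, 11] <- 1
  # anisotropic voxels: 2 um axial, 0.5 um lateral; sigma 1 um
  sm <- gaussian_smooth(img, 1, c(2, 0.5, 0.5))
  expect_equal(sum(sm), 1, tolerance = 1e-6)  # kernel is normalised
  # spread is wider (in voxels) along the finely sampled axes
  prof_z <- sm[, 11, 11] / max(sm)
  prof_x <- sm[3, 11, ] / max(sm)
  expect_gt(sum(prof_x > 0.1), sum(prof_z > 0.1))
})

test_that("histogram matching reproduces reference distributions", {
  set.seed(12)
  dims <- c(2L, 16L, 16L)
  vals <- c(rnorm(256, 30, 4), rnorm(256, 90, 8))
  img <- array(sample(vals), dims)
  st <- marker_stack(img, c(1, 1, 1))
  # matching an image to its own values is the identity (up to quantisation)
  self <- match_reference_histogram(st, as.numeric(img))
  expect_lt(max(abs(sort(as.numeric(self$intensity)) -
                    sort(as.numeric(img)))), 1e-8)
  # a linearly rescaled copy is mapped back onto the reference
  st2 <- marker_stack(2.5 * img + 7, c(1, 1, 1))
  back <- match_reference_histogram(st2, as.numeric(img))
  expect_lt(max(abs(sort(as.numeric(back$intensity)) -
                    sort(as.numeric(img)))), 1e-8)
  # two-Gaussian image matched to a shifted reference: means line up
  ref <- c(rnorm(4000, 50, 4), rnorm(4000, 120, 8))
  matched <- match_reference_histogram(st, ref)
  lowm <- mean(matched$intensity[img < 60])
  highm <- mean(matched$intensity[img >= 60])
  expect_lt(abs(lowm - 50) / 50, 0.05)
  expect_lt(abs(highm - 120) / 120, 0.05)
  # constant input warns and passes through
  stc <- marker_stack(array(1, c(1, 2, 2)), c(1, 1, 1))
  expect_warning(out <- match_reference_histogram(stc, ref), "constant")
  expect_identical(out$intensity, stc$intensity)
})
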