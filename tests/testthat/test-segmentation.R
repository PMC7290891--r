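make_vol <- function(arr, vs = 4) suv_volume(arr, vs)

test_that("liver reference applies 1.5*mean + 2*SD and matches voxel enumeration", {
  # uniform SUV 5 -> mean 5, SD 0, threshold 7.5
  vol <- make_vol(array(5, dim = c(16, 16, 16)))
  ref <- liver_reference(vol, c(32, 32, 32))
  expect_equal(ref$mean_suv, 5)
  expect_equal(ref$sd_suv, 0)
  expect_equal(ref$threshold_suv, 7.5)
  # known-mean/SD Gaussian voxels: match brute-force enumeration of the ROI
  set.seed(21)
  arr <- array(abs(rnorm(16^3, 5, 1)), dim = c(16, 16, 16))
  vol <- make_vol(arr)
  ref <- liver_reference(vol, c(30, 30, 30))
  oracle <- sphere_voxel_stats(arr, rep(4, 3), c(30, 30, 30), 15)
  expect_equal(ref$mean_suv, oracle$mean)
  expect_equal(ref$sd_suv, oracle$sd)
  expect_equal(ref$threshold_suv, 1.5 * oracle$mean + 2 * oracle$sd)
})

test_that("liver reference formula arithmetic: mean 5, SD 1 gives 9.5", {
  # two voxel values 4 and 6 repeated give mean 5; scale SD to exactly 1 by
  # checking the formula on the returned stats instead of engineering voxels
  set.seed(2)
  arr <- array(abs(rnorm(16^3, 5, 1)), dim = c(16, 16, 16))
  ref <- liver_reference(make_vol(arr), c(32, 32, 32))
  expect_equal(ref$threshold_suv, 1.5 * ref$mean_suv + 2 * ref$sd_suv)
  expect_gt(ref$threshold_suv, ref$mean_suv)
})

test_that("aortic reference applies 2*mean + 2*SD over the cylinder", {
  vol <- make_vol(array(2, dim = c(16, 16, 16)), vs = 2)
  ref <- aorta_reference(vol, c(16, 16, 16))
  expect_equal(ref$threshold_suv, 4.0)
  expect_equal(ref$region_kind, "aorta_cylinder")
  # mean 2, SD 0.5 -> 5.0 by the formula on measured stats
  set.seed(4)
  arr <- array(abs(rnorm(16^3, 2, 0.5)), dim = c(16, 16, 16))
  ref2 <- aorta_reference(make_vol(arr, vs = 2), c(16, 16, 16))
  expect_equal(ref2$threshold_suv, 2 * ref2$mean_suv + 2 * ref2$sd_suv)
  # brute-force cylinder voxel set
  d <- dim(arr); vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- (c(i, j, k) - 0.5) * 2
    if ((p[1] - 16)^2 + (p[2] - 16)^2 <= 25 && abs(p[3] - 16) <= 10)
      vals <- c(vals, arr[i, j, k])
  }
  expect_equal(ref2$mean_suv, mean(vals))
  expect_equal(ref2$sd_suv, sd(vals))
})

test_that("reference ROIs that exit the volume or are too small error", {
  vol <- make_vol(array(5, dim = c(16, 16, 16)))
  expect_error(liver_reference(vol, c(5, 32, 32)), "outside")
  expect_error(aorta_reference(vol, c(4, 32, 32)), "outside")
  tiny <- suv_volume(array(5, dim = c(40, 40, 40)), 0.1)
  expect_error(liver_reference(tiny, c(2, 2, 2), diameter_mm = 0.25),
               "voxels")
})

test_that("segmentation of a constructed cube is exact", {
  arr <- array(1, dim = c(16, 16, 16))
  arr[6:8, 6:8, 6:8] <- 10
  les <- segment_lesions(make_vol(arr), 9.5)
  expect_equal(nrow(les), 1)
  expect_equal(les$voxel_count, 27)
  expect_equal(les$volume_cm3, 1.728)
  expect_equal(les$suv_mean, 10)
  expect_equal(les$suv_max, 10)
  expect_equal(c(les$centroid_x_mm, les$centroid_y_mm, les$centroid_z_mm),
               rep((7 - 0.5) * 4, 3))
})

test_that("no supra-threshold voxel yields an empty lesion table", {
  les <- segment_lesions(make_vol(array(1, dim = c(8, 8, 8))), 5)
  expect_equal(nrow(les), 0)
  expect_error(hottest_lesion(les), "no measurable lesion")
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(31)
  for (rep in 1:4) {
    mask <- array(runif(18^3) < 0.18, dim = c(18, 18, 18))
    lab <- petburden:::label_components_26(mask)
    oracle <- flood_fill_label_26(mask)
    expect_true(same_partition(lab, oracle))
    expect_equal(sort(tabulate(lab[lab > 0])),
                 sort(tabulate(oracle[oracle > 0])))
  }
})

test_that("two disjoint phantom spheres give two lesions matching the oracle", {
  sp <- phantom_spec(grid_shape = c(28, 28, 28), voxel_size_mm = 4,
                     liver_center_mm = c(30, 30, 30), liver_radius_mm = 14,
                     liver_sd_suv = 0,
                     lesions = list(
                       lesion_spec(c(80, 80, 40), "sphere", 9, 12),
                       lesion_spec(c(80, 30, 90), "sphere", 6, 9)),
                     seed = 1)
  ph <- generate_phantom(sp)
  les <- segment_lesions(ph$volume, 8)
  expect_equal(nrow(les), 2)
  # ordered by descending SUVmax
  expect_equal(les$suv_max, c(12, 9))
  oracle <- flood_fill_label_26(ph$volume$data >= 8)
  expect_equal(sort(les$voxel_count), sort(tabulate(oracle[oracle > 0])))
  expect_equal(sort(les$voxel_count), sort(ph$ground_truth$voxel_count))
})

test_that("exclusion mask removes physiological uptake from the lesion set", {
  arr <- array(1, dim = c(16, 16, 16))
  arr[2:4, 2:4, 2:4] <- 10    # "salivary gland"
  arr[10:12, 10:12, 10:12] <- 10
  excl <- array(FALSE, dim = dim(arr))
  excl[2:4, 2:4, 2:4] <- TRUE
  les <- segment_lesions(make_vol(arr), 5, exclude = excl)
  expect_equal(nrow(les), 1)
  expect_equal(les$centroid_x_mm, (11 - 0.5) * 4)
})

test_that("volume conservation and threshold monotonicity hold", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = 4,
                     liver_center_mm = c(48, 48, 48), liver_radius_mm = 20,
                     lesions = list(lesion_spec(c(80, 20, 80), "sphere", 8, 12)),
                     psf_sigma_mm = 2, noise_sd = 0.1, seed = 9)
  vol <- generate_phantom(sp)$volume
  total <- function(thr) {
    les <- segment_lesions(vol, thr)
    c(vox = sum(les$voxel_count), cm3 = sum(les$volume_cm3))
  }
  for (thr in c(2, 5, 8)) {
    expect_equal(unname(total(thr)["vox"]), sum(vol$data >= thr))
  }
  vols <- vapply(seq(1, 11, by = 0.5), function(t) total(t)["cm3"], numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("min_voxels drops speck components", {
  arr <- array(1, dim = c(12, 12, 12))
  arr[2, 2, 2] <- 10
  arr[6:8, 6:8, 6:8] <- 10
  les <- segment_lesions(make_vol(arr), 5, min_voxels = 2)
  expect_equal(nrow(les), 1)
  expect_equal(les$voxel_count, 27)
})

test_that("hottest lesion is the SUVmax argmax with deterministic ties", {
  les <- data.frame(lesion_id = 1:3, voxel_count = c(5, 5, 5),
                    volume_cm3 = 1, suv_mean = 5, suv_max = c(8, 12, 9),
                    centroid_x_mm = 0, centroid_y_mm = 0, centroid_z_mm = 0)
  expect_equal(hottest_lesion(les)$suv_max, 12)
  les$suv_max <- c(12, 12, 9)
  expect_equal(hottest_lesion(les)$lesion_id, 1)
  # brute-force max over shuffled random lesions
  set.seed(12)
  big <- data.frame(lesion_id = 1:100, voxel_count = 1, volume_cm3 = 1,
                    suv_mean = 1, suv_max = runif(100, 2, 30),
                    centroid_x_mm = 0, centroid_y_mm = 0, centroid_z_mm = 0)
  big <- big[sample(100), ]
  expect_equal(hottest_lesion(big)$suv_max, max(big$suv_max))
})

test_that("noise-free phantom lesions are recovered with exact volumes", {
  # liver sphere must cover the whole 3 cm reference ROI (radius 15 mm)
  sp <- phantom_spec(grid_shape = c(28, 28, 28), voxel_size_mm = 4,
                     background_suv = 0.5,
                     liver_center_mm = c(30, 30, 30), liver_radius_mm = 16,
                     liver_mean_suv = 5, liver_sd_suv = 0.3,
                     lesions = list(
                       lesion_spec(c(84, 84, 40), "sphere", 10, 12),
                       lesion_spec(c(84, 28, 90), "box", c(6, 6, 6), 9)),
                     seed = 2)
  ph <- generate_phantom(sp)
  ref <- liver_reference(ph$volume, c(30, 30, 30))
  les <- segment_lesions(ph$volume, ref$threshold_suv)
  expect_equal(sort(les$voxel_count), sort(ph$ground_truth$voxel_count))
  expect_equal(sum(les$volume_cm3), sum(ph$ground_truth$volume_cm3))
})

test_that("blurred noisy phantom tumour volume is recovered within 15%", {
  sp <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_mm = 4,
                     background_suv = 0.5,
                     liver_center_mm = c(32, 32, 32), liver_radius_mm = 16,
                     liver_mean_suv = 5, liver_sd_suv = 0.3,
                     lesions = list(lesion_spec(c(96, 96, 60), "sphere", 12, 15)),
                     psf_sigma_mm = 2, noise_sd = 0.1, seed = 7)
  ph <- generate_phantom(sp)
  ref <- liver_reference(ph$volume, c(32, 32, 32))
  les <- segment_lesions(ph$volume, ref$threshold_suv, min_voxels = 3)
  tv <- sum(les$volume_cm3)
  truth <- sum(ph$ground_truth$volume_cm3)
  expect_lt(abs(tv - truth) / truth, 0.15)
})
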