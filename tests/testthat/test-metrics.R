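test_that("SUV formula is activity over dose-per-weight", {
  expect_equal(compute_suv(0.01, 370, 74000), 2.0)
  expect_equal(compute_suv(0, 370, 74000), 0)
  expect_equal(compute_suv(0.005, 296, 59200), 1.0)
  expect_error(compute_suv(0.01, 0, 74000), "dose")
  expect_error(compute_suv(0.01, 370, -1), "weight")
})

test_that("background threshold is mean + 2 SD of the reference region", {
  sp <- phantom_spec(grid_shape = c(40, 40, 40), tumor_radius_mm = 10,
                     suv_max_target = 8, background_sd = 0.25, seed = 2)
  ph <- generate_phantom(sp)
  bg <- role_mask(ph$lesions, "background")

  # constant background -> SD 0 -> threshold = the constant
  vol_const <- ph$volume
  vol_const$values[bg] <- 2.0
  expect_equal(background_threshold(vol_const, ph$lesions), 2.0)

  # three known voxels: 2 + 2 * sample SD of {1,2,3} = 4
  v3 <- c(1, 2, 3)
  idx <- which(bg)[1:3]
  vol3 <- ph$volume
  vol3$values[bg] <- 2               # make the rest irrelevant
  vol3$values[idx] <- v3
  lab3 <- ph$lesions$labels
  keep <- array(FALSE, dim(lab3)); keep[idx] <- TRUE
  bg_label <- as.integer(names(ph$lesions$role_map)[
    ph$lesions$role_map == "background"])
  lab3[bg & !keep] <- 0L
  les3 <- lesion_set(lab3, ph$lesions$role_map)
  expect_equal(background_threshold(vol3, les3), 2 + 2 * sd(v3))
  expect_equal(background_threshold(vol3, les3, sd_type = "population"),
               2 + 2 * sqrt(2 / 3))
})

test_that("Monte-Carlo background threshold approaches mean + 2 sigma", {
  set.seed(11)
  vals <- array(pmax(rnorm(21^3, 2.0, 0.25), 0), dim = c(21, 21, 21))
  vol <- suv_volume(vals, c(1, 1, 1))
  lab <- array(1L, dim = c(21, 21, 21)); lab[1, 1, 1] <- 2L
  # whole grid is the background region; a single voxel plays the primary
  les <- lesion_set(lab, c("2" = "primary", "1" = "background"))
  thr <- background_threshold(vol, les)
  expect_equal(thr, 2.5, tolerance = 0.02 / 2.5)
})

test_that("lesion metrics on a uniform sphere match the analytic volume", {
  sp <- phantom_spec(grid_shape = c(61, 61, 61), tumor_radius_mm = 20,
                     profile = "uniform", suv_max_target = 10, seed = 1)
  ph <- generate_phantom(sp)
  m <- lesion_metrics(ph$volume, role_mask(ph$lesions, "primary"), 2.5)
  expect_equal(m$mtv_cm3, 4 / 3 * pi * 8, tolerance = 0.02)
  expect_equal(m$suv_mean, 10)
  expect_equal(m$tlg, m$mtv_cm3 * 10)
  expect_equal(m$suv_max, 10)
})

test_that("threshold semantics: inclusive ties, supra-max empties the MTV", {
  vals <- array(1, dim = c(4, 4, 4))
  vals[1:2, 1, 1] <- c(5, 3)
  vol <- suv_volume(vals, c(10, 10, 10))   # 1 cm^3 voxels
  mask <- array(TRUE, dim = c(4, 4, 4))
  at3 <- lesion_metrics(vol, mask, 3)      # ties at the threshold belong in
  expect_equal(at3$mtv_cm3, 2)
  expect_equal(at3$suv_mean, 4)
  expect_equal(at3$tlg, 8)
  empty <- lesion_metrics(vol, mask, 6)
  expect_equal(empty$mtv_cm3, 0)
  expect_equal(empty$tlg, 0)
  expect_equal(empty$suv_mean, 0)
  expect_true(empty$empty_mtv)
})

test_that("raising the threshold never increases MTV or TLG", {
  sp <- phantom_spec(grid_shape = c(41, 41, 41), tumor_radius_mm = 15,
                     profile = "radial_linear", suv_max_target = 9,
                     noise_sd = 0.2, seed = 8)
  ph <- generate_phantom(sp)
  mask <- role_mask(ph$lesions, "primary")
  ms <- lapply(seq(1, 6, by = 0.5), function(th)
    lesion_metrics(ph$volume, mask, th))
  mtv <- vapply(ms, `[[`, 0, "mtv_cm3")
  tlg <- vapply(ms, `[[`, 0, "tlg")
  expect_true(all(diff(mtv) <= 0))
  expect_true(all(diff(tlg) <= 0))
})

test_that("metrics are invariant to axis permutation", {
  sp <- phantom_spec(grid_shape = c(30, 36, 42),
                     voxel_spacing_mm = c(1, 1.5, 2),
                     tumor_center_mm = c(15, 27, 42), tumor_radius_mm = 10,
                     profile = "radial_linear", suv_max_target = 9,
                     noise_sd = 0.1, seed = 4)
  ph <- generate_phantom(sp)
  mask <- role_mask(ph$lesions, "primary")
  m1 <- lesion_metrics(ph$volume, mask, 3)
  perm <- aperm(ph$volume$values, c(3, 1, 2))
  vol2 <- suv_volume(perm, ph$volume$spacing_mm[c(3, 1, 2)])
  m2 <- lesion_metrics(vol2, aperm(mask, c(3, 1, 2)), 3)
  expect_equal(m1$mtv_cm3, m2$mtv_cm3)
  expect_equal(m1$suv_mean, m2$suv_mean)
  expect_equal(m1$tlg, m2$tlg)
})

test_that("patient aggregation is exactly additive", {
  mk <- function(mtv, mean, smax) {
    structure(list(suv_max = smax, suv_mean = mean, mtv_cm3 = mtv,
                   tlg = mtv * mean, threshold_used = 2,
                   n_voxels = 1L, empty_mtv = FALSE),
              class = "lesion_metrics")
  }
  primary <- mk(10, 5, 12)
  # no nodes: nodal values zero, whole-body = primary
  p0 <- aggregate_patient(primary)
  expect_equal(p0$nodal_mtv_cm3, 0)
  expect_equal(p0$nodal_suvmax, 0)
  expect_equal(p0$wb_mtv_cm3, 10)
  nodes <- list(mk(2, 4, 4.0), mk(3, 4, 6.5))
  p <- aggregate_patient(primary, nodes)
  expect_equal(p$nodal_mtv_cm3, 5)
  expect_equal(p$wb_mtv_cm3, 15)
  expect_equal(p$nodal_suvmax, 6.5)
  expect_equal(p$wb_tlg, primary$tlg + 2 * 4 + 3 * 4)
})
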