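test_that("a brightness ramp along x maps to the first orientation bin", {
  # convention fixed by hand-evaluating the 3x3 Sobel kernel on a ramp:
  # interior Gx = 8, Gy = 0, so orientation 0 degrees (bin centered at 2.5)
  ramp <- matrix(rep(1:50, times = 50), nrow = 50, byrow = TRUE)
  f <- sobel_orientation_field(ramp)
  pf <- patch_osi(f)
  h <- pf$histogram[[1]]
  expect_equal(which.max(h), 1L)
  expect_equal(sum(h[-1]), 0)
  expect_equal(pf$osi, 1)
})

test_that("a constant image has zero gradient magnitude everywhere", {
  f <- sobel_orientation_field(matrix(128, 40, 40))
  expect_true(all(f$magnitude == 0))
  pf <- patch_osi(f)
  expect_equal(pf$osi, 0)
  expect_true(is.na(pf$mean_orientation_deg))
})

test_that("gratings recover their generated orientation within one histogram bin", {
  for (ang in c(0, 30, 45, 101, 160)) {
    pf <- patch_osi(sobel_orientation_field(grating_rgb(ang, size = 80)))
    err <- abs(crossadapt:::circ_diff_deg(pf$mean_orientation_deg, ang, 180))
    expect_lt(err, 5)
    expect_gt(pf$osi, 0.8)
    expect_equal(pf$n_histogram_peaks, 1L)
  }
})

test_that("rotating a grating shifts the mean orientation equivariantly", {
  base <- patch_osi(sobel_orientation_field(grating_rgb(20, size = 60)))
  for (phi in c(30, 60, 90, 120)) {
    rot <- patch_osi(sobel_orientation_field(grating_rgb(20 + phi, size = 60)))
    shift <- crossadapt:::circ_diff_deg(rot$mean_orientation_deg,
                                        base$mean_orientation_deg, 180)
    expect_lt(abs(crossadapt:::circ_diff_deg(shift, phi, 180)), 5)
  }
})

test_that("patch OSI is invariant to uniform brightness scaling", {
  img <- grating_rgb(70, size = 50)[, , 1]
  a <- patch_osi(sobel_orientation_field(img))
  b <- patch_osi(sobel_orientation_field(0.3 * img))
  expect_equal(a$osi, b$osi, tolerance = 1e-9)
})

test_that("two equal-mass orientations 90 degrees apart cancel under angle doubling", {
  half <- cbind(grating_rgb(0, size = 60)[, 1:30, 1],
                grating_rgb(90, size = 60)[, 1:30, 1])
  pf <- patch_osi(sobel_orientation_field(half))
  # antipodal cancellation: near-zero OSI despite strong local gradients
  expect_lt(pf$osi, 0.15)
})

test_that("isotropic white noise has low OSI", {
  set.seed(21)
  for (i in 1:3) {
    img <- matrix(runif(100 * 100, 0, 255), 100, 100)
    expect_lt(patch_osi(sobel_orientation_field(img))$osi, 0.1)
  }
})

test_that("patch classification separates gray, coloured and oriented patches", {
  expect_equal(classify_patch(uniform_rgb(128, 128, 128)), "neither")
  expect_equal(classify_patch(uniform_rgb(200, 40, 40)), "colored")
  expect_equal(classify_patch(grating_rgb(45)), "oriented")
  # near-black and near-white uniform patches fail criterion (a)
  expect_equal(classify_patch(uniform_rgb(10, 10, 40)), "neither")
  expect_equal(classify_patch(uniform_rgb(250, 230, 240)), "neither")
  expect_error(classify_patch(uniform_rgb(200, 40, 40, size = 2)),
               class = "crossadapt_size_error")
})

test_that("feature map covers only full windows on the stride grid", {
  img <- matrix(128, 50, 50)
  expect_equal(nrow(feature_map(img)), 1L)
  img2 <- matrix(128, 100, 100)
  expect_equal(nrow(feature_map(img2)), 36L)   # (floor((100-50)/10)+1)^2
  expect_error(feature_map(img2, stride = 0), class = "crossadapt_config_error")
  expect_error(feature_map(matrix(0, 20, 20)), class = "crossadapt_config_error")
})

test_that("windows fully inside generated patches recover the ground-truth label", {
  sc <- generate_scene(scene_config(image_size = c(220, 220), patch_size = 80,
                                    n_oriented_patches = 2, n_colored_patches = 2,
                                    seed = 31))
  fm <- feature_map(sc$image)
  w <- attr(fm, "window")
  hits <- 0; total <- 0
  for (i in seq_len(nrow(sc$patches))) {
    p <- sc$patches[i, ]
    # strict interior: a 1-px margin keeps the Sobel kernel off the patch
    # border, whose edge gradient would otherwise dominate uniform patches
    inside <- fm$row0 >= p$row0 + 1 & fm$row0 + w - 1 <= p$row0 + p$size - 2 &
      fm$col0 >= p$col0 + 1 & fm$col0 + w - 1 <= p$col0 + p$size - 2
    total <- total + sum(inside)
    hits <- hits + sum(fm$label[inside] == p$type)
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.95)
})

test_that("interior-window label recovery holds across seeds", {
  for (s in c(101, 202, 303)) {
    sc <- generate_scene(scene_config(image_size = c(200, 200), patch_size = 70,
                                      n_oriented_patches = 1,
                                      n_colored_patches = 1, seed = s))
    fm <- feature_map(sc$image)
    w <- attr(fm, "window")
    for (i in seq_len(nrow(sc$patches))) {
      p <- sc$patches[i, ]
      inside <- fm$row0 >= p$row0 + 1 & fm$row0 + w - 1 <= p$row0 + p$size - 2 &
        fm$col0 >= p$col0 + 1 & fm$col0 + w - 1 <= p$col0 + p$size - 2
      if (any(inside)) expect_true(all(fm$label[inside] == p$type))
    }
  }
})

test_that("an empty gray scene classifies as neither everywhere", {
  sc <- generate_scene(scene_config(image_size = c(100, 100),
                                    n_oriented_patches = 0,
                                    n_colored_patches = 0, seed = 1))
  fm <- feature_map(sc$image)
  expect_true(all(fm$label == "neither"))
})

test_that("overlapping patch requests fail with a placement error", {
  expect_error(generate_scene(scene_config(image_size = c(60, 60),
                                           patch_size = 50,
                                           n_oriented_patches = 3,
                                           n_colored_patches = 0, seed = 1)),
               class = "crossadapt_placement_error")
})
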