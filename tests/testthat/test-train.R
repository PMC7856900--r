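test_that("patch extraction reproduces the published tiling geometry", {
  img <- matrix(runif(200 * 200), 200, 200)
  p100 <- extract_patches(img, 100, 100)
  expect_length(p100$patches, 4)
  p50 <- extract_patches(img, 50, 50)
  expect_length(p50$patches, 16)
  expect_true(all(p50$origins %% 50 == 0))
  expect_error(extract_patches(img, 300), "larger than image")
})

test_that("extract/stitch is the identity on exact tilings", {
  img <- matrix(runif(120 * 80), 120, 80)
  ex <- extract_patches(img, 40, 40)
  back <- stitch_patches(ex$patches, ex$origins, dim(img), scale = 1)
  expect_equal(back, img)
})

test_that("remainder tiles shift inward so coverage is complete", {
  img <- matrix(runif(37 * 29), 37, 29)
  ex <- extract_patches(img, 16, 16)
  back <- stitch_patches(ex$patches, ex$origins, dim(img), scale = 1)
  expect_equal(back, img) # overlap-averaged duplicates agree with source
  expect_true(all(ex$origins[, 1] + 16 <= 37))
  expect_true(all(ex$origins[, 2] + 16 <= 29))
})

test_that("overlapping patches are averaged", {
  p <- list(matrix(0, 4, 4), matrix(1, 4, 4))
  origins <- rbind(c(0, 0), c(0, 2))
  out <- stitch_patches(p, origins, c(4, 6), scale = 1)
  expect_true(all(out[, 1:2] == 0))
  expect_true(all(out[, 3:4] == 0.5))
  expect_true(all(out[, 5:6] == 1))
  expect_error(stitch_patches(p, rbind(c(0, 0), c(0, 8)), c(4, 6), 1),
               "beyond out_shape")
  expect_error(stitch_patches(p[1], origins[1, , drop = FALSE], c(8, 8), 1),
               "uncovered")
})

test_that("scaled stitching places low-resolution origins at scale x coordinates", {
  # oracle: direct coordinate arithmetic. LR image 20 x 20, patch 5,
  # scale 4: 16 HR patches of 20 x 20 -> 80 x 80 output; HR patch (a, b)
  # lands at rows 20*a + 1..20, cols 20*b + 1..20.
  lr <- matrix(seq_len(400), 20, 20)
  ex <- extract_patches(lr, 5, 5)
  hr_patches <- lapply(ex$patches, function(p) upsample_nearest(p, 4))
  out <- stitch_patches(hr_patches, ex$origins, c(80, 80), scale = 4)
  oracle <- upsample_nearest(lr, 4)
  expect_equal(out, oracle)
  expect_identical(dim(out), c(80L, 80L))
})

test_that("aligned patch sets pair all five roles by origin", {
  scenes <- lapply(1:2, function(k) make_test_scene(seed = k,
                                                    field = c(64, 64)))
  spec <- degradation_spec(0.5, 2L, 0.02, seed = 5)
  ps <- make_patch_set(scenes, spec, patch_lr = 16)
  n <- length(ps$input1)
  expect_identical(lengths(list(ps$input2, ps$gt1, ps$gt2, ps$gt3)),
                   rep(n, 4), ignore_attr = TRUE)
  expect_identical(dim(ps$input1[[1]]), c(16L, 16L))
  expect_identical(dim(ps$gt1[[1]]), c(32L, 32L))
  # the HR ground-truth patch is the scene content at the scaled origin
  o <- ps$origins[1, ]
  expect_equal(ps$gt1[[1]],
               scenes[[1]]$gt532[o[1] * 2 + 1:32, o[2] * 2 + 1:32])
})

test_that("training is deterministic, finite, and records its loss history", {
  scenes <- lapply(1:2, function(k) make_test_scene(seed = k,
                                                    field = c(48, 48)))
  spec <- degradation_spec(0.5, 2L, 0.02, seed = 5)
  ps <- make_patch_set(scenes, spec, patch_lr = 16)
  p0 <- mtrdn_params(scale = 2L, D = 1L, C = 1L, G = 2L, G0 = 4L, seed = 1)
  st1 <- train_model(ps, p0, steps = 1, batch = 1, seed = 3)
  expect_identical(nrow(st1$loss_history), 1L)
  expect_true(is.finite(st1$loss_history$loss))

  st3a <- train_model(ps, p0, steps = 3, batch = 2, seed = 3)
  st3b <- train_model(ps, p0, steps = 3, batch = 2, seed = 3)
  expect_identical(st3a$loss_history, st3b$loss_history)
  expect_error(train_model(ps, mtrdn_params(scale = 4L, D = 1L, C = 1L,
                                            G = 2L, G0 = 4L),
                           steps = 1),
               "scale")
})

test_that("whole-image reconstruction equals a single forward pass", {
  p <- mtrdn_params(scale = 2L, D = 1L, C = 2L, G = 3L, G0 = 4L, seed = 4)
  in1 <- matrix(runif(24 * 24), 24, 24)
  in2 <- matrix(runif(24 * 24), 24, 24)
  rc <- reconstruct(p, in1, in2) # patch defaults to the whole image
  fw <- mtrdn_forward(p, in1, in2)
  expect_equal(rc$recon1, fw$output1)
  expect_equal(rc$recon3, fw$output3)
  expect_identical(dim(rc$recon3), c(48L, 48L))

  # overlapped stitching differs from tiled only by bounded seam error
  rc_tile <- reconstruct(p, in1, in2, patch = 12, stride = 12)
  rc_lap <- reconstruct(p, in1, in2, patch = 12, stride = 6)
  seam <- max(abs(rc_tile$recon3 - rc_lap$recon3))
  expect_true(is.finite(seam))
})

test_that("nearest-neighbor upsampling replicates pixels in s x s blocks", {
  m <- matrix(1:4, 2, 2)
  up <- upsample_nearest(m, 2)
  expect_identical(dim(up), c(4L, 4L))
  expect_true(all(up[1:2, 1:2] == 1))
  expect_true(all(up[3:4, 3:4] == 4))
})
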