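test_that("vessel tree generation handles the vacuous case and is deterministic", {
  empty <- generate_vessel_tree(seed = 1, n_roots = 0)
  expect_length(empty$segments, 0)

  a <- generate_vessel_tree(seed = 11, n_roots = 3, max_depth = 4)
  b <- generate_vessel_tree(seed = 11, n_roots = 3, max_depth = 4)
  expect_identical(a, b)

  c <- generate_vessel_tree(seed = 12, n_roots = 3, max_depth = 4)
  expect_false(identical(a$segments, c$segments))
})

test_that("tree segments satisfy the geometric invariants", {
  for (seed in 1:5) {
    tr <- generate_vessel_tree(seed = seed, n_roots = 4, max_depth = 5,
                               field_size = c(100, 120))
    for (seg in tr$segments) {
      expect_true(all(seg$end >= 1) && all(seg$end <= c(100, 120)))
      expect_gt(seg$radius, 0)
      expect_true(seg$so2 >= 0 && seg$so2 <= 1)
      expect_gte(seg$depth, 1)
    }
  }
})

test_that("segment count matches an independent replay of the branching recursion", {
  # independent oracle: replay the documented recursion, counting segments
  # and consuming the RNG stream in the documented order
  oracle_count <- function(seed, n_roots, max_depth, branch_prob) {
    set.seed(seed)
    count <- 0L
    grow <- function(depth) {
      count <<- count + 1L
      if (depth >= max_depth) return(invisible())
      for (side in 1:2) {
        if (runif(1) < branch_prob) {
          runif(3) # angle offset, length factor, radius factor
          grow(depth + 1L)
        }
      }
    }
    for (r in seq_len(n_roots)) {
      runif(6) # start (2), angle, length, radius, so2
      grow(1L)
    }
    count
  }
  for (seed in c(1, 9, 23)) {
    tr <- generate_vessel_tree(seed = seed, n_roots = 3, max_depth = 4,
                               branch_prob = 0.7)
    expect_identical(length(tr$segments),
                     as.integer(oracle_count(seed, 3, 4, 0.7)))
  }
})

test_that("tree generation rejects invalid parameters", {
  expect_error(generate_vessel_tree(1, field_size = c(8, 8)), "field_size")
  expect_error(generate_vessel_tree(1, radius_range = c(-1, 2)), "radius")
})

test_that("rasterization of an empty tree yields all-zero channels", {
  tr <- generate_vessel_tree(seed = 1, n_roots = 0, field_size = c(32, 32))
  sc <- rasterize_scene(tr, background_level = 0.1)
  expect_true(all(sc$gt532 == 0))
  expect_true(all(sc$gt560 == 0))
  expect_false(any(sc$vessel_mask))
})

test_that("rendered scenes are normalized and share vessel support", {
  sc <- make_test_scene(seed = 5, n_roots = 2, background_level = 0.02)
  expect_equal(max(sc$gt532, sc$gt560), 1)
  expect_equal(min(sc$gt532, sc$gt560), 0)
  expect_true(all(sc$gt532 >= 0 & sc$gt532 <= 1))
  expect_true(all(sc$gt560 >= 0 & sc$gt560 <= 1))
  # channel coupling: both channels rendered from the same support
  expect_true(any(sc$vessel_mask))
  expect_true(all(is.na(sc$so2_true) == !sc$vessel_mask))
})

test_that("centerline channel ratio equals the extinction ratio for so2 = 1", {
  # single horizontal fully oxygenated segment, no background
  tree <- structure(list(
    segments = list(list(start = c(24, 8), end = c(24, 40), radius = 2,
                         so2 = 1, depth = 1L)),
    field_size = c(48L, 48L)), class = "VesselTree")
  ext <- default_extinction_table()
  sc <- rasterize_scene(tree, extinction = ext, background_level = 0)
  # midpoint of the centerline, far from endpoints and borders
  r <- 24; cols <- 20:28
  ratio <- sc$gt532[r, cols] / sc$gt560[r, cols]
  expect_equal(ratio, rep(ext["532", "HbO2"] / ext["560", "HbO2"],
                          length(cols)), tolerance = 1e-10)
})

test_that("extinction table validation catches singular and non-positive tables", {
  expect_error(extinction_table(matrix(c(1, 2, 2, 4), 2)), "singular")
  expect_error(extinction_table(matrix(c(1, -1, 2, 3), 2)), "positive")
})

test_that("scene splitting is a disjoint exhaustive deterministic partition", {
  scenes <- lapply(1:10, function(k) list(id = k))
  sp <- split_scenes(scenes, 0.8, seed = 2)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  ids <- c(sapply(sp$train, `[[`, "id"), sapply(sp$test, `[[`, "id"))
  expect_setequal(ids, 1:10)
  sp2 <- split_scenes(scenes, 0.8, seed = 2)
  expect_identical(sp, sp2)
  expect_error(split_scenes(scenes[1], 0.8, 1), "at least 2")
  expect_error(split_scenes(scenes, 1.2, 1), "between 0 and 1")
})

test_that("scene TIFF round trip preserves images and mask", {
  sc <- make_test_scene(seed = 7, field = c(48, 48))
  path <- tempfile(fileext = ".tif")
  write_scene(sc, path, params = list(seed = 7))
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_scene(path)
  expect_equal(back$gt532, sc$gt532, tolerance = 1e-6)
  expect_equal(back$gt560, sc$gt560, tolerance = 1e-6)
  expect_identical(back$vessel_mask, sc$vessel_mask)
  keep <- sc$vessel_mask
  expect_equal(back$so2_true[keep], sc$so2_true[keep], tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})
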