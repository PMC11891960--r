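test_that("stack write/read round-trips are bit-identical", {
  set.seed(11)
  v <- voxel_volume(array(sample(0:1, 20^3, TRUE), c(20, 20, 20)), 150)

  tif <- tempfile(fileext = ".tif")
  write_stack(v, tif)
  v2 <- read_stack(tif)
  expect_identical(v2$data, v$data)
  expect_equal(v2$spacing_nm, c(150, 150, 150))

  mha <- tempfile(fileext = ".mha")
  write_stack(v, mha)
  v3 <- read_stack(mha)
  expect_identical(v3$data, v$data)

  # TIFF shape convention: 10 pages of 32 x 16 -> (z=10, y=32, x=16)
  w <- voxel_volume(array(sample(0:255, 10 * 32 * 16, TRUE),
                          c(10, 32, 16)), 100)
  tif2 <- tempfile(fileext = ".tif")
  write_stack(w, tif2)
  w2 <- read_stack(tif2)
  expect_equal(dim(w2$data), c(10L, 32L, 16L))
  expect_identical(w2$data, w$data)

  # MetaImage preserves anisotropic spacing
  a <- voxel_volume(array(runif(6 * 5 * 4), c(6, 5, 4)), c(80, 40, 40))
  mhd <- tempfile(fileext = ".mhd")
  write_stack(a, mhd)
  a2 <- read_stack(mhd)
  expect_equal(a2$spacing_nm, c(80, 40, 40))
  expect_equal(a2$data, a$data)

  # spacing required when no sidecar exists
  file.remove(paste0(tif, ".json"))
  expect_error(read_stack(tif), "spacing")
  expect_equal(read_stack(tif, spacing_nm = 99)$spacing_nm, rep(99, 3))
})

test_that("the TIFF codec interoperates with an external reader/writer", {
  # the image ships python + tifffile; write with our codec, read with
  # tifffile, and vice versa
  set.seed(5)
  v <- voxel_volume(array(sample(0:1, 4 * 9 * 7, TRUE), c(4, 9, 7)), 150)
  ours <- tempfile(fileext = ".tif")
  write_stack(v, ours)
  out <- system2("python",
                 c("-c", shQuote(paste0(
                   "import tifffile; a = tifffile.imread('", ours,
                   "'); print(a.shape); print(int(a.sum()))"))),
                 stdout = TRUE)
  expect_equal(out[1], "(4, 9, 7)")
  expect_equal(as.integer(out[2]), sum(v$data))

  theirs <- tempfile(fileext = ".tif")
  system2("python",
          c("-c", shQuote(paste0(
            "import tifffile, numpy as np; ",
            "rng = np.random.default_rng(3); ",
            "a = (rng.random((5, 8, 12)) > 0.5).astype('uint8'); ",
            "tifffile.imwrite('", theirs, "', a); print(int(a.sum()))"))),
          stdout = TRUE) -> pysum
  w <- read_stack(theirs, spacing_nm = 150)
  expect_equal(dim(w$data), c(5L, 8L, 12L))
  expect_equal(sum(w$data), as.integer(pysum))
})

test_that("resampling shapes and identities follow the extent rule", {
  expect_equal(resampled_dims(c(7500, 100, 100), c(80, 40, 40), 150),
               c(4000L, 26L, 26L))

  # already isotropic at the target: identity
  v <- voxel_volume(array(sample(0:1, 6^3, TRUE), c(6, 6, 6)), 150)
  expect_identical(resample_isotropic(v, 150, "nearest"), v)

  # constant volume stays constant under linear resampling
  cv <- voxel_volume(array(7, c(6, 6, 6)), 100)
  r <- resample_isotropic(cv, 40, "linear")
  expect_true(all(abs(r$data - 7) < 1e-9))
  expect_equal(dim(r$data), c(15L, 15L, 15L))
  expect_equal(r$spacing_nm, rep(40, 3))

  # binary + linear is rejected unless thresholded
  expect_error(resample_isotropic(v, 100, "linear"), "binary")
  rt <- resample_isotropic(v, 100, "linear", threshold = TRUE)
  expect_true(is_binary_volume(rt))
  rn <- resample_isotropic(v, 100, "nearest")
  expect_true(is_binary_volume(rn))
  expect_equal(dim(rn$data), c(9L, 9L, 9L))
})

test_that("fill_holes fills enclosed cavities only", {
  cube <- array(0L, c(11, 11, 11))
  cube[2:10, 2:10, 2:10] <- 1L
  solid <- cube
  cube[5:7, 5:7, 5:7] <- 0L
  v <- voxel_volume(cube, 150)
  f <- fill_holes(v)
  expect_equal(sum(f$data != cube), 27L)
  expect_identical(f$data, solid)

  # background channel reaching a face is not filled
  open_cube <- solid
  open_cube[6, 6, 1:6] <- 0L
  vo <- voxel_volume(open_cube, 150)
  expect_identical(fill_holes(vo)$data, open_cube)

  # idempotence and foreground monotonicity
  expect_identical(fill_holes(f)$data, f$data)
  expect_true(all(f$data[v$data == 1] == 1))
})

test_that("per-slice hole filling closes z-through tunnels", {
  tube <- array(0L, c(6, 9, 9))
  tube[, 2:8, 2:8] <- 1L
  tube[, 4:6, 4:6] <- 0L  # z-through tunnel: open in 3D, enclosed per slice
  v <- voxel_volume(tube, 150)
  expect_identical(fill_holes(v, "full_3d")$data, tube)
  f2 <- fill_holes(v, "per_slice_2d")
  for (z in 1:6)
    expect_identical(f2$data[z, , ], oracle_fill_2d(tube[z, , ]))
  expect_true(all(f2$data[, 4:6, 4:6] == 1))
})

test_that("largest_component keeps one deterministic component", {
  a <- array(0L, c(10, 10, 10))
  a[2:5, 2:5, 2:5] <- 1L           # 64 voxels
  a[8, 8, 8] <- 1L                 # 1 voxel
  v <- voxel_volume(a, 150)
  lc <- largest_component(v)
  expect_equal(sum(lc$data), 64L)
  expect_equal(lc$data[8, 8, 8], 0L)
  # idempotent, never adds foreground
  expect_identical(largest_component(lc)$data, lc$data)
  expect_true(all(lc$data[a == 0] == 0))

  # single component: identity
  b <- array(0L, c(5, 5, 5)); b[2:3, 2:3, 2:3] <- 1L
  vb <- voxel_volume(b, 150)
  expect_identical(largest_component(vb)$data, b)

  # equal-size tie: the component with the smaller (z,y,x) voxel wins
  c0 <- array(0L, c(9, 9, 9))
  c0[7:8, 7:8, 7:8] <- 1L
  c0[2:3, 2:3, 2:3] <- 1L
  vc <- voxel_volume(c0, 150)
  lc2 <- largest_component(vc)
  expect_equal(lc2$data[2, 2, 2], 1L)
  expect_equal(lc2$data[7, 7, 7], 0L)
  expect_identical(largest_component(vc)$data, lc2$data)  # deterministic

  expect_error(largest_component(voxel_volume(array(0L, c(3, 3, 3)), 150)),
               "no foreground")
})

test_that("subregion extraction records origin and physical volume", {
  set.seed(2)
  v <- voxel_volume(array(sample(0:1, 8000, TRUE), c(20, 20, 20)), 150)
  s <- extract_subregion(v, c(2, 3, 4), c(10, 10, 10))
  expect_equal(dim(s$data), c(10L, 10L, 10L))
  expect_equal(s$origin_vx, c(2L, 3L, 4L))
  expect_identical(s$data[1, 1, 1], v$data[3, 4, 5])

  # full-volume extraction is the identity
  s2 <- extract_subregion(v, c(0, 0, 0), dim(v$data))
  expect_identical(s2$data, v$data)

  expect_error(extract_subregion(v, c(15, 0, 0), c(10, 10, 10)), "exceeds")
  expect_error(extract_subregion(v, c(25, 0, 0), c(1, 1, 1)), "exceeds")

  # reference-scale volume: 1000^3 vx at 150 nm = 3.375e-3 mm^3
  expect_equal(volume_mm3(c(1000, 1000, 1000), 150), 3.375e-3)
  expect_equal(volume_mm3(s), (10 * 150)^3 / 1e18)
})
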