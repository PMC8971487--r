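test_that("MAT round trip is bit-exact for arrays of any rank", {
  path <- withr::local_tempfile(fileext = ".mat")
  a3 <- array(as.numeric(1:12), c(2, 2, 3))
  vars <- list(stack = a3, vec = c(3.5, -1e-9, pi),
               img = matrix(rnorm(20), 4, 5))
  write_mat(vars, path)
  back <- read_mat(path)
  expect_identical(back$stack, a3)
  expect_identical(back$img, vars$img)
  expect_identical(as.numeric(back$vec), vars$vec)
})

test_that("compressed (v7-style) variables round trip identically", {
  path <- withr::local_tempfile(fileext = ".mat")
  set.seed(1)
  a <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  write_mat(list(m = a), path, compress = TRUE)
  expect_identical(read_mat(path)$m, a)
})

test_that("the largest 3-D variable is selected, with explicit override", {
  path <- withr::local_tempfile(fileext = ".mat")
  big <- array(rnorm(64 * 64 * 100), c(64, 64, 100))
  small <- array(1, c(4, 4, 4))
  write_mat(list(tiny = small, cmos = big), path)
  mv <- load_mat_movie(path, 500, 320)
  expect_equal(dim(mv$data), c(100, 64, 64))   # frame, row, col
  mv2 <- load_mat_movie(path, 500, 320, var = "tiny")
  expect_equal(dim(mv2$data), c(4, 4, 4))
  expect_error(load_mat_movie(path, 500, 320, var = "nope"), "not found")
})

test_that("a container without 3-D numerics fails naming the variables", {
  path <- withr::local_tempfile(fileext = ".mat")
  write_mat(list(alpha = matrix(1, 2, 2), beta = 1:3), path)
  expect_error(load_mat_movie(path, 500, 320), "alpha")
})

test_that("movie save/load preserves data and dim_order is an involution", {
  m <- fluor_movie(array(rnorm(5 * 3 * 4), c(5, 3, 4)), 1000, 156,
                   polarity = "inverted_voltage")
  p1 <- withr::local_tempfile(fileext = ".mat")
  save_mat_movie(m, p1, dim_order = "row_col_frame")
  b1 <- load_mat_movie(p1, 1000, 156, dim_order = "row_col_frame")
  expect_identical(b1$data, m$data)
  expect_identical(b1$polarity, "inverted_voltage")
  # on disk the stack is (row, col, frame); loading frame-major instead
  # returns the on-disk layout untouched
  b2 <- load_mat_movie(p1, 1000, 156, dim_order = "frame_row_col")
  expect_identical(b2$data, aperm(m$data, c(2, 3, 1)))
  p2 <- withr::local_tempfile(fileext = ".mat")
  save_mat_movie(b1, p2, dim_order = "frame_row_col")
  b3 <- load_mat_movie(p2, 1000, 156, dim_order = "frame_row_col")
  expect_identical(b3$data, m$data)
})

test_that("v7.3 (HDF5) containers are read through the python fallback", {
  path <- withr::local_tempfile(fileext = ".mat")
  py <- sprintf(paste0(
    "import numpy as np, h5py\n",
    "a = np.arange(24.0).reshape(2, 3, 4)\n",     # MATLAB dims (4,3,2)
    "with h5py.File(%s, 'w', userblock_size=512) as f:\n",
    "    f['stack'] = a\n",
    "with open(%s, 'r+b') as f:\n",
    "    hdr = b' ' * 124 + bytes([0x00, 0x02]) + b'IM'\n",
    "    f.write(hdr)\n"), shQuote(path), shQuote(path))
  res <- system2("python", "-", input = py, stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  expect_true(omapr:::is_mat73(path))
  vars <- read_mat73(path)
  expect_equal(dim(vars$stack), c(4, 3, 2))
  # h5py wrote C-order; MATLAB order is the reverse: element [1,1,2] is
  # a[1,0,0] = 12
  expect_equal(vars$stack[1, 1, 2], 12)
  mv <- load_mat_movie(path, 1000, 156, dim_order = "row_col_frame")
  expect_equal(dim(mv$data), c(2, 4, 3))
})

test_that("settings files parse, type and report unknown keys", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# dataset settings", "tophat_ms = 200",
               "speed_caps: 1,150", "activation_mode = max_dvdt", ""), f)
  s <- load_settings(f)
  expect_identical(s$overrides$tophat_ms, 200)
  expect_identical(s$overrides$speed_caps, c(1, 150))
  expect_identical(s$overrides$activation_mode, "max_dvdt")
  expect_length(s$unknown, 0)

  writeLines(character(), f)
  expect_identical(load_settings(f)$overrides, list())

  writeLines("frobnicate = 3", f)
  expect_warning(s <- load_settings(f), "frobnicate")
  expect_identical(s$overrides, list())
  expect_identical(s$unknown, "frobnicate")

  writeLines(c("tophat_ms = 100", "not a settings line"), f)
  expect_error(load_settings(f), ":2:")
})

test_that("scalar map CSV is row-major with NaN and round-trips exactly", {
  m <- scalar_map(matrix(c(1, 3, 2, NA), 2, 2),
                  tissue_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)),
                  kind = "apd_ms")
  f <- withr::local_tempfile(fileext = ".csv")
  write_scalar_map(m, f, image = FALSE)
  expect_identical(readLines(f), c("1,2", "3,NaN"))

  set.seed(42)
  v <- matrix(rnorm(30), 5, 6)
  mask <- matrix(runif(30) > 0.3, 5, 6)
  mask[1, 1] <- TRUE
  m2 <- scalar_map(v, tissue_mask(mask), kind = "df_hz")
  write_scalar_map(m2, f, image = FALSE)
  back <- read_scalar_map(f, kind = "df_hz")
  expect_identical(back$values[mask], m2$values[mask])
  expect_true(all(is.na(back$values[!mask])))
})

test_that("an all-undefined map writes a CSV of NaNs", {
  mask <- tissue_mask(matrix(c(TRUE, rep(FALSE, 3)), 2, 2))
  m <- scalar_map(matrix(NA_real_, 2, 2), mask, kind = "ows")
  f <- withr::local_tempfile(fileext = ".csv")
  write_scalar_map(m, f, image = FALSE)
  expect_identical(readLines(f), c("NaN,NaN", "NaN,NaN"))
})

test_that("map rendering writes a PNG alongside the CSV", {
  m <- scalar_map(matrix(runif(16), 4, 4),
                  tissue_mask(matrix(TRUE, 4, 4)), kind = "apd_ms")
  f <- withr::local_tempfile(fileext = ".csv")
  write_scalar_map(m, f, image = TRUE)
  png <- paste0(tools::file_path_sans_ext(f), ".png")
  expect_true(file.exists(png) && file.size(png) > 0)
})
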