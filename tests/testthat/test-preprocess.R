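make_movie <- function(M, nr, nc, rate = 1000, px = 156,
                       polarity = "upright") {
  fluor_movie(array(M, c(nrow(M), nr, nc)), rate, px, polarity = polarity)
}

test_that("Gaussian filter preserves constants and matches the sampled
           kernel on impulses", {
  m <- make_movie(matrix(7, 4, 25), 5, 5)
  out <- gaussian_spatial_filter(m)
  expect_equal(out$data, m$data)

  # interior impulse reproduces the normalised kernel patch
  fr <- matrix(0, 7, 7); fr[4, 4] <- 1
  m <- fluor_movie(array(rep(fr, each = 1), c(1, 7, 7)), 1000, 156)
  out <- gaussian_spatial_filter(m, size = 3, sigma = 1.5)
  k <- brute_gauss_kernel(3, 1.5)
  expect_equal(out$data[1, 3:5, 3:5], k, tolerance = 1e-12)
  expect_equal(k[2, 2], 0.1478, tolerance = 1e-3)

  # corner impulse: per-pixel renormalisation over the in-image weights
  fr <- matrix(0, 5, 5); fr[1, 1] <- 1
  m <- fluor_movie(array(fr, c(1, 5, 5)), 1000, 156)
  out <- gaussian_spatial_filter(m, size = 3, sigma = 1.5)
  expect_equal(out$data[1, , ], brute_gauss_frame(fr, 3, 1.5),
               tolerance = 1e-12)
  # at the corner itself: centre weight over the four nearest weights
  expect_equal(out$data[1, 1, 1], k[2, 2] / sum(k[2:3, 2:3]),
               tolerance = 1e-12)

  # a random masked frame matches the enumeration oracle everywhere
  set.seed(31)
  fr2 <- matrix(rnorm(81), 9, 9)
  msk <- matrix(runif(81) > 0.25, 9, 9); msk[5, 5] <- TRUE
  m2 <- fluor_movie(array(fr2, c(1, 9, 9)), 1000, 156)
  o2 <- gaussian_spatial_filter(m2, mask = tissue_mask(msk))
  expect_equal(o2$data[1, , ][msk], brute_gauss_frame(fr2, 3, 1.5, msk)[msk],
               tolerance = 1e-12)
})

test_that("Gaussian filter never bleeds intensity across the mask", {
  set.seed(7)
  base <- matrix(rnorm(100, 10), 10, 10)
  poisoned <- base
  poisoned[, 6:10] <- 1e6
  mask <- tissue_mask(cbind(matrix(TRUE, 10, 5), matrix(FALSE, 10, 5)))
  m1 <- fluor_movie(array(base, c(1, 10, 10)), 1000, 156)
  m2 <- fluor_movie(array(poisoned, c(1, 10, 10)), 1000, 156)
  o1 <- gaussian_spatial_filter(m1, mask = mask)
  o2 <- gaussian_spatial_filter(m2, mask = mask)
  expect_equal(o1$data[1, , 1:5], o2$data[1, , 1:5])
})

test_that("Gaussian filter preserves the mean of interior-supported
           frames and rejects even sizes", {
  set.seed(8)
  fr <- matrix(0, 12, 12)
  fr[4:9, 4:9] <- rnorm(36)
  m <- fluor_movie(array(fr, c(1, 12, 12)), 1000, 156)
  out <- gaussian_spatial_filter(m)
  expect_equal(sum(out$data), sum(fr), tolerance = 1e-12)
  expect_error(gaussian_spatial_filter(m, size = 4), "odd")
})

test_that("top-hat baseline removal matches the morphological definition", {
  # constant trace -> identically zero output
  m <- make_movie(matrix(7, 50, 4), 2, 2)
  out <- tophat_baseline(m, 5)
  expect_equal(max(abs(out$data)), 0)

  # narrow spike with a 3-sample kernel is untouched
  tr <- c(0, 0, 5, 0, 0)
  m <- make_movie(matrix(tr, 5, 1), 1, 1)
  out <- tophat_baseline(m, 3)
  expect_equal(as.vector(out$data), tr)

  expect_error(tophat_baseline(make_movie(matrix(1, 10, 1), 1, 1), 2),
               "3 samples")
})

test_that("top-hat equals a brute-force opening and is offset invariant", {
  set.seed(11)
  for (k_ms in c(7, 21)) {
    tr <- cumsum(rnorm(200)) + 5 * sin(seq(0, 6 * pi, length.out = 200))
    m <- make_movie(matrix(tr, 200, 1), 1, 1)
    out <- tophat_baseline(m, k_ms)
    k <- 2 * round((k_ms - 1) / 2) + 1
    expect_equal(as.vector(out$data), tr - brute_opening(tr, k),
                 tolerance = 1e-12)
    out2 <- tophat_baseline(make_movie(matrix(tr + 123.4, 200, 1), 1, 1),
                            k_ms)
    expect_equal(out2$data, out$data, tolerance = 1e-10)
  }
})

test_that("top-hat pins the diastolic level of a drifting AP train near 0", {
  spec <- sim_spec(grid = c(8, 8), speed = 50, apd80 = 40,
                   pcl_schedule = cbind(120, 8), drift = c(0.3, 1.5),
                   polarity = "upright", seed = 2)
  sim <- simulate_paced_movie(spec)
  out <- tophat_baseline(sim$movie, 100)
  tr <- out$data[, 4, 4]
  dia <- sort(tr)[seq_len(round(0.3 * length(tr)))]   # diastolic samples
  expect_lt(abs(median(dia)), 0.02)
  expect_gt(abs(median(sim$movie$data[, 4, 4][
    sim$movie$data[, 4, 4] < quantile(sim$movie$data[, 4, 4], 0.3)])),
    0.05)                                # drift really was there
})

test_that("polarity handling inverts once and is then idempotent", {
  tr <- c(10, 2, 10)
  m <- make_movie(matrix(tr, 3, 1), 1, 1, polarity = "inverted_voltage")
  out <- apply_polarity(m)
  expect_equal(as.vector(out$data), c(0, 8, 0))
  expect_identical(out$polarity, "upright")
  expect_equal(apply_polarity(out)$data, out$data)

  up <- make_movie(matrix(tr, 3, 1), 1, 1, polarity = "upright")
  expect_equal(apply_polarity(up)$data, up$data)
})

test_that("polarity inversion uses per-pixel maxima", {
  M <- cbind(c(10, 2, 10), c(100, 92, 100))   # brightness gradient
  m <- make_movie(M, 1, 2, polarity = "inverted_voltage")
  out <- apply_polarity(m)
  expect_equal(matrix(out$data, 3, 2), cbind(c(0, 8, 0), c(0, 8, 0)))
})

test_that("tissue segmentation recovers active geometry", {
  nr <- 21
  xy <- expand.grid(r = 1:nr, c = 1:nr)
  disc <- matrix((xy$r - 11)^2 + (xy$c - 11)^2 <= 36, nr, nr)
  for (noise in c(0.02, 0.1)) {         # SNR 50 and 10
    spec <- sim_spec(grid = c(nr, nr), speed = 50, apd80 = 40,
                     pcl_schedule = cbind(100, 10), noise_sd = noise,
                     active_mask = disc, polarity = "upright", seed = 5)
    sim <- simulate_paced_movie(spec)
    mask <- segment_tissue(sim$movie)
    expect_gte(mean(mask[disc]), 0.99)
    expect_lte(mean(mask[!disc]), 0.01)
  }

  # two disjoint blobs: only the larger survives
  blob <- matrix(FALSE, nr, nr)
  blob[3:12, 3:12] <- TRUE         # 100 px
  blob[16:19, 16:19] <- TRUE       # 16 px
  spec2 <- sim_spec(grid = c(nr, nr), speed = 50, apd80 = 40,
                    pcl_schedule = cbind(100, 3), active_mask = blob,
                    polarity = "upright", seed = 6)
  m2 <- segment_tissue(simulate_paced_movie(spec2)$movie)
  expect_true(all(m2[3:12, 3:12]))
  expect_false(any(m2[16:19, 16:19]))

  # uniform dynamics -> full-frame mask
  tr <- sin(seq(0, 10, length.out = 40))
  m3 <- make_movie(matrix(tr, 40, 16), 4, 4)
  expect_true(all(segment_tissue(m3)))
})

test_that("trace normalisation is exact and affine invariant", {
  expect_equal(normalise_trace(c(2, 4, 6)), c(0, 0.5, 1))
  tr <- c(0, 0.25, 1, 0.5)
  expect_equal(normalise_trace(tr), tr)
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(30)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 50)
    expect_equal(normalise_trace(a * x + b), normalise_trace(x),
                 tolerance = 1e-12)
  }
  expect_error(normalise_trace(rep(1, 5)), "flat")
})
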