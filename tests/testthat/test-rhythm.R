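test_that("dominant frequency finds pure and mixed tones", {
  t <- seq(0, 5, by = 1e-3)[-1]
  res <- dominant_frequency(sin(2 * pi * 5 * t), 1000)
  expect_equal(res$df, 5, tolerance = 0.0501)
  mix <- sin(2 * pi * 4 * t) + 2 * sin(2 * pi * 9 * t)
  expect_equal(dominant_frequency(mix, 1000)$df, 9, tolerance = 0.0501)
  expect_error(dominant_frequency(sin(t), 80, band = c(0.5, 50)),
               "Nyquist")
})

test_that("DF matches a brute-force DFT on random signals", {
  set.seed(16)
  for (i in 1:8) {
    n <- sample(80:200, 1)
    x <- rnorm(n) + 3 * sin(2 * pi * runif(1, 2, 30) * (1:n) / 100)
    got <- dominant_frequency(x, 100, band = c(0.5, 40),
                              resolution = 0.5)$df
    expect_equal(got, brute_df(x, 100, c(0.5, 40), 0.5))
  }
})

test_that("DF is invariant to amplitude scaling and offset", {
  set.seed(17)
  x <- sin(2 * pi * 7.3 * seq(0, 3, by = 2e-3)) + rnorm(1501, sd = 0.1)
  d0 <- dominant_frequency(x, 500)$df
  expect_equal(dominant_frequency(5 * x + 100, 500)$df, d0)
  expect_equal(dominant_frequency(-0.2 * x, 500)$df, d0)
})

test_that("the padded grid meets the resolution at every profile rate", {
  for (fr in c(1000, 987, 500)) {
    res <- dominant_frequency(rnorm(400), fr)
    expect_lte(unique(round(diff(res$frequencies), 10))[1], 0.05)
  }
})

test_that("a paced train has its pacing fundamental as DF", {
  spec <- sim_spec(grid = c(9, 9), speed = 50, apd80 = 60,
                   pcl_schedule = cbind(160, 20), polarity = "upright",
                   seed = 18)
  sim <- simulate_paced_movie(spec)
  res <- dominant_frequency(global_signal(sim$movie), 1000)
  expect_equal(res$df, 1000 / 160, tolerance = 0.0501)
})

test_that("DF maps resolve spatial frequency domains and flag flat
           pixels undefined", {
  left <- matrix(FALSE, 12, 12); left[, 1:6] <- TRUE
  sim <- simulate_irregular_movie(
    c(12, 12), 500,
    domains = list(list(mask = left, freq = 8),
                   list(mask = !left, freq = 14)),
    jitter = 0, duration_s = 4, noise_sd = 0, seed = 19)
  mask <- tissue_mask(matrix(TRUE, 12, 12))
  dm <- df_map(sim$movie, mask)
  expect_equal(unname(dm$values[, 1:6]), matrix(8, 12, 6),
               tolerance = 0.0501)
  expect_equal(unname(dm$values[, 7:12]), matrix(14, 12, 6),
               tolerance = 0.0501)

  flat <- fluor_movie(array(3, c(100, 4, 4)), 500, 156)
  dm2 <- df_map(flat, tissue_mask(matrix(TRUE, 4, 4)))
  expect_true(all(is.na(dm2$values)))
})

test_that("OWS is 1 for identical beats, 0 for orthogonal ones", {
  tr <- ap_template(3, 40, 1000, 100)
  expect_equal(ows(replicate(5, as.numeric(tr), simplify = FALSE)), 1)
  b1 <- c(1, 0, 0, 0); b2 <- c(0, 1, 0, 0)
  expect_equal(ows(list(b1, b2)), 0)
})

test_that("OWS is symmetric, affine invariant, and weights are
           injectable", {
  set.seed(20)
  beats <- lapply(1:6, function(i) random_beat(seed = 600 + i))
  o <- ows(beats)
  expect_equal(ows(rev(beats)), o, tolerance = 1e-12)
  expect_equal(ows(lapply(beats, function(b) 3.2 * b + 7)), o,
               tolerance = 1e-12)
  expect_equal(ows(beats, weights = rep(2, 6)), o, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ows(beats, weights = c(5, 1, 1, 1, 1, 1)),
                                o)))
})

test_that("OWS degrades monotonically with beat-to-beat jitter", {
  vals <- vapply(c(0, 0.15, 0.3), function(j) {
    sim <- simulate_irregular_movie(
      c(6, 6), 1000,
      domains = list(list(mask = matrix(TRUE, 6, 6), freq = 5)),
      jitter = j, duration_s = 4, noise_sd = 0, seed = 77)
    m <- sim$movie
    tb <- identify_pcls(detect_beats(global_signal(m), 1000), 1000)
    tb$pcl_group[] <- 1L               # jittered intervals, one rhythm
    attr(tb, "groups") <- data.frame(
      pcl_group = 1L, nominal_pcl = round(median(tb$cycle_length_ms,
                                                 na.rm = TRUE)),
      beat_count = nrow(tb))
    bw <- suppressWarnings(omapr:::beat_windows(m, tb, 1, n_last = 10))
    ows(lapply(bw$windows, function(W) W[, 15]))
  }, numeric(1))
  expect_equal(vals[1], 1, tolerance = 0.02)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], vals[1] - 0.1)     # material, not marginal, drop
})

test_that("OWS maps localise instability and handle degenerate groups", {
  mk_half <- function(delta, seed) {
    sim_spec(grid = c(10, 10), speed = 50, apd80 = 50,
             alternans_delta = delta, upstroke_ms = 4,
             pcl_schedule = cbind(130, 9), polarity = "upright",
             seed = seed)
  }
  stable <- simulate_paced_movie(mk_half(0, 55))$movie
  altern <- simulate_paced_movie(mk_half(25, 55))$movie
  # splice: left half stable, right half alternating
  spliced <- stable
  spliced$data[, , 6:10] <- altern$data[, , 6:10]
  mask <- tissue_mask(matrix(TRUE, 10, 10))
  tb <- identify_pcls(detect_beats(global_signal(spliced, mask), 1000),
                      1000)
  om <- ows_map(spliced, tb, 1, mask)
  expect_gt(min(om$values[, 1:5]), 0.995)
  expect_lt(max(om$values[, 6:10]), min(om$values[, 1:5]))

  # stable pacing: near 1 everywhere
  tb0 <- identify_pcls(detect_beats(global_signal(stable, mask), 1000),
                       1000)
  om0 <- ows_map(stable, tb0, 1, mask)
  expect_gt(min(map_values(om0)), 0.99)

  # single-beat group: all-undefined map plus a warning
  tb1 <- tb0[tb0$peak_frame < tb0$peak_frame[2], , drop = FALSE]
  attr(tb1, "groups") <- data.frame(pcl_group = 1L, nominal_pcl = 130,
                                    beat_count = 1L)
  class(tb1) <- c("beat_table", "data.frame")
  expect_warning(om1 <- ows_map(stable, tb1, 1, mask), "single-beat")
  expect_true(all(is.na(om1$values)))
})
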