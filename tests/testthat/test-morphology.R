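test_that("activation midpoint of a linear rise is its centre", {
  # rise in exactly representable 1/16 steps between t = 10 and 20 ms,
  # so all first differences on the ramp tie bit-exactly
  tr <- c(rep(0, 11), cumsum(rep(1 / 16, 10)), rep(10 / 16, 15))
  expect_equal(activation_time(tr, 1000, "midpoint"), 15)
  expect_equal(activation_time(tr, 1000, "max_dvdt"), 10)  # earliest tie
})

test_that("activation is invariant under positive affine transforms", {
  set.seed(21)
  for (i in 1:20) {
    tr <- random_beat(seed = 300 + i)
    a <- runif(1, 0.2, 8); b <- rnorm(1, 0, 10)
    expect_equal(activation_time(a * tr + b, 1000),
                 activation_time(tr, 1000), tolerance = 1e-9)
  }
})

test_that("flat or non-crossing traces give undefined results", {
  expect_true(is.na(activation_time(rep(1, 20), 1000)))
  expect_true(is.na(apd(rep(1, 20), 1000)))
  # repolarisation never reaches the level inside the window
  tr <- c(rep(0, 5), seq(0, 1, length.out = 5), rep(1, 20))
  tr[length(tr)] <- 0.95
  expect_true(is.na(apd(tr, 1000, level = 80)))
})

test_that("APD80 of an instantaneous-rise, linear-fall AP is 80% of the
           fall time", {
  tr <- c(rep(0, 10), seq(1, 0, length.out = 101), rep(0, 10))
  got <- apd(tr, 1000, level = 80)
  # 0.8 * 100 ms fall, within the one-frame quantisation of the start
  expect_equal(got, 80, tolerance = 1.01 / 80)
  # end-crossing interpolation is exact: levels differ by exactly the
  # corresponding stretch of the fall
  expect_equal(apd(tr, 1000, level = 90) - apd(tr, 1000, level = 50), 40,
               tolerance = 1e-9)
})

test_that("APD is non-decreasing in level on monotone repolarisation", {
  set.seed(9)
  for (i in 1:10) {
    tr <- random_beat(seed = 400 + i)
    levels <- c(30, 50, 70, 80, 90)
    vals <- vapply(levels, function(L) apd(tr, 1000, L), numeric(1))
    ok <- !is.na(vals)
    expect_true(all(diff(vals[ok]) >= -1e-9))
  }
})

test_that("compiled map path agrees with the plain scan on random beats", {
  set.seed(10)
  X <- vapply(1:50, function(i) random_beat(seed = 500 + i),
              numeric(120))
  expect_equal(omapr:::cpp_apd_cols(X, 1000, 80),
               apply(X, 2, r_apd, rate = 1000, level = 80))
  expect_equal(omapr:::cpp_act_cols(X, 1000, TRUE),
               apply(X, 2, r_act_mid, rate = 1000))
})

test_that("morphology maps recover simulator ground truth", {
  spec <- sim_spec(grid = c(25, 25), speed = 50, apd80 = 60,
                   upstroke_ms = 4, pcl_schedule = cbind(130, 11),
                   seed = 31)
  sim <- simulate_paced_movie(spec)
  m <- apply_polarity(sim$movie)
  mask <- segment_tissue(m)
  tb <- identify_pcls(detect_beats(global_signal(m, mask), 1000), 1000)
  ens <- ensemble_average(m, tb, 1)
  apd_m <- map_beat(ens, mask, "apd")
  expect_lt(max(abs(map_values(apd_m) - 60)), 1.01)
  act_m <- map_beat(ens, mask, "activation")
  tr <- sim$truth$activation - min(sim$truth$activation)
  expect_lt(max(abs(act_m$values - tr), na.rm = TRUE), 1.01)
  # activation is re-zeroed to the earliest pixel
  expect_equal(min(map_values(act_m)), 0)
})

test_that("simultaneous activation maps to identically zero", {
  tr <- ap_template(4, 50, 1000, 150)
  M <- matrix(rep(tr, 16), ncol = 16)
  ens <- structure(list(window = array(M, c(length(tr), 4, 4)),
                        frame_rate = 1000, pixel_size = 156,
                        pre_ms = 20, post_ms = 120, n_averaged = 1,
                        source_pcl = 150), class = "ensemble_beat")
  act <- map_beat(ens, tissue_mask(matrix(TRUE, 4, 4)), "activation")
  expect_equal(unname(act$values), matrix(0, 4, 4))
})

test_that("heterogeneity follows the percentile definition", {
  mask <- tissue_mask(matrix(TRUE, 101, 1))
  cm <- scalar_map(matrix(50, 101, 1), mask, "apd_ms")
  expect_equal(heterogeneity(cm), 0)
  v <- c(rep(90, 10), rep(100, 81), rep(110, 10))
  m <- scalar_map(matrix(v, 101, 1), mask, "apd_ms")
  expect_equal(heterogeneity(m), 0.2)
  set.seed(12)
  x <- matrix(rexp(101) + 1, 101, 1)
  for (cc in c(0.1, 3, 1e4))
    expect_equal(heterogeneity(scalar_map(x * cc, mask, "apd_ms")),
                 heterogeneity(scalar_map(x, mask, "apd_ms")),
                 tolerance = 1e-12)
  expect_error(heterogeneity(scalar_map(matrix(rnorm(101), 101, 1), mask,
                                        "apd_ms") |>
                 (\(s) { s$values <- s$values - median(s$values); s })()),
               "median")
  expect_error(heterogeneity(scalar_map(matrix(1, 4, 4),
                                        tissue_mask(matrix(TRUE, 4, 4)),
                                        "apd_ms")), "20")
})

test_that("alternans maps recover the programmed alternation", {
  spec <- sim_spec(grid = c(17, 17), speed = 50, apd80 = 60,
                   alternans_delta = 10, upstroke_ms = 4,
                   pcl_schedule = cbind(140, 9), noise_sd = 0.02,
                   seed = 33)
  sim <- simulate_paced_movie(spec)
  m <- apply_polarity(sim$movie)
  mask <- segment_tissue(m)
  m <- gaussian_spatial_filter(m, mask = mask)
  tb <- identify_pcls(detect_beats(global_signal(m, mask), 1000), 1000)
  dm <- alternans_map(m, tb, 1, mask)
  expect_equal(mean(map_values(dm)), 10, tolerance = 2 / 10)

  # no alternation: the map sits at the noise floor
  spec0 <- sim_spec(grid = c(17, 17), speed = 50, apd80 = 60,
                    upstroke_ms = 4, pcl_schedule = cbind(140, 9),
                    noise_sd = 0.02, seed = 34)
  sim0 <- simulate_paced_movie(spec0)
  m0 <- apply_polarity(sim0$movie)
  m0 <- gaussian_spatial_filter(m0, mask = mask)
  tb0 <- identify_pcls(detect_beats(global_signal(m0, mask), 1000), 1000)
  dm0 <- alternans_map(m0, tb0, 1, mask)
  expect_lt(mean(map_values(dm0)), 1)
  expect_error(alternans_map(m0, tb0, 2, mask), "group")
})
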