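test_that("das_beamform matches the brute-force double loop and is linear", {
  fr <- toy_frame(nt = 8L, N = 3L, L = 2L, seed = 21)
  img <- das_beamform(fr)
  expect_equal(img$values, oracle_das(fr$samples))
  expect_identical(img$mode, "DAS")
  expect_identical(img$display_state, "linear")

  # N identical channels -> N * s; channels summing to zero -> 0
  co <- coherent_frame(nt = 16L, N = 6L, L = 2L)
  expect_equal(das_beamform(co)$values, 6 * co$samples[, 1, ])
  z <- toy_frame(nt = 8L, N = 4L, L = 1L, seed = 22)
  z$samples[, 4, ] <- -rowSums(z$samples[, 1:3, 1, drop = FALSE], dims = 1)
  expect_equal(max(abs(das_beamform(z)$values)), 0)
})

test_that("das_beamform requires applied delays", {
  fr <- toy_frame()
  fr$delays_applied <- FALSE
  expect_error(das_beamform(fr), "delays")
})

test_that("envelope detection recovers a sinusoid's amplitude and rejects coherence images", {
  g <- toy_geometry(N = 4L, L = 1L)
  n <- 0:255
  s <- array(0, c(256, 4, 1))
  for (i in 1:4) s[, i, 1] <- 1.5 * sin(2 * pi * 0.15 * n)
  img <- das_beamform(channel_frame(s, g, "fundamental", delays_applied = TRUE))
  env <- envelope_detect(img)
  interior <- 30:226
  expect_equal(env$values[interior, 1], rep(6, length(interior)), tolerance = 1e-2)
  expect_identical(env$display_state, "envelope")

  zero <- beamformed_image(matrix(0, 8, 2), "DAS", "fundamental", g)
  expect_true(all(envelope_detect(zero)$values == 0))

  # envelope bounds the RF from above on a windowed pulse
  pulse <- exp(-(n - 128)^2 / 200) * sin(2 * pi * 0.2 * n)
  pimg <- beamformed_image(matrix(pulse, ncol = 1), "DAS", "fundamental", g)
  penv <- envelope_detect(pimg)
  expect_gte(max(penv$values), max(pulse))

  sl <- beamformed_image(matrix(1, 8, 2), "SLSC", "fundamental", g)
  expect_error(envelope_detect(sl), "DAS")
})

test_that("coherence_stack matches the literal nested-loop oracle", {
  for (seed in 1:3) {
    fr <- toy_frame(nt = 16L, N = 6L, L = 4L, seed = seed)
    st <- coherence_stack(fr, M = 5L, kernel_length = 3L)
    expect_equal(st$lag_images, oracle_coherence(fr$samples, 5L, 3L),
                 tolerance = 1e-12)
  }
  # 4-element toy with kernel 3 (different shape) against the same oracle
  fr <- toy_frame(nt = 10L, N = 4L, L = 2L, seed = 77)
  st <- coherence_stack(fr, M = 3L, kernel_length = 3L)
  expect_equal(st$lag_images, oracle_coherence(fr$samples, 3L, 3L),
               tolerance = 1e-12)
})

test_that("coherence values are bounded and perfect for identical channels", {
  co <- coherent_frame(nt = 24L, N = 6L, L = 2L)
  st <- coherence_stack(co, M = 5L, kernel_length = 5L)
  expect_equal(max(abs(st$lag_images - 1)), 0, tolerance = 1e-12)

  for (seed in 1:4) {
    fr <- toy_frame(nt = 20L, N = 8L, L = 3L, seed = 30 + seed)
    st <- coherence_stack(fr, M = 7L, kernel_length = 5L)
    expect_true(all(st$lag_images >= -1 - 1e-12 & st$lag_images <= 1 + 1e-12))
    # SLSC pixel can never exceed M
    expect_true(all(slsc_image(st, 7L)$values <= 7 + 1e-12))
  }
})

test_that("independent noise has near-zero mean coherence (Monte Carlo)", {
  set.seed(99)
  trials <- 60
  vals <- replicate(trials, {
    s <- array(rnorm(24 * 6 * 1), c(24, 6, 1))
    fr <- channel_frame(s, toy_geometry(N = 6L, L = 1L), "fundamental",
                        delays_applied = TRUE)
    mean(coherence_stack(fr, M = 3L, kernel_length = 5L)$lag_images)
  })
  expect_lt(abs(mean(vals)), 3 / sqrt(trials))
})

test_that("coherence_stack validates M and kernel", {
  fr <- toy_frame(N = 4L)
  expect_error(coherence_stack(fr, M = 4L), "M <= N - 1")
  expect_error(coherence_stack(fr, M = 0L), "M <= N - 1")
  expect_error(coherence_stack(fr, M = 2L, kernel_length = 4L), "odd")
  expect_error(coherence_stack(fr, M = 2L, kernel_length = 21L), "fit")
})

test_that("slsc_image sums lags and zeroes negative sums after summation", {
  g <- toy_geometry()
  li <- array(0, c(2, 2, 3))
  li[1, 1, ] <- c(0.5, 0.3, 0.2)     # positive sum 1.0
  li[2, 1, ] <- c(-0.1, -0.1, -0.1)  # negative sum -> zeroed
  li[1, 2, ] <- c(-0.5, 0.4, 0.2)    # mixed, sum 0.1 kept (no per-lag zeroing)
  st <- structure(list(lag_images = li, M = 3L, kernel_length = 5L,
                       band = "fundamental", geometry = g),
                  class = "coherence_stack")
  img <- slsc_image(st, 3L)
  expect_equal(img$values[1, 1], 1.0)
  expect_equal(img$values[2, 1], 0)
  expect_equal(img$values[1, 2], 0.1, tolerance = 1e-12)

  # fully coherent pixel -> M
  co <- coherent_frame(N = 6L)
  expect_equal(max(abs(slsc_image(coherence_stack(co, 5L), 5L)$values - 5)), 0,
               tolerance = 1e-12)

  # random stack equals oracle cumulative sum with zeroing
  fr <- toy_frame(nt = 12L, N = 6L, L = 2L, seed = 55)
  st2 <- coherence_stack(fr, M = 5L, kernel_length = 3L)
  or <- oracle_coherence(fr$samples, 5L, 3L)
  expected <- pmax(apply(or[, , 1:4, drop = FALSE], c(1, 2), sum), 0)
  expect_equal(slsc_image(st2, 4L)$values, expected, tolerance = 1e-12)
})

test_that("m_slsc_image applies per-lag zeroing then linear weights", {
  # weights are 1 at m=1 and 1/M at m=M; fully coherent pixel with M=20
  # gives the closed-form sum (M+1)/2 = 10.5
  co <- coherent_frame(N = 24L, nt = 24L, L = 1L)
  st <- coherence_stack(co, M = 20L, kernel_length = 5L)
  img <- m_slsc_image(st, 20L)
  expect_equal(max(abs(img$values - 10.5)), 0, tolerance = 1e-9)

  # M = 1 degenerates to SLSC with M = 1
  fr <- toy_frame(nt = 12L, N = 5L, L = 2L, seed = 66)
  st2 <- coherence_stack(fr, M = 4L, kernel_length = 3L)
  expect_equal(m_slsc_image(st2, 1L)$values,
               slsc_image(st2, 1L)$values, tolerance = 1e-12)

  # per-lag zeroing BEFORE weighting (differs from slsc zeroing order)
  or <- oracle_coherence(fr$samples, 4L, 3L)
  w <- 1 - (0:3) / 4
  expected <- matrix(0, 12, 2)
  for (m in 1:4) expected <- expected + w[m] * pmax(or[, , m], 0)
  expect_equal(m_slsc_image(st2, 4L)$values, expected, tolerance = 1e-12)
})

test_that("select_M uses the ceiling rule", {
  g <- acq_geometry()  # N = 64
  expect_identical(select_M(g, 0.10), 7L)
  expect_identical(select_M(g, 0.30), 20L)
  expect_identical(select_M(g, 1 / 64), 1L)
  expect_error(select_M(g, 0), "fraction")
  expect_error(select_M(g, 1), "fraction")
})

test_that("display_process normalizes, log compresses, clips and retains linear values", {
  g <- toy_geometry()
  v <- matrix(c(1, 0.001, 0.1, 0.5), 2, 2)
  img <- beamformed_image(v, "SLSC", "fundamental", g)
  out <- display_process(img, 60)
  expect_identical(out$display_state, "log_compressed")
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 1], -60)        # 0.001 -> -60 dB at the clip
  expect_equal(out$values[1, 2], -20)
  expect_equal(linear_values(out), v)        # metrics read the retained values

  zeroed <- beamformed_image(matrix(c(1, 0), 1, 2), "SLSC", "fundamental", g)
  expect_equal(display_process(zeroed, 60)$values[1, 2], -60)  # floor

  expect_error(display_process(beamformed_image(matrix(0, 2, 2), "SLSC",
                                                "fundamental", g)),
               "all-zero")
})

test_that("parameter bookkeeping reproduces the printed kernel conversions", {
  g <- acq_geometry()
  expect_equal(kernel_wavelengths(g, 5), 1.5625)
  expect_equal(axial_extent_mm(g, 78), 78 * 1540 / (2 * 40e6) * 1e3)
  expect_equal(round(axial_extent_mm(g, 78), 1), 1.5)
})

test_that("write_image_csv round-trips the linear pixel values", {
  img <- das_beamform(toy_frame(nt = 8L, N = 3L, L = 2L, seed = 23))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_image_csv(img, path)
  back <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(back) <- NULL
  expect_equal(back, img$values, tolerance = 1e-12)
})
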