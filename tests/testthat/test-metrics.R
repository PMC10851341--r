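# Exact double-sum transcription of the Wand plug-in rule (oracle for the
# binned implementation in select_bin_count).
oracle_wand_h <- function(x, stage = 1L) {
  n <- length(x); s <- sd(x)
  psi_ns <- function(r, sg) (-1)^(r / 2) * factorial(r) /
    ((2 * sg)^(r + 1) * factorial(r / 2) * sqrt(pi))
  psi_exact <- function(r, g) {
    d <- outer(x, x, "-") / g
    k <- if (r == 2) (d^2 - 1) * dnorm(d) else (d^4 - 6 * d^2 + 3) * dnorm(d)
    sum(k) / (n^2 * g^(r + 1))
  }
  psi2 <- if (stage == 0L) {
    psi_ns(2, s)
  } else if (stage == 1L) {
    g2 <- (2 / (sqrt(2 * pi) * psi_ns(4, s) * n))^(1 / 5)
    psi_exact(2, g2)
  } else {
    g4 <- (6 / (sqrt(2 * pi) * (-psi_ns(6, s)) * n))^(1 / 7)
    psi4 <- psi_exact(4, g4)
    g2 <- (2 / (sqrt(2 * pi) * psi4 * n))^(1 / 5)
    psi_exact(2, g2)
  }
  (6 / (-psi2 * n))^(1 / 3)
}

test_that("roi_mask equals the brute-force point-in-ellipse test", {
  g <- acq_geometry(n_scan_lines = 20L)
  dims <- c(300L, 20L)
  roi <- ellipse_roi(c(4, 0.3), c(1.2, 0.6), "mass")
  mk <- roi_mask(roi, g, dims)
  z <- axial_depth_mm(g, 0:(dims[1] - 1))
  x <- lateral_position_mm(g, 1:dims[2])
  brute <- matrix(FALSE, dims[1], dims[2])
  for (n in seq_len(dims[1])) for (l in seq_len(dims[2])) {
    brute[n, l] <- ((z[n] - 4) / 1.2)^2 + ((x[l] - 0.3) / 0.6)^2 <= 1
  }
  expect_identical(mk, brute)
  expect_gt(sum(mk), 0)

  # half-overlapping ellipse is clipped to in-image pixels
  roi2 <- ellipse_roi(c(0.1, 0), c(0.5, 0.5), "mass")
  mk2 <- roi_mask(roi2, g, dims)
  expect_true(any(mk2))
  # fully outside -> error
  expect_error(roi_mask(ellipse_roi(c(50, 0), c(1, 1), "mass"), g, dims),
               "no pixel")
})

test_that("roi pair constraints are enforced", {
  m <- ellipse_roi(c(10, -2), c(1, 1), "mass")
  ok_lat <- ellipse_roi(c(10, 1), c(1, 1), "tissue")      # gap 1 mm
  expect_true(validate_roi_pair(m, ok_lat))
  ok_depth <- ellipse_roi(c(14, -2), c(1, 1), "tissue")   # depth gap 2 mm
  expect_true(validate_roi_pair(m, ok_depth))
  expect_error(validate_roi_pair(m, ellipse_roi(c(10, 0.5), c(1, 1), "tissue")),
               "separation")
  expect_error(validate_roi_pair(m, ellipse_roi(c(10, 1), c(1, 2), "tissue")),
               "semi-axes")
})

test_that("contrast follows dB arithmetic and scale invariance", {
  g <- acq_geometry(n_scan_lines = 20L)
  v <- matrix(1, 300, 20)
  mask_m <- ellipse_roi(c(4, -0.5), c(0.8, 0.3), "mass")
  mask_t <- ellipse_roi(c(4, 0.5), c(0.8, 0.3), "tissue")
  mk <- roi_mask(mask_m, g, dim(v))
  v[mk] <- 0.1
  img <- beamformed_image(v, "SLSC", "fundamental", g)
  expect_equal(contrast(img, mask_m, mask_t), -20, tolerance = 1e-12)

  img2 <- beamformed_image(7.3 * v, "SLSC", "fundamental", g)
  expect_equal(contrast(img2, mask_m, mask_t),
               contrast(img, mask_m, mask_t), tolerance = 1e-12)

  expect_equal(contrast(beamformed_image(matrix(1, 300, 20), "SLSC",
                                         "fundamental", g), mask_m, mask_t),
               0, tolerance = 1e-12)

  vz <- matrix(1, 300, 20); vz[mk] <- 0
  expect_identical(contrast(beamformed_image(vz, "SLSC", "fundamental", g),
                            mask_m, mask_t), -Inf)
  vz2 <- matrix(0, 300, 20); vz2[mk] <- 1
  expect_error(contrast(beamformed_image(vz2, "SLSC", "fundamental", g),
                        mask_m, mask_t), "tissue")
  # raw (non-envelope) DAS images are refused
  expect_error(contrast(beamformed_image(v, "DAS", "fundamental", g),
                        mask_m, mask_t), "envelope")
})

test_that("contrast_difference subtracts with the fluid-positive sign convention", {
  g <- acq_geometry(n_scan_lines = 20L)
  mask_m <- ellipse_roi(c(4, -0.5), c(0.8, 0.3), "mass")
  mask_t <- ellipse_roi(c(4, 0.5), c(0.8, 0.3), "tissue")
  mk <- roi_mask(mask_m, g, c(300L, 20L))
  mkimg <- function(val, mode, band = "fundamental", state = "envelope") {
    v <- matrix(1, 300, 20); v[mk] <- val
    beamformed_image(v, mode, band, g, display_state = state)
  }
  b <- mkimg(0.1, "DAS")            # -20 dB
  s <- mkimg(0.01, "SLSC", state = "linear")  # -40 dB
  expect_equal(contrast_difference(b, s, mask_m, mask_t), 20, tolerance = 1e-10)
  expect_equal(contrast_difference(b, mkimg(0.1, "SLSC", state = "linear"),
                                   mask_m, mask_t), 0, tolerance = 1e-10)
  expect_error(contrast_difference(b, mkimg(0.1, "SLSC", "harmonic",
                                            state = "linear"),
                                   mask_m, mask_t), "band")
})

test_that("LOC map equals the lag-one slice of the coherence stack, unzeroed", {
  fr <- toy_frame(nt = 16L, N = 6L, L = 3L, seed = 44)
  map <- lag_one_coherence_map(fr, kernel_length = 3L)
  st <- coherence_stack(fr, M = 4L, kernel_length = 3L)
  expect_equal(map$values, st$lag_images[, , 1], tolerance = 1e-12)
  expect_true(any(map$values < 0))   # negatives retained

  co <- coherent_frame(N = 6L)
  expect_equal(max(abs(lag_one_coherence_map(co)$values - 1)), 0,
               tolerance = 1e-12)
})

test_that("mean_loc is the plain ROI mean (oracle loop)", {
  g <- acq_geometry(n_scan_lines = 20L)
  set.seed(12)
  v <- matrix(runif(300 * 20, -0.5, 1), 300, 20)
  map <- beamformed_image(v, "LOC", "fundamental", g)
  roi <- ellipse_roi(c(3, 0), c(0.9, 0.5), "mass")
  mk <- roi_mask(roi, g, dim(v))
  acc <- 0; cnt <- 0
  for (n in 1:300) for (l in 1:20) if (mk[n, l]) { acc <- acc + v[n, l]; cnt <- cnt + 1 }
  expect_equal(mean_loc(map, roi), acc / cnt, tolerance = 1e-12)
  cmap <- beamformed_image(matrix(0.42, 300, 20), "LOC", "fundamental", g)
  expect_equal(mean_loc(cmap, roi), 0.42)
})

test_that("select_bin_count matches the exact Wand oracle and the printed range", {
  set.seed(31)
  for (stage in c(0L, 1L, 2L)) {
    x <- rnorm(400); y <- rnorm(350, mean = 0.5)
    nb <- select_bin_count(x, y, stage = stage)
    h_or <- oracle_wand_h(c(x, y), stage)
    nb_or <- max(2L, as.integer(ceiling(diff(range(c(x, y))) / h_or)))
    expect_true(abs(nb - nb_or) <= 1L,
                label = sprintf("stage %d: binned %d vs exact %d", stage, nb, nb_or))
  }
  # standard-normal pool of n = 1000 falls in the reported 19..304 range
  set.seed(5)
  p <- rnorm(1000)
  nb <- select_bin_count(p[1:500], p[501:1000])
  expect_gte(nb, 19L)
  expect_lte(nb, 304L)

  expect_identical(select_bin_count(rep(1, 10), rep(1, 12)), 2L)
  expect_error(select_bin_count(1, c(1, 2)), "2 samples")

  # doubling the sample size changes the count smoothly (both near n^(1/3) law)
  set.seed(77)
  a <- rnorm(2000)
  n1 <- select_bin_count(a[1:500], a[501:1000])
  n2 <- select_bin_count(a[1:1000], a[1001:2000])
  expect_lt(abs(n2 / n1 - 2^(1 / 3)), 0.5)
})

test_that("gcnr is bounded with exact extremes and rescale invariance", {
  g <- acq_geometry(n_scan_lines = 20L)
  mask_m <- ellipse_roi(c(4, -0.5), c(0.8, 0.3), "mass")
  mask_t <- ellipse_roi(c(4, 0.5), c(0.8, 0.3), "tissue")
  mkm <- roi_mask(mask_m, g, c(300L, 20L))
  mkt <- roi_mask(mask_t, g, c(300L, 20L))

  set.seed(3)
  v <- matrix(rnorm(300 * 20, 5), 300, 20)
  v[mkm] <- v[mkt]                     # identical ROI contents
  img <- beamformed_image(v, "SLSC", "fundamental", g)
  expect_equal(as.numeric(gcnr(img, mask_m, mask_t)), 0)

  v2 <- matrix(0, 300, 20); v2[mkm] <- runif(sum(mkm)); v2[mkt] <- 5 + runif(sum(mkt))
  img2 <- beamformed_image(v2, "SLSC", "fundamental", g)
  expect_equal(as.numeric(gcnr(img2, mask_m, mask_t)), 1)

  set.seed(9)
  v3 <- matrix(1, 300, 20)
  v3[mkm] <- runif(sum(mkm), 0, 1); v3[mkt] <- runif(sum(mkt), 0.5, 1.5)
  img3 <- beamformed_image(v3, "SLSC", "fundamental", g)
  g1 <- as.numeric(gcnr(img3, mask_m, mask_t))
  img3s <- beamformed_image(100 * v3, "SLSC", "fundamental", g)
  expect_equal(as.numeric(gcnr(img3s, mask_m, mask_t)), g1, tolerance = 1e-12)
  expect_true(g1 >= 0 && g1 <= 1)
})

test_that("gcnr of half-overlapping uniforms is 0.5 up to binning error", {
  # analytic overlap integral: uniforms on [0,1] and [0.5,1.5] overlap 0.5
  g <- acq_geometry(n_scan_lines = 40L)
  mask_m <- ellipse_roi(c(4, -1), c(1.4, 0.8), "mass")
  mask_t <- ellipse_roi(c(4, 1), c(1.4, 0.8), "tissue")
  mkm <- roi_mask(mask_m, g, c(400L, 40L))
  mkt <- roi_mask(mask_t, g, c(400L, 40L))
  set.seed(21)
  reps <- sapply(1:5, function(r) {
    v <- matrix(1, 400, 40)
    v[mkm] <- runif(sum(mkm), 0, 1)
    v[mkt] <- runif(sum(mkt), 0.5, 1.5)
    img <- beamformed_image(v, "SLSC", "fundamental", g)
    as.numeric(gcnr(img, mask_m, mask_t))
  })
  expect_equal(mean(reps), 0.5, tolerance = 0.06)
})

test_that("classification thresholds and tie rules are as published", {
  th <- list(loc = 0.28, cd = 0, gcnr = 0.73)
  expect_identical(classify_mass(list(mean_loc = 0.10), th)[["mean_loc"]], "fluid")
  expect_identical(classify_mass(list(mean_loc = 0.50), th)[["mean_loc"]], "solid")
  expect_identical(classify_mass(list(mean_loc = 0.28), th)[["mean_loc"]], "solid")
  expect_identical(classify_mass(list(contrast_difference = -5), th)[["contrast_difference"]], "solid")
  expect_identical(classify_mass(list(contrast_difference = 5), th)[["contrast_difference"]], "fluid")
  expect_identical(classify_mass(list(contrast_difference = 0), th)[["contrast_difference"]], "solid")
  expect_identical(classify_mass(list(gcnr = 0.9), th)[["gcnr"]], "fluid")
  expect_identical(classify_mass(list(gcnr = 0.73), th)[["gcnr"]], "solid")
})

test_that("sensitivity and specificity reproduce the published confusion arithmetic", {
  ss <- sensitivity_specificity(list(TP = 7, FN = 0, TN = 25, FP = 3))
  expect_equal(unname(ss), c(1, 25 / 28))
  expect_equal(round(ss[["specificity"]], 2), 0.89)
  ss2 <- sensitivity_specificity(list(TP = 7, FN = 0, TN = 24, FP = 4))
  expect_equal(round(ss2[["specificity"]], 2), 0.86)
  ss3 <- sensitivity_specificity(list(TP = 7, FN = 0, TN = 27, FP = 1))
  expect_equal(round(ss3[["specificity"]], 2), 0.96)
  und <- sensitivity_specificity(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(und[["sensitivity"]]))
  expect_identical(attr(und, "undefined"), "sensitivity")
})

test_that("confusion counts derive from labels with fluid as positive", {
  truth <- c("fluid", "fluid", "solid", "solid", "solid")
  pred <- c("fluid", "solid", "solid", "fluid", "solid")
  cc <- confusion_counts(truth, pred)
  expect_identical(unlist(cc[c("TP", "FN", "TN", "FP")]),
                   c(TP = 1L, FN = 1L, TN = 2L, FP = 1L))
})

test_that("harmonic_ratio_map quantizes to 3-dB levels and averages correctly", {
  g <- acq_geometry(n_scan_lines = 20L)
  f <- beamformed_image(matrix(2, 200, 20), "DAS", "fundamental", g,
                        display_state = "envelope")
  h <- beamformed_image(matrix(1, 200, 20), "DAS", "harmonic", g,
                        display_state = "envelope")
  hr <- harmonic_ratio_map(f, h)
  expect_equal(hr$mean_reduction_db, 20 * log10(2), tolerance = 1e-9)
  expect_true(all(hr$map == 6))        # 6.02 dB falls in the 6-dB level
  expect_identical(hr$n_excluded, 0L)

  hr0 <- harmonic_ratio_map(f, f)
  expect_equal(hr0$mean_reduction_db, 0)
  expect_true(all(hr0$map == 0))

  hz <- beamformed_image(matrix(0, 200, 20), "DAS", "harmonic", g,
                         display_state = "envelope")
  hrz <- harmonic_ratio_map(f, hz)
  expect_identical(hrz$n_excluded, 200L * 20L)
  expect_true(is.nan(hrz$mean_reduction_db) || is.na(hrz$mean_reduction_db))
})
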