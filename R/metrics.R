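#' Elliptical region of interest
#'
#' Mass and tissue ROIs are same-size ellipses at the same depth; the tissue
#' ROI sits laterally beside the mass (nearest-edge separation 0.9-8.2 mm) or,
#' when the mass spans the lateral field of view, above/below it (nearest-edge
#' depth offset < 5 mm).  [validate_roi_pair()] checks these constraints.
#'
#' @param center `c(depth, lateral)` in mm.
#' @param semi_axes `c(axial, lateral)` semi-axes in mm.
#' @param role `"mass"` or `"tissue"`.
#' @return an object of class `ellipse_roi`.
#' @export
ellipse_roi <- function(center, semi_axes, role = c("mass", "tissue")) {
  role <- match.arg(role)
  if (length(center) != 2L || any(!is.finite(center))) {
    stopf("ellipse_roi: center must be c(depth, lateral) in mm")
  }
  if (length(semi_axes) != 2L || any(semi_axes <= 0)) {
    stopf("ellipse_roi: semi_axes must be positive")
  }
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 role = role), class = "ellipse_roi")
}

#' Check the geometric constraints on a mass/tissue ROI pair
#'
#' @param mass,tissue [ellipse_roi()]s.
#' @return `TRUE` invisibly; errors when a constraint is violated.
#' @export
validate_roi_pair <- function(mass, tissue) {
  if (!isTRUE(all.equal(mass$semi_axes, tissue$semi_axes))) {
    stopf("validate_roi_pair: tissue ROI must have the same semi-axes as the mass ROI")
  }
  same_depth <- isTRUE(all.equal(mass$center[1L], tissue$center[1L]))
  lat_gap <- abs(mass$center[2L] - tissue$center[2L]) - 2 * mass$semi_axes[2L]
  depth_gap <- abs(mass$center[1L] - tissue$center[1L]) - 2 * mass$semi_axes[1L]
  lateral_ok <- same_depth && lat_gap >= 0.9 && lat_gap <= 8.2
  depth_ok <- depth_gap >= 0 && depth_gap < 5
  if (!lateral_ok && !depth_ok) {
    stopf(paste0("validate_roi_pair: tissue ROI must be at the same depth with ",
                 "nearest-edge lateral separation in [0.9, 8.2] mm, or offset in ",
                 "depth by < 5 mm (got lateral gap %.2f mm, depth gap %.2f mm)"),
          lat_gap, depth_gap)
  }
  invisible(TRUE)
}

#' Pixel mask of an elliptical ROI
#'
#' @param roi an [ellipse_roi()].
#' @param geometry an [acq_geometry()].
#' @param dims `c(axial, lateral)` image dimensions in pixels.
#' @return logical matrix marking pixels whose centers fall inside the
#'   ellipse; empty masks are an error.
#' @export
roi_mask <- function(roi, geometry, dims) {
  z <- axial_depth_mm(geometry, 0:(dims[1L] - 1L))
  x <- lateral_position_mm(geometry, seq_len(dims[2L]))
  mk <- outer(((z - roi$center[1L]) / roi$semi_axes[1L])^2,
              ((x - roi$center[2L]) / roi$semi_axes[2L])^2, `+`) <= 1
  if (!any(mk)) stopf("roi_mask: ROI contains no pixel centers (outside image?)")
  mk
}

roi_values <- function(image, roi) {
  v <- linear_values(image)
  v[roi_mask(roi, image$geometry, dim(v))]
}

#' Mass-to-tissue contrast in dB
#'
#' `20 log10(mu_mass / mu_tissue)` of the mean linear-scale beamformed values
#' (envelope for B-mode, pre-log coherence values for coherence images).
#'
#' @param image a [beamformed_image()] (DAS images must be envelope detected).
#' @param mass,tissue [ellipse_roi()]s.
#' @return contrast in dB (`-Inf` if the mass mean is zero).
#' @export
contrast <- function(image, mass, tissue) {
  if (image$mode == "DAS" && image$display_state == "linear") {
    stopf("contrast: envelope-detect DAS images before measuring contrast")
  }
  mu_m <- mean(roi_values(image, mass))
  mu_t <- mean(roi_values(image, tissue))
  if (mu_t == 0) stopf("contrast: zero tissue mean, contrast undefined")
  if (mu_m == 0) return(-Inf)
  20 * log10(mu_m / mu_t)
}

#' Contrast difference between B-mode and coherence images
#'
#' `Contrast_Bmode - Contrast_Coherence` for two images of the same frequency
#' band; a positive value indicates fluid content, a negative value solid
#' content.
#'
#' @param bmode envelope-detected DAS [beamformed_image()].
#' @param coherence a coherence-mode [beamformed_image()] from the same band.
#' @param mass,tissue [ellipse_roi()]s.
#' @return contrast difference in dB.
#' @export
contrast_difference <- function(bmode, coherence, mass, tissue) {
  if (!identical(bmode$band, coherence$band)) {
    stopf("contrast_difference: images must come from the same band (got %s vs %s)",
          bmode$band, coherence$band)
  }
  contrast(bmode, mass, tissue) - contrast(coherence, mass, tissue)
}

#' Lag-one coherence (LOC) map
#'
#' The spatial coherence image at lag `m = 1`, i.e. a coherence stack with
#' `M = 1` returned as an image.  No negative-pixel zeroing is applied:
#' negative coherence is retained so that ROI means are unbiased.
#'
#' @param frame a [channel_frame()] with delays applied.
#' @param kernel_length odd axial kernel length in samples (default 5).
#' @return a linear-state [beamformed_image()] with mode `"LOC"`.
#' @export
lag_one_coherence_map <- function(frame, kernel_length = 5L) {
  st <- coherence_stack(frame, M = 1L, kernel_length = kernel_length)
  beamformed_image(st$lag_images[, , 1L], "LOC", st$band, st$geometry)
}

#' Mean lag-one coherence within a mass ROI
#'
#' @param map a [lag_one_coherence_map()] image.
#' @param mass the mass [ellipse_roi()].
#' @return arithmetic mean of the (unzeroed) LOC values in the ROI.
#' @export
mean_loc <- function(map, mass) {
  mean(roi_values(map, mass))
}

#' Histogram bin count by Wand's plug-in rule
#'
#' Selects the histogram bin width for the pooled mass + tissue samples using
#' Wand's data-based plug-in rule (one-stage by default) and converts it to a
#' bin count over the pooled range.  Stage 0 is the normal-scale rule
#' `h = 3.49 sigma n^(-1/3)`; stages 1 and 2 plug kernel functional estimates
#' of `psi_2` (and `psi_4`) into `h = (6 / (-psi_2 n))^(1/3)`.  Functionals
#' are evaluated on a 401-point linearly binned grid.
#'
#' @param values_mass,values_tissue numeric samples from the two ROIs (>= 2
#'   each).
#' @param stage plug-in stage: 0, 1 (default) or 2.
#' @return integer bin count `N >= 2`.
#' @export
select_bin_count <- function(values_mass, values_tissue, stage = 1L) {
  if (length(values_mass) < 2L || length(values_tissue) < 2L) {
    stopf("select_bin_count: need at least 2 samples per ROI")
  }
  pooled <- c(values_mass, values_tissue)
  rng <- diff(range(pooled))
  if (rng == 0 || sd(pooled) == 0) return(2L)
  h <- wand_bin_width(pooled, stage = stage)
  if (!is.finite(h) || h <= 0) return(2L)
  max(2L, as.integer(ceiling(rng / h)))
}

# Wand plug-in bin width (stages 0-2), binned evaluation of the psi
# functionals with a normal kernel.
wand_bin_width <- function(x, stage = 1L, gridsize = 401L) {
  n <- length(x)
  sigma <- sd(x)
  psi_ns <- function(r, s) {
    # psi_r for a N(0, s^2) reference
    (-1)^(r / 2) * factorial(r) /
      ((2 * s)^(r + 1) * factorial(r / 2) * sqrt(pi))
  }
  if (stage == 0L) {
    psi2 <- psi_ns(2L, sigma)
    return((6 / (-psi2 * n))^(1 / 3))
  }
  # linear binning on an equispaced grid
  g <- seq(min(x), max(x), length.out = gridsize)
  delta <- g[2L] - g[1L]
  pos <- (x - g[1L]) / delta
  lo <- pmin(pmax(floor(pos), 0), gridsize - 1L)
  w <- pos - lo
  cts <- numeric(gridsize)
  tab1 <- tapply(1 - w, lo, sum)
  tab2 <- tapply(w, lo + 1, sum)
  cts[as.integer(names(tab1)) + 1L] <- cts[as.integer(names(tab1)) + 1L] + tab1
  idx2 <- pmin(as.integer(names(tab2)), gridsize - 1L) + 1L
  cts[idx2] <- cts[idx2] + tab2
  psi_hat <- function(r, bw) {
    # n^-2 sum_ij phi_bw^(r)(x_i - x_j), phi derivatives via Hermite terms
    d <- (0:(gridsize - 1L)) * delta / bw
    kr <- switch(as.character(r),
                 "2" = (d^2 - 1) * dnorm(d),
                 "4" = (d^4 - 6 * d^2 + 3) * dnorm(d),
                 stopf("unsupported functional order"))
    # weights: number of grid pairs at each absolute distance
    wts <- crossdist_weights(cts)
    sum(wts * kr) / (n^2 * bw^(r + 1))
  }
  psi2 <- if (stage == 1L) {
    psi4 <- psi_ns(4L, sigma)
    g2 <- (2 / (sqrt(2 * pi) * psi4 * n))^(1 / 5)
    psi_hat(2L, g2)
  } else if (stage == 2L) {
    psi6 <- psi_ns(6L, sigma)
    g4 <- (2 * 3 / (sqrt(2 * pi) * (-psi6) * n))^(1 / 7)
    psi4 <- psi_hat(4L, g4)
    g2 <- (2 / (sqrt(2 * pi) * psi4 * n))^(1 / 5)
    psi_hat(2L, g2)
  } else {
    stopf("select_bin_count: stage must be 0, 1 or 2")
  }
  if (psi2 >= 0) return(NA_real_)  # degenerate estimate
  (6 / (-psi2 * n))^(1 / 3)
}

# sum over all (k, k') grid pairs grouped by |k - k'|: autocorrelation of the
# bin counts, lag 0 first.
crossdist_weights <- function(cts) {
  G <- length(cts)
  ff <- fft(c(cts, numeric(G)))
  ac <- Re(fft(ff * Conj(ff), inverse = TRUE)) / (2 * G)
  w <- ac[seq_len(G)]
  w[-1L] <- 2 * w[-1L]   # distances appear in both orders
  w
}

#' Generalized contrast-to-noise ratio (gCNR)
#'
#' `1 - sum_j min(h_mass(j), h_tissue(j))` over histograms of the linear-scale
#' pixel values in the two ROIs, computed on shared bin edges spanning the
#' pooled range with the bin count from [select_bin_count()].  Bounded in
#' `[0, 1]`: 0 for identical distributions, 1 for disjoint supports.
#'
#' @param image a [beamformed_image()] (DAS images must be envelope detected).
#' @param mass,tissue [ellipse_roi()]s.
#' @param n_bins optional fixed bin count overriding the plug-in rule.
#' @param stage plug-in stage for [select_bin_count()].
#' @return gCNR in `[0, 1]`, with the bin count attached as attribute
#'   `n_bins`.
#' @export
gcnr <- function(image, mass, tissue, n_bins = NULL, stage = 1L) {
  if (image$mode == "DAS" && image$display_state == "linear") {
    stopf("gcnr: envelope-detect DAS images before measuring gCNR")
  }
  vm <- roi_values(image, mass)
  vt <- roi_values(image, tissue)
  if (!length(vm) || !length(vt)) stopf("gcnr: empty ROI")
  rng <- range(c(vm, vt))
  if (diff(rng) == 0) {
    out <- 0
    attr(out, "n_bins") <- 2L
    return(out)
  }
  nb <- as.integer(n_bins %||% select_bin_count(vm, vt, stage = stage))
  edges <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  bin_of <- function(v) pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), nb)
  hm <- tabulate(bin_of(vm), nbins = nb) / length(vm)
  ht <- tabulate(bin_of(vt), nbins = nb) / length(vt)
  out <- 1 - sum(pmin(hm, ht))
  attr(out, "n_bins") <- nb
  out
}

#' Threshold classification of mass contents
#'
#' Applies the fixed, previously published thresholds: fluid iff mean LOC
#' below 0.28, fluid iff contrast difference above 0 dB, fluid iff gCNR above
#' 0.73.  Values exactly at a threshold classify as solid (conservative tie
#' rule).
#'
#' @param metrics named list with any of `mean_loc`, `contrast_difference`,
#'   `gcnr`.
#' @param thresholds named list of thresholds (defaults `loc = 0.28`,
#'   `cd = 0`, `gcnr = 0.73`).
#' @return named character vector of `"fluid"`/`"solid"` labels, one per
#'   supplied metric.
#' @export
classify_mass <- function(metrics,
                          thresholds = list(loc = 0.28, cd = 0, gcnr = 0.73)) {
  lab <- function(value, fluid_when) {
    if (is.na(value)) NA_character_ else if (fluid_when(value)) "fluid" else "solid"
  }
  out <- character(0)
  if (!is.null(metrics$mean_loc)) {
    out["mean_loc"] <- lab(metrics$mean_loc, function(v) v < thresholds$loc)
  }
  if (!is.null(metrics$contrast_difference)) {
    out["contrast_difference"] <-
      lab(metrics$contrast_difference, function(v) v > thresholds$cd)
  }
  if (!is.null(metrics$gcnr)) {
    out["gcnr"] <- lab(metrics$gcnr, function(v) v > thresholds$gcnr)
  }
  out
}

#' Confusion counts for fluid-mass detection
#'
#' Fluid is the positive class: TP = fluid called fluid, FN = fluid called
#' solid, TN = solid called solid, FP = solid called fluid.
#'
#' @param truth,predicted character vectors of `"fluid"`/`"solid"` labels.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  structure(list(TP = sum(truth == "fluid" & predicted == "fluid"),
                 FN = sum(truth == "fluid" & predicted == "solid"),
                 TN = sum(truth == "solid" & predicted == "solid"),
                 FP = sum(truth == "solid" & predicted == "fluid")),
            class = "confusion_counts")
}

#' Sensitivity and specificity from confusion counts
#'
#' `TP/(TP+FN)` and `TN/(TN+FP)`; a statistic with a zero denominator is
#' returned as `NA` with the `undefined` attribute naming it.
#'
#' @param counts a [confusion_counts()] or a list with fields TP, FN, TN, FP.
#' @return `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(counts) {
  undef <- character(0)
  sens <- if (counts$TP + counts$FN >= 1) counts$TP / (counts$TP + counts$FN)
          else { undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (counts$TN + counts$FP >= 1) counts$TN / (counts$TN + counts$FP)
          else { undef <- c(undef, "specificity"); NA_real_ }
  out <- c(sensitivity = sens, specificity = spec)
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Harmonic-to-fundamental amplitude ratio analysis
#'
#' Low-pass filters the two envelope images with a rectangular moving-average
#' kernel (default 78 axial samples x 15 lines, ~1.5 x 1.5 mm at the default
#' geometry), forms the pixel-wise signal reduction `20 log10(fund / harm)`
#' in dB, quantizes it to 3-dB levels spanning -6 to 21 dB for the contour
#' map, and reports the mean of the unquantized reduction.  Pixels whose
#' filtered amplitude is non-positive in either band are excluded from the
#' mean and counted in the `n_excluded` field.
#'
#' @param fund_env,harm_env envelope-state [beamformed_image()]s with matching
#'   shapes.
#' @param kernel `c(axial samples, lines)` moving-average kernel.
#' @param levels quantization levels in dB.
#' @return list with `map` (quantized dB levels), `ratio_db` (unquantized,
#'   `NA` where excluded), `mean_reduction_db` and `n_excluded`.
#' @export
harmonic_ratio_map <- function(fund_env, harm_env, kernel = c(78L, 15L),
                               levels = seq(-6, 21, by = 3)) {
  if (fund_env$display_state != "envelope" || harm_env$display_state != "envelope") {
    stopf("harmonic_ratio_map: envelope-detected images required")
  }
  if (!identical(dim(fund_env$values), dim(harm_env$values))) {
    stopf("harmonic_ratio_map: image shapes differ")
  }
  f <- box_filter_truncated(fund_env$values, kernel)
  h <- box_filter_truncated(harm_env$values, kernel)
  valid <- f > 0 & h > 0
  db <- matrix(NA_real_, nrow(f), ncol(f))
  db[valid] <- 20 * log10(f[valid] / h[valid])
  step <- diff(levels)[1L]
  q <- levels[pmin(pmax(floor((db - levels[1L]) / step), 0) + 1L, length(levels))]
  q <- matrix(q, nrow(f), ncol(f))
  list(map = q, ratio_db = db,
       mean_reduction_db = mean(db[valid]),
       n_excluded = sum(!valid))
}
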