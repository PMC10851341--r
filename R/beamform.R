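#' Beamformed image container
#'
#' 2-D beamformed values on the (axial pixel, scan line) grid, tagged with the
#' imaging mode, frequency band and display state.  Metrics always consume
#' linear-scale (pre-log) values: [display_process()] retains them in the
#' `linear` field, and [linear_values()] returns the right matrix regardless
#' of display state.
#'
#' @param values numeric matrix (axial x lateral), linear scale.
#' @param mode one of `"DAS"`, `"SLSC"`, `"M-SLSC"`, `"r-SLSC"`, `"R-SLSC"`,
#'   `"LOC"`.
#' @param band `"fundamental"` or `"harmonic"` (or another polarity tag for
#'   intermediate images).
#' @param geometry the source [acq_geometry()].
#' @param display_state `"linear"`, `"envelope"` or `"log_compressed"`.
#' @param linear retained linear values (defaults to `values`).
#' @return an object of class `beamformed_image`.
#' @export
beamformed_image <- function(values, mode, band, geometry,
                             display_state = "linear", linear = NULL) {
  stopifnot(is.matrix(values))
  structure(list(values = values, mode = mode, band = band,
                 geometry = geometry, display_state = display_state,
                 linear = linear %||% values),
            class = "beamformed_image")
}

#' @export
print.beamformed_image <- function(x, ...) {
  cat(sprintf("%s image [%s, %s]: %d x %d pixels\n", x$mode, x$band,
              x$display_state, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Linear-scale pixel values of a beamformed image
#'
#' @param image a [beamformed_image()].
#' @return the pre-log (linear or envelope) value matrix.
#' @export
linear_values <- function(image) {
  if (image$display_state == "log_compressed") image$linear else image$values
}

#' Delay-and-sum (DAS) beamforming
#'
#' Sums the time-delayed signals over the receive elements at each (depth,
#' line) pixel.  Envelope detection ([envelope_detect()]) and display
#' processing ([display_process()]) turn the result into a B-mode image.
#'
#' @param frame a [channel_frame()] with `delays_applied = TRUE`.
#' @return a linear-state [beamformed_image()] with mode `"DAS"`.
#' @export
das_beamform <- function(frame) {
  check_beamformable(frame)
  d <- dim(frame$samples)
  v <- colSums(aperm(frame$samples, c(2L, 1L, 3L)))  # sum over elements
  beamformed_image(matrix(v, d[1L], d[3L]), "DAS", frame$polarity_tag,
                   frame$geometry)
}

check_beamformable <- function(frame) {
  if (!inherits(frame, "channel_frame")) stopf("expected a channel_frame")
  if (!frame$delays_applied) {
    stopf("channel frame must have delays applied before beamforming")
  }
  if (dim(frame$samples)[2L] < 2L) stopf("beamforming requires N >= 2 elements")
  invisible(frame)
}

#' Envelope detection of a DAS image
#'
#' Magnitude of the axial analytic signal (FFT Hilbert transform per scan
#' line).  Coherence images are not envelope detected; passing one is an
#' error.
#'
#' @param image a linear-state `"DAS"` [beamformed_image()].
#' @return the image with `display_state = "envelope"`.
#' @export
envelope_detect <- function(image) {
  if (!inherits(image, "beamformed_image")) stopf("envelope_detect: need a beamformed_image")
  if (image$mode != "DAS") {
    stopf("envelope_detect: only DAS images are envelope detected (got %s)", image$mode)
  }
  if (image$display_state != "linear") {
    stopf("envelope_detect: image must be in linear display state")
  }
  env <- analytic_envelope(image$values)
  beamformed_image(env, image$mode, image$band, image$geometry,
                   display_state = "envelope")
}

#' Per-lag spatial coherence stack
#'
#' For every pixel and every lag `m = 1..M`, the normalized spatial coherence
#' is the average over the `N - m` element pairs separated by `m` of the
#' correlation coefficient of the two channels over an axial kernel of
#' `kernel_length` samples centered on the pixel (symmetrically truncated at
#' the image edges).  Per-kernel mean removal is not applied: the input RF is
#' assumed zero-mean (`zero_mean_removal = TRUE` subtracts kernel means first
#' if required).  Element pairs with zero kernel energy contribute 0.
#'
#' @param frame a [channel_frame()] with delays applied.
#' @param M maximum lag (`1 <= M <= N - 1`).
#' @param kernel_length odd axial kernel length in samples (default 5).
#' @param zero_mean_removal subtract the per-kernel mean from each channel
#'   before correlating (off by default).
#' @return an object of class `coherence_stack` with fields `lag_images`
#'   (axial x lateral x lag array, every entry in `[-1, 1]`), `M`,
#'   `kernel_length`, `band`, `geometry`.
#' @export
coherence_stack <- function(frame, M, kernel_length = 5L,
                            zero_mean_removal = FALSE) {
  check_beamformable(frame)
  d <- dim(frame$samples)
  N <- d[2L]
  M <- as.integer(M)
  kernel_length <- as.integer(kernel_length)
  if (M < 1L || M >= N) stopf("coherence_stack: need 1 <= M <= N - 1 = %d", N - 1L)
  if (kernel_length < 1L || kernel_length %% 2L == 0L) {
    stopf("coherence_stack: kernel_length must be odd and positive")
  }
  if (kernel_length > d[1L]) {
    stopf("coherence_stack: kernel does not fit the image depth")
  }
  samples <- frame$samples
  if (zero_mean_removal) {
    half <- kernel_length %/% 2L
    cnt <- running_sum_truncated(rep(1, d[1L]), half)
    for (l in seq_len(d[3L])) {
      s <- samples[, , l]
      mu <- apply(s, 2L, running_sum_truncated, half = half) / cnt
      samples[, , l] <- s - mu
    }
  }
  li <- coh_stack_cpp(samples, M, kernel_length)
  structure(list(lag_images = li, M = M, kernel_length = kernel_length,
                 band = frame$polarity_tag, geometry = frame$geometry),
            class = "coherence_stack")
}

#' @export
print.coherence_stack <- function(x, ...) {
  cat(sprintf("Coherence stack [%s]: %d x %d pixels, lags 1..%d, kernel %d samples\n",
              x$band, dim(x$lag_images)[1L], dim(x$lag_images)[2L], x$M,
              x$kernel_length))
  invisible(x)
}

#' SLSC image from a coherence stack
#'
#' Pixel-wise sum of the per-lag coherence images up to lag `M`; negative sums
#' are zeroed after summation.
#'
#' @param stack a [coherence_stack()].
#' @param M short-lag cutoff (`<= stack$M`), default the full stack.
#' @return a linear-state [beamformed_image()] with mode `"SLSC"`.
#' @export
slsc_image <- function(stack, M = stack$M) {
  M <- check_stack_M(stack, M)
  v <- lag_sum(stack$lag_images, M)
  v[v < 0] <- 0
  beamformed_image(v, "SLSC", stack$band, stack$geometry)
}

#' M-weighted SLSC (M-SLSC) image from a coherence stack
#'
#' Each per-lag image is zeroed (negatives to 0) first, then combined with the
#' linearly decreasing weights `1 - (m - 1)/M` (weight 1 at lag 1, `1/M` at
#' lag `M`).
#'
#' @inheritParams slsc_image
#' @return a linear-state [beamformed_image()] with mode `"M-SLSC"`.
#' @export
m_slsc_image <- function(stack, M = stack$M) {
  M <- check_stack_M(stack, M)
  v <- weighted_lag_sum(pmax(stack$lag_images, 0), M)
  beamformed_image(v, "M-SLSC", stack$band, stack$geometry)
}

check_stack_M <- function(stack, M) {
  if (!inherits(stack, "coherence_stack")) stopf("expected a coherence_stack")
  M <- as.integer(M)
  if (M < 1L || M > stack$M) stopf("M must be in 1..%d (stack lags)", stack$M)
  M
}

lag_sum <- function(li, M) {
  d <- dim(li)
  v <- matrix(0, d[1L], d[2L])
  for (m in seq_len(M)) v <- v + li[, , m]
  v
}

weighted_lag_sum <- function(li, M) {
  d <- dim(li)
  v <- matrix(0, d[1L], d[2L])
  for (m in seq_len(M)) v <- v + (1 - (m - 1) / M) * li[, , m]
  v
}

#' Export a beamformed image as CSV
#'
#' Writes the linear-scale pixel matrix (axial rows, scan-line columns) with
#' a small metadata header in comment lines.
#'
#' @param image a [beamformed_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_csv <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s band=%s display_state=%s", image$mode,
                     image$band, image$display_state), con)
  utils::write.table(linear_values(image), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Short-lag cutoff from an aperture fraction
#'
#' `M = ceiling(fraction * N)`: 10% of a 64-element aperture gives `M = 7`,
#' 30% gives `M = 20`.
#'
#' @param geometry an [acq_geometry()].
#' @param fraction aperture fraction in (0, 1).
#' @return integer lag count.
#' @export
select_M <- function(geometry, fraction) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stopf("select_M: fraction must be in (0, 1)")
  }
  as.integer(ceiling(fraction * geometry$n_receive_elements))
}

#' Normalize, log compress and clip for display
#'
#' Divides by the image maximum, converts to dB (`20 log10`) and clips at
#' `-dynamic_range_db`.  The pre-log values are retained in the `linear`
#' field so that metrics remain computable from the displayed image.
#'
#' @param image a linear- or envelope-state [beamformed_image()].
#' @param dynamic_range_db displayed dynamic range in dB (default 60).
#' @return the image with `display_state = "log_compressed"`.
#' @export
display_process <- function(image, dynamic_range_db = 60) {
  if (!inherits(image, "beamformed_image")) stopf("display_process: need a beamformed_image")
  if (!image$display_state %in% c("linear", "envelope")) {
    stopf("display_process: image is already log compressed")
  }
  v <- abs(image$values)
  mx <- max(v)
  if (mx <= 0) stopf("display_process: all-zero image, normalization undefined")
  db <- 20 * log10(v / mx)
  db[db < -dynamic_range_db | !is.finite(db)] <- -dynamic_range_db
  out <- beamformed_image(db, image$mode, image$band, image$geometry,
                          display_state = "log_compressed",
                          linear = image$values)
  attr(out, "dynamic_range_db") <- dynamic_range_db
  out
}
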