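#' Acquisition geometry for focused RF channel data
#'
#' Describes the transducer and scan geometry shared by all beamformers: a
#' linear array with `n_receive_elements` active receive channels per scan
#' line, a walking receive aperture centered on each line, and focused
#' transmits with a single focal depth.  Defaults match a 64-channel receive
#' aperture sampled at 40 MHz with a 12.5-MHz probe, a 6-MHz transmit, 256
#' scan lines at 0.1-mm spacing and 0.2-mm element pitch.
#'
#' Axial sample `n` (0-based) maps to depth `n * c / (2 * fs)` (round-trip
#' convention).  Scan line `l` (1-based) sits at lateral position
#' `(l - (L + 1)/2) * scan_line_spacing` mm, so the image is laterally
#' centered on zero.
#'
#' @param sampling_frequency RF sampling rate in Hz.
#' @param transmit_center_frequency transmit pulse center frequency in Hz.
#' @param probe_center_frequency probe (receive) center frequency in Hz.
#' @param n_receive_elements number of receive elements N (>= 2).
#' @param n_scan_lines number of scan lines per image.
#' @param element_pitch receive element pitch in mm.
#' @param scan_line_spacing lateral spacing of scan lines in mm.
#' @param sound_speed speed of sound in m/s.
#' @param focal_depth transmit focal depth in mm.
#' @return an object of class `acq_geometry`.
#' @export
acq_geometry <- function(sampling_frequency = 40e6,
                         transmit_center_frequency = 6e6,
                         probe_center_frequency = 12.5e6,
                         n_receive_elements = 64L,
                         n_scan_lines = 256L,
                         element_pitch = 0.2,
                         scan_line_spacing = 0.1,
                         sound_speed = 1540,
                         focal_depth = 14) {
  g <- list(
    sampling_frequency = as.numeric(sampling_frequency),
    transmit_center_frequency = as.numeric(transmit_center_frequency),
    probe_center_frequency = as.numeric(probe_center_frequency),
    n_receive_elements = as.integer(n_receive_elements),
    n_scan_lines = as.integer(n_scan_lines),
    element_pitch = as.numeric(element_pitch),
    scan_line_spacing = as.numeric(scan_line_spacing),
    sound_speed = as.numeric(sound_speed),
    focal_depth = as.numeric(focal_depth)
  )
  num <- vapply(g, function(x) is.finite(x) && x > 0, logical(1))
  if (!all(num)) {
    stopf("acq_geometry: all fields must be finite and positive (offending: %s)",
          paste(names(g)[!num], collapse = ", "))
  }
  if (g$n_receive_elements < 2L) {
    stopf("acq_geometry: n_receive_elements must be >= 2, got %d",
          g$n_receive_elements)
  }
  class(g) <- "acq_geometry"
  g
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("Acquisition geometry: N = %d elements (pitch %.3g mm), %d lines ",
           "(spacing %.3g mm)\n  fs = %.4g MHz, tx f0 = %.4g MHz, probe fc = ",
           "%.4g MHz, c = %g m/s, focus = %g mm\n"),
    x$n_receive_elements, x$element_pitch, x$n_scan_lines, x$scan_line_spacing,
    x$sampling_frequency / 1e6, x$transmit_center_frequency / 1e6,
    x$probe_center_frequency / 1e6, x$sound_speed, x$focal_depth))
  invisible(x)
}

#' Depth of an axial sample in mm
#'
#' @param geometry an [acq_geometry()].
#' @param n 0-based axial sample index (vectorized).
#' @return depth in mm under the round-trip convention `n * c / (2 * fs)`.
#' @export
axial_depth_mm <- function(geometry, n) {
  n * geometry$sound_speed / (2 * geometry$sampling_frequency) * 1e3
}

#' Axial extent of a sample count in mm
#'
#' Companion of [axial_depth_mm()]: the round-trip axial distance spanned by
#' `n_samples` consecutive samples (e.g. a 78-sample kernel is ~1.5 mm at
#' 40 MHz and 1540 m/s).
#' @inheritParams axial_depth_mm
#' @param n_samples number of samples.
#' @export
axial_extent_mm <- function(geometry, n_samples) {
  axial_depth_mm(geometry, n_samples)
}

#' Lateral position of scan lines in mm
#'
#' @inheritParams axial_depth_mm
#' @param l 1-based scan line index (vectorized); defaults to all lines.
#' @export
lateral_position_mm <- function(geometry, l = seq_len(geometry$n_scan_lines)) {
  (l - (geometry$n_scan_lines + 1) / 2) * geometry$scan_line_spacing
}

#' Correlation kernel length expressed in probe wavelengths
#'
#' The samples-per-period bookkeeping uses `fs / fc`: a k-sample kernel spans
#' `k * fc / fs` periods of the probe center frequency (5 samples = 1.5625
#' wavelengths at fs = 40 MHz, fc = 12.5 MHz).
#' @inheritParams axial_depth_mm
#' @param kernel_length kernel length in samples.
#' @export
kernel_wavelengths <- function(geometry, kernel_length) {
  kernel_length * geometry$probe_center_frequency / geometry$sampling_frequency
}

#' Receive element lateral offsets relative to the scan line (mm)
#' @inheritParams axial_depth_mm
#' @keywords internal
element_offsets_mm <- function(geometry) {
  N <- geometry$n_receive_elements
  (seq_len(N) - (N + 1) / 2) * geometry$element_pitch
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}
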