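#' RF channel data frame
#'
#' Container for (axial sample x receive element x scan line) RF channel data
#' together with its [acq_geometry()], a polarity tag and a flag recording
#' whether receive focusing delays have been applied.  All beamformers require
#' `delays_applied = TRUE`.
#'
#' @param samples 3-D numeric array (axial, element, line); all values finite.
#' @param geometry an [acq_geometry()]; `n_receive_elements` and
#'   `n_scan_lines` must match the array dimensions.
#' @param polarity_tag one of `"normal"`, `"inverted"`, `"fundamental"`,
#'   `"harmonic"`.
#' @param delays_applied logical; `TRUE` once receive delays are applied.
#' @return an object of class `channel_frame`.
#' @export
channel_frame <- function(samples, geometry,
                          polarity_tag = c("normal", "inverted",
                                           "fundamental", "harmonic"),
                          delays_applied = FALSE) {
  polarity_tag <- match.arg(polarity_tag)
  if (!is.array(samples) || length(dim(samples)) != 3L) {
    stopf("channel_frame: samples must be a 3-D array (axial, element, line)")
  }
  if (!inherits(geometry, "acq_geometry")) {
    stopf("channel_frame: geometry must be an acq_geometry")
  }
  d <- dim(samples)
  if (d[2L] != geometry$n_receive_elements) {
    stopf("channel_frame: dim(samples)[2] = %d does not match n_receive_elements = %d",
          d[2L], geometry$n_receive_elements)
  }
  if (d[3L] != geometry$n_scan_lines) {
    stopf("channel_frame: dim(samples)[3] = %d does not match n_scan_lines = %d",
          d[3L], geometry$n_scan_lines)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stopf("channel_frame: all samples must be finite")
  }
  structure(list(samples = samples, geometry = geometry,
                 polarity_tag = polarity_tag,
                 delays_applied = isTRUE(delays_applied)),
            class = "channel_frame")
}

#' @export
print.channel_frame <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("RF channel frame [%s]: %d axial x %d elements x %d lines (delays %s)\n",
              x$polarity_tag, d[1L], d[2L], d[3L],
              if (x$delays_applied) "applied" else "NOT applied"))
  invisible(x)
}

#' Normal/inverted pulse pair from a pulse-inversion sequence
#'
#' @param normal,inverted [channel_frame()]s with matching shapes and geometry,
#'   tagged `"normal"` and `"inverted"` respectively.
#' @return an object of class `pulse_pair`.
#' @export
pulse_pair <- function(normal, inverted) {
  if (!inherits(normal, "channel_frame") || !inherits(inverted, "channel_frame")) {
    stopf("pulse_pair: both members must be channel_frame objects")
  }
  if (normal$polarity_tag != "normal" || inverted$polarity_tag != "inverted") {
    stopf("pulse_pair: frames must be tagged 'normal' and 'inverted' (got '%s'/'%s')",
          normal$polarity_tag, inverted$polarity_tag)
  }
  if (!identical(dim(normal$samples), dim(inverted$samples))) {
    stopf("pulse_pair: frame shapes differ")
  }
  if (!geometry_equal(normal$geometry, inverted$geometry)) {
    stopf("pulse_pair: frame geometries differ")
  }
  structure(list(normal = normal, inverted = inverted), class = "pulse_pair")
}

#' Fundamental channel data from a pulse pair
#'
#' Fundamental channel data are the echoes received from the normal pulse,
#' re-tagged `"fundamental"`.
#' @param pair a [pulse_pair()].
#' @return a [channel_frame()] tagged `"fundamental"`.
#' @export
make_fundamental <- function(pair) {
  if (!inherits(pair, "pulse_pair")) stopf("make_fundamental: need a pulse_pair")
  f <- pair$normal
  if (dim(f$samples)[3L] == 0L || dim(f$samples)[1L] == 0L) {
    stopf("make_fundamental: degenerate (empty) frame")
  }
  f$polarity_tag <- "fundamental"
  f
}

#' Harmonic channel data from a pulse pair
#'
#' Pulse-inversion summation: the element-wise sum of normal and inverted
#' frames cancels linear (odd-order) echoes and retains even-order content.
#' Summation only is performed by default; whether a band-pass around twice
#' the transmit frequency should follow is acquisition-dependent, so a
#' `filter_hook` is exposed instead of assumed.
#' @param pair a [pulse_pair()].
#' @param filter_hook optional function applied to the summed 3-D sample
#'   array (e.g. an axial band-pass around `2 f0`); must return an array of
#'   the same shape.
#' @return a [channel_frame()] tagged `"harmonic"`.
#' @export
make_harmonic <- function(pair, filter_hook = NULL) {
  if (!inherits(pair, "pulse_pair")) stopf("make_harmonic: need a pulse_pair")
  if (dim(pair$normal$samples)[3L] == 0L) {
    stopf("make_harmonic: degenerate (empty) frame")
  }
  h <- pair$normal
  h$samples <- pair$normal$samples + pair$inverted$samples
  if (!is.null(filter_hook)) {
    out <- filter_hook(h$samples)
    if (!identical(dim(out), dim(h$samples))) {
      stopf("make_harmonic: filter_hook changed the array shape")
    }
    h$samples <- out
  }
  h$polarity_tag <- "harmonic"
  h
}

#' Apply receive focusing delays to raw channel data
#'
#' Resamples each channel along the axial axis so that echoes from on-axis
#' scatterers align across the aperture.  By default dynamic-receive geometric
#' delays are used: output sample `n` (depth `z_n = n c / (2 fs)`) of element
#' `i` is taken from the raw signal at time `(z_n + sqrt(z_n^2 + d_i^2)) / c`,
#' where `d_i` is the element's lateral offset from the scan line.  Linear
#' interpolation permits sub-sample shifts.  Alternatively a fixed per-element
#' advance (in samples) can be supplied via `delays`; `delays = rep(0, N)` is
#' the identity.
#'
#' @param raw a [channel_frame()] with `delays_applied = FALSE`.
#' @param geometry an [acq_geometry()] consistent with `raw` (defaults to the
#'   frame's own geometry).
#' @param delays optional numeric vector of length N: per-element advance in
#'   samples (positive values shift the channel toward earlier output
#'   samples), overriding the geometric rule.
#' @return a [channel_frame()] with `delays_applied = TRUE`.
#' @export
apply_focal_delays <- function(raw, geometry = raw$geometry, delays = NULL) {
  if (!inherits(raw, "channel_frame")) stopf("apply_focal_delays: need a channel_frame")
  if (!geometry_equal(geometry, raw$geometry)) {
    stopf("apply_focal_delays: geometry does not match the frame")
  }
  d <- dim(raw$samples)
  nt <- d[1L]; N <- d[2L]; L <- d[3L]
  out <- raw$samples
  if (is.null(delays)) {
    c_mms <- geometry$sound_speed * 1e3          # mm/s
    fs <- geometry$sampling_frequency
    z <- axial_depth_mm(geometry, 0:(nt - 1L))   # mm
    dx <- element_offsets_mm(geometry)
    for (i in seq_len(N)) {
      # receive time in samples for output depth z_n on element i
      pos <- (z / c_mms + sqrt(z^2 + dx[i]^2) / c_mms) * fs
      out[, i, ] <- interp_columns(raw$samples[, i, , drop = FALSE], pos, nt, L)
    }
  } else {
    if (length(delays) != N || any(!is.finite(delays))) {
      stopf("apply_focal_delays: delays must be a finite vector of length N = %d", N)
    }
    for (i in seq_len(N)) {
      pos <- (0:(nt - 1L)) + delays[i]
      out[, i, ] <- interp_columns(raw$samples[, i, , drop = FALSE], pos, nt, L)
    }
  }
  fr <- raw
  fr$samples <- out
  fr$delays_applied <- TRUE
  fr
}

# Linear interpolation of one element's (nt x 1 x L) slab at fractional
# 0-based sample positions `pos`; out-of-range positions give 0.
interp_columns <- function(slab, pos, nt, L) {
  m <- matrix(slab, nrow = nt, ncol = L)
  f <- floor(pos)
  w <- pos - f
  i0 <- as.integer(f) + 1L               # 1-based lower sample
  valid0 <- i0 >= 1L & i0 <= nt
  valid1 <- (i0 + 1L) >= 1L & (i0 + 1L) <= nt
  a <- matrix(0, nt, L); b <- matrix(0, nt, L)
  a[valid0, ] <- m[i0[valid0], , drop = FALSE]
  b[valid1, ] <- m[i0[valid1] + 1L, , drop = FALSE]
  a * (1 - w) + b * w
}

# ---------------------------------------------------------------------------
# Single-file container I/O.
#
# Layout: magic line "SLSCBF1\n", a 4-byte little-endian integer giving the
# length of a JSON attribute header (geometry fields, polarity_tag,
# delays_applied, dims, dtype), followed by the sample payload as little-endian
# float64 in column-major order.  The format is hierarchical in the HDF5 sense
# (one /samples dataset plus an attribute group) while remaining dependency
# free and losslessly round-trippable.
# ---------------------------------------------------------------------------

FRAME_MAGIC <- "SLSCBF1\n"

#' Write a channel frame to a single-file container
#'
#' @param frame a [channel_frame()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_frame()]
#' @export
write_frame <- function(frame, path) {
  if (!inherits(frame, "channel_frame")) stopf("write_frame: need a channel_frame")
  header <- list(
    format = "slscbf-frame", version = 1L,
    dims = dim(frame$samples), dtype = "float64",
    polarity_tag = frame$polarity_tag,
    delays_applied = frame$delays_applied,
    geometry = unclass(frame$geometry)
  )
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(FRAME_MAGIC), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.vector(frame$samples), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a channel frame from a single-file container
#'
#' @param path file written by [write_frame()].
#' @return a [channel_frame()].
#' @export
read_frame <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(FRAME_MAGIC)))
  if (!identical(magic, FRAME_MAGIC)) stopf("read_frame: not a slscbf frame file")
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || hlen <= 0L) stopf("read_frame: corrupt header")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  required <- c("dims", "dtype", "polarity_tag", "delays_applied", "geometry")
  missing <- setdiff(required, names(header))
  if (length(missing)) {
    stopf("read_frame: format error, missing attributes: %s",
          paste(missing, collapse = ", "))
  }
  gfields <- c("sampling_frequency", "transmit_center_frequency",
               "probe_center_frequency", "n_receive_elements", "n_scan_lines",
               "element_pitch", "scan_line_spacing", "sound_speed", "focal_depth")
  gmiss <- setdiff(gfields, names(header$geometry))
  if (length(gmiss)) {
    stopf("read_frame: format error, missing geometry attributes: %s",
          paste(gmiss, collapse = ", "))
  }
  geometry <- do.call(acq_geometry, header$geometry[gfields])
  dims <- as.integer(header$dims)
  vals <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
  if (length(vals) != prod(dims)) stopf("read_frame: truncated payload")
  channel_frame(array(vals, dim = dims), geometry,
                polarity_tag = header$polarity_tag,
                delays_applied = isTRUE(header$delays_applied))
}
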