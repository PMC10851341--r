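#' Scene configuration for the synthetic channel-data simulator
#'
#' Describes one synthetic breast-mass scene: an elliptical mass embedded in
#' diffuse speckle-generating tissue, insonified with a two-pulse
#' (normal/inverted) pulse-inversion sequence.  The simulator controls mass
#' echogenicity and internal spatial coherence independently, so fluid masses
#' (low internal coherence) and solid masses (tissue-like coherence, reduced
#' echogenicity) can both be emulated.
#'
#' @param mass_kind one of `"simple_cyst"`, `"complicated_cyst"`,
#'   `"solid_benign"`, `"solid_malignant"`, `"mixed"`.
#' @param mass_center `c(depth, lateral)` in mm.
#' @param mass_semi_axes `c(axial, lateral)` semi-axes in mm (positive).
#' @param echogenicity_contrast mass scatterer amplitude relative to tissue,
#'   in dB (0 = isoechoic, -60 ~ anechoic).
#' @param internal_coherence target coherent-signal power fraction inside the
#'   mass, in `[0, 1]`; 1 leaves the scatterer echoes untouched, 0 replaces
#'   them by spatially incoherent noise of the same power.
#' @param clutter_level additive spatially incoherent clutter, in dB relative
#'   to the tissue echo level; injected into the linear component only, so
#'   pulse-inversion summation cancels it. Use `-Inf` to disable.
#' @param harmonic_distortion relative amplitude of the even-order
#'   (second-harmonic) proxy component, in `[0, 1]`; it grows linearly with
#'   depth up to the transmit focus and has equal sign for both pulse
#'   polarities.
#' @param seed integer seed; recorded in all outputs.
#' @param depth_extent_mm imaged depth range in mm.
#' @param scatterer_density scatterers per mm^2 (default 30, several per
#'   resolution cell: fully developed speckle).
#' @param noise_floor_db independent electronic noise per receive event, in dB
#'   relative to tissue echo level (does not cancel under pulse inversion).
#' @param fractional_bandwidth -6 dB fractional bandwidth of the transmit
#'   pulse envelope.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(mass_kind = c("complicated_cyst", "simple_cyst",
                                       "solid_benign", "solid_malignant",
                                       "mixed"),
                         mass_center = c(14, -2.4),
                         mass_semi_axes = c(2.0, 1.8),
                         echogenicity_contrast = -20,
                         internal_coherence = 0.1,
                         clutter_level = -50,
                         harmonic_distortion = 0.7,
                         seed = 1L,
                         depth_extent_mm = 18,
                         scatterer_density = 30,
                         noise_floor_db = -60,
                         fractional_bandwidth = 0.6) {
  mass_kind <- match.arg(mass_kind)
  if (length(mass_center) != 2L || any(!is.finite(mass_center))) {
    stopf("scene_config: mass_center must be c(depth, lateral) in mm")
  }
  if (length(mass_semi_axes) != 2L || any(mass_semi_axes <= 0)) {
    stopf("scene_config: mass_semi_axes must be positive")
  }
  if (!is.finite(internal_coherence) || internal_coherence < 0 ||
      internal_coherence > 1) {
    stopf("scene_config: internal_coherence must be in [0, 1]")
  }
  if (harmonic_distortion < 0 || harmonic_distortion > 1) {
    stopf("scene_config: harmonic_distortion must be in [0, 1]")
  }
  if (depth_extent_mm <= 0 || scatterer_density <= 0) {
    stopf("scene_config: depth_extent_mm and scatterer_density must be positive")
  }
  structure(list(mass_kind = mass_kind,
                 mass_center = as.numeric(mass_center),
                 mass_semi_axes = as.numeric(mass_semi_axes),
                 echogenicity_contrast = as.numeric(echogenicity_contrast),
                 internal_coherence = as.numeric(internal_coherence),
                 clutter_level = as.numeric(clutter_level),
                 harmonic_distortion = as.numeric(harmonic_distortion),
                 seed = as.integer(seed),
                 depth_extent_mm = as.numeric(depth_extent_mm),
                 scatterer_density = as.numeric(scatterer_density),
                 noise_floor_db = as.numeric(noise_floor_db),
                 fractional_bandwidth = as.numeric(fractional_bandwidth)),
            class = "scene_config")
}

# Band-limited spatially incoherent noise: white Gaussian noise filtered
# axially to the transmit pulse band (clutter and in-mass incoherent echoes
# are acoustic, hence band-limited; electronic noise stays white).  Returns an
# array of the requested dim with unit RMS.
bandlimited_noise <- function(dims, fs, f0, bw) {
  nax <- dims[1L]
  w <- matrix(rnorm(prod(dims)), nrow = nax)
  sigma_t <- 1 / (2 * pi * (bw * f0 / 2.355))
  K <- as.integer(ceiling(3 * sigma_t * fs))
  t <- (-K:K) / fs
  h <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
  v <- fir_filter_cols_cpp(w, h)
  v <- v / sqrt(mean(v^2))
  array(v, dim = dims)
}

# in-ellipse predicate, vectorized over (depth, lateral) in mm
in_mass_ellipse <- function(config, depth_mm, lateral_mm) {
  ((depth_mm - config$mass_center[1L]) / config$mass_semi_axes[1L])^2 +
    ((lateral_mm - config$mass_center[2L]) / config$mass_semi_axes[2L])^2 <= 1
}

#' Random point-scatterer field for a scene
#'
#' Scatterers are placed uniformly at random over the field of view (lateral
#' span of the scan lines plus a transmit-beam margin, depths from 2 mm to the
#' scene depth extent plus 1 mm) with standard-normal amplitudes; amplitudes
#' inside the mass ellipse are scaled by the configured echogenicity contrast.
#' Reproducible from `config$seed`.
#'
#' @param config a [scene_config()].
#' @param geometry an [acq_geometry()].
#' @return a `data.frame` with columns `depth_mm`, `lateral_mm`, `amplitude`
#'   and class `scatterer_field`; the seed and mass ellipse are attached as
#'   attributes.
#' @export
make_scatterer_field <- function(config, geometry) {
  lat <- lateral_position_mm(geometry)
  margin <- 3
  x_min <- min(lat) - margin
  x_max <- max(lat) + margin
  z_min <- 2
  z_max <- config$depth_extent_mm + 1
  if (config$mass_center[1L] - config$mass_semi_axes[1L] < 0 ||
      config$mass_center[1L] + config$mass_semi_axes[1L] > config$depth_extent_mm ||
      config$mass_center[2L] - config$mass_semi_axes[2L] < min(lat) ||
      config$mass_center[2L] + config$mass_semi_axes[2L] > max(lat)) {
    stopf("make_scatterer_field: mass ellipse extends outside the field of view")
  }
  n <- as.integer(round(config$scatterer_density * (x_max - x_min) * (z_max - z_min)))
  with_seed(config$seed, {
    f <- data.frame(depth_mm = runif(n, z_min, z_max),
                    lateral_mm = runif(n, x_min, x_max),
                    amplitude = rnorm(n))
    inside <- in_mass_ellipse(config, f$depth_mm, f$lateral_mm)
    f$amplitude[inside] <- f$amplitude[inside] *
      db_to_amplitude(config$echogenicity_contrast)
    attr(f, "seed") <- config$seed
    attr(f, "n_inside_mass") <- sum(inside)
    class(f) <- c("scatterer_field", "data.frame")
    f
  })
}

#' Simulate a pulse-inversion pulse pair for a scene
#'
#' Produces time-delayed (receive-focused) normal and inverted channel data
#' frames.  The linear component is the superposition of band-limited
#' scatterer echoes (focused transmit, per-element round-trip delays); the
#' inverted pulse negates it.  An even-order proxy component at twice the
#' transmit frequency, with amplitude `harmonic_distortion` growing with depth
#' up to the focus and identical sign in both frames, survives pulse-inversion
#' summation.  Spatially incoherent clutter is added to the linear component
#' only, and inside the mass the coherent echo power fraction is set to
#' `internal_coherence` by mixing the common (across-element) echo with
#' independent per-element noise of matched power.
#'
#' @param field a [make_scatterer_field()] result (or `NULL` to generate one).
#' @param config a [scene_config()].
#' @param geometry an [acq_geometry()].
#' @return a [pulse_pair()] with `delays_applied = TRUE` on both frames.
#' @export
simulate_pulse_pair <- function(field, config, geometry) {
  if (is.null(field)) field <- make_scatterer_field(config, geometry)
  fs <- geometry$sampling_frequency
  c_mms <- geometry$sound_speed * 1e3
  f0 <- geometry$transmit_center_frequency
  nax <- as.integer(ceiling(config$depth_extent_mm * 2 * fs / c_mms)) + 1L
  dx <- element_offsets_mm(geometry)
  lat <- lateral_position_mm(geometry)
  aperture <- geometry$n_receive_elements * geometry$element_pitch
  lambda_tx <- c_mms / f0                       # mm
  sigma_t <- 1 / (2 * pi * (config$fractional_bandwidth * f0 / 2.355))
  zf <- geometry$focal_depth

  # raw receive-time extent: farthest element, deepest scatterer, pulse tail
  z_max <- config$depth_extent_mm + 1
  t_max <- (z_max + sqrt(z_max^2 + (max(abs(dx)) + 3)^2)) / c_mms + 4 * sigma_t
  nt_raw <- as.integer(ceiling(t_max * fs)) + 2L

  cubes <- sim_echo_cubes_cpp(field$lateral_mm, field$depth_mm, field$amplitude,
                              lat, dx, nt_raw, fs, c_mms, f0, sigma_t,
                              zf, aperture, lambda_tx,
                              config$harmonic_distortion)
  lin_raw <- cubes$lin
  harm_raw <- if (config$harmonic_distortion > 0) cubes$harm else NULL

  to_frame <- function(x, tag) channel_frame(x, geometry, tag, delays_applied = FALSE)
  lin <- apply_focal_delays(to_frame(lin_raw, "normal"), geometry)$samples[seq_len(nax), , , drop = FALSE]
  if (is.null(harm_raw)) {
    normal <- lin
    inverted <- -lin
  } else {
    harm <- apply_focal_delays(to_frame(harm_raw, "normal"), geometry)$samples[seq_len(nax), , , drop = FALSE]
    normal <- lin + harm
    inverted <- -lin + harm
  }

  # region masks on the (axial sample, line) grid
  z_px <- axial_depth_mm(geometry, 0:(nax - 1L))
  mass_mask <- outer(z_px, lat, function(z, x) in_mass_ellipse(config, z, x))
  band <- z_px >= 0.25 * config$depth_extent_mm &
          z_px <= 0.95 * config$depth_extent_mm
  tissue_sel <- band & !mass_mask
  N <- geometry$n_receive_elements
  expand_mask <- function(mk) aperm(array(mk, dim = c(nax, ncol(mk), N)), c(1, 3, 2))
  tissue_rms <- sqrt(mean(lin[expand_mask(tissue_sel)]^2))

  with_seed(config$seed + 1L, {
    # in-mass coherence mixing (linear-polarity noise: cancels in harmonic)
    alpha <- config$internal_coherence
    if (any(mass_mask) && alpha < 1) {
      idx <- which(expand_mask(mass_mask))
      e_rms <- sqrt(mean(normal[idx]^2))
      if (e_rms == 0) e_rms <- tissue_rms * db_to_amplitude(config$echogenicity_contrast)
      eta <- e_rms * bandlimited_noise(dim(normal), fs, f0,
                                       config$fractional_bandwidth)[idx]
      normal[idx] <- sqrt(alpha) * normal[idx] + sqrt(1 - alpha) * eta
      inverted[idx] <- sqrt(alpha) * inverted[idx] - sqrt(1 - alpha) * eta
    }
    # global spatially incoherent clutter, linear component only
    if (is.finite(config$clutter_level)) {
      sig_c <- tissue_rms * db_to_amplitude(config$clutter_level)
      if (sig_c > 0) {
        cl <- sig_c * bandlimited_noise(dim(normal), fs, f0,
                                        config$fractional_bandwidth)
        normal <- normal + cl
        inverted <- inverted - cl
      }
    }
    # independent electronic noise floor per receive event
    if (is.finite(config$noise_floor_db)) {
      sig_e <- tissue_rms * db_to_amplitude(config$noise_floor_db)
      if (sig_e > 0) {
        normal <- normal + array(rnorm(length(normal), sd = sig_e), dim = dim(normal))
        inverted <- inverted + array(rnorm(length(normal), sd = sig_e), dim = dim(normal))
      }
    }
    NULL
  })

  pulse_pair(channel_frame(normal, geometry, "normal", delays_applied = TRUE),
             channel_frame(inverted, geometry, "inverted", delays_applied = TRUE))
}

#' Generate a labelled synthetic cohort of mass scenes
#'
#' Stands in for an in vivo cohort: `n_fluid` fluid masses are drawn at low
#' internal coherence (simple cysts at lower echogenicity, complicated cysts
#' at higher, in a 4:3 ratio) and `n_solid` solid masses at tissue-like
#' coherence with reduced echogenicity (benign:malignant 22:6).  The cohort is
#' returned as a manifest of per-scene configurations plus truth labels;
#' scenes are realized on demand with [realize_scene()] to keep memory flat.
#'
#' @param n_fluid,n_solid non-negative scene counts.
#' @param parameter_ranges named list overriding any of the default ranges:
#'   `fluid_coherence`, `solid_coherence` (length-2 ranges),
#'   `echogenicity_simple`, `echogenicity_complicated`, `echogenicity_solid`,
#'   `semi_axis_axial`, `semi_axis_lateral`, `mass_lateral`, `clutter_level`,
#'   `harmonic_distortion` (scalars or ranges as noted).
#' @param seed integer cohort seed; per-scene seeds derive from it.
#' @param geometry an [acq_geometry()] used for every scene; the default is a
#'   desk-scale 96-line grid.
#' @return an object of class `mass_cohort`: a list with `manifest` (a
#'   data.frame with scene id, kind, truth label and generator parameters),
#'   `configs` (list of [scene_config()]s) and `geometry`.
#' @export
make_cohort <- function(n_fluid, n_solid, parameter_ranges = list(),
                        seed = 1L, geometry = cohort_geometry()) {
  if (n_fluid < 0 || n_solid < 0) stopf("make_cohort: counts must be >= 0")
  pr <- modifyList(list(
    fluid_coherence = c(0.02, 0.2),
    solid_coherence = c(1, 1),
    echogenicity_simple = c(-25, -20),
    echogenicity_complicated = c(-20, -15),
    echogenicity_solid = c(-25, -15),
    semi_axis_axial = c(1.6, 2.2),
    semi_axis_lateral = c(1.5, 2.0),
    mass_lateral = c(-2.7, -2.1),
    clutter_level = -50,
    harmonic_distortion = 0.7,
    depth_extent_mm = 18,
    scatterer_density = 30
  ), parameter_ranges)
  n <- n_fluid + n_solid
  draw <- function(rg) if (length(rg) == 1L) rg else runif(1, rg[1L], rg[2L])
  kinds <- c(
    rep(c("simple_cyst", "complicated_cyst"),
        c(round(4 / 7 * n_fluid), n_fluid - round(4 / 7 * n_fluid))),
    rep(c("solid_benign", "solid_malignant"),
        c(round(22 / 28 * n_solid), n_solid - round(22 / 28 * n_solid)))
  )
  truth <- rep(c("fluid", "solid"), c(n_fluid, n_solid))
  configs <- vector("list", n)
  rows <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      kind <- kinds[i]
      coh_rg <- if (truth[i] == "fluid") pr$fluid_coherence else pr$solid_coherence
      ech_rg <- switch(kind,
                       simple_cyst = pr$echogenicity_simple,
                       complicated_cyst = pr$echogenicity_complicated,
                       pr$echogenicity_solid)
      cfg <- scene_config(
        mass_kind = kind,
        mass_center = c(geometry$focal_depth, draw(pr$mass_lateral)),
        mass_semi_axes = c(draw(pr$semi_axis_axial), draw(pr$semi_axis_lateral)),
        echogenicity_contrast = draw(ech_rg),
        internal_coherence = draw(coh_rg),
        clutter_level = draw(pr$clutter_level),
        harmonic_distortion = draw(pr$harmonic_distortion),
        depth_extent_mm = pr$depth_extent_mm,
        scatterer_density = pr$scatterer_density,
        seed = seed + i * 101L
      )
      configs[[i]] <- cfg
      rows[[i]] <- data.frame(
        scene_id = i, mass_kind = kind, truth = truth[i],
        mass_depth_mm = cfg$mass_center[1L], mass_lateral_mm = cfg$mass_center[2L],
        semi_axial_mm = cfg$mass_semi_axes[1L], semi_lateral_mm = cfg$mass_semi_axes[2L],
        echogenicity_db = cfg$echogenicity_contrast,
        internal_coherence = cfg$internal_coherence,
        clutter_db = cfg$clutter_level,
        harmonic_distortion = cfg$harmonic_distortion,
        seed = cfg$seed
      )
    }
  })
  structure(list(manifest = do.call(rbind, rows), configs = configs,
                 geometry = geometry, seed = as.integer(seed)),
            class = "mass_cohort")
}

#' Desk-scale cohort geometry
#'
#' Default per-scene acquisition geometry for synthetic cohorts: the standard
#' 64-element receive aperture but 64 scan lines at 0.15-mm spacing (9.45-mm
#' lateral field of view), keeping single-scene simulation fast while leaving
#' room for a mass and a laterally offset tissue region of interest.
#' @export
cohort_geometry <- function() {
  acq_geometry(n_scan_lines = 64L, scan_line_spacing = 0.15, focal_depth = 14)
}

#' Realize one cohort scene as a pulse pair
#'
#' @param cohort a [make_cohort()] result.
#' @param i scene index (row of the manifest).
#' @return `list(pair = pulse_pair, truth = label, config = scene_config)`.
#' @export
realize_scene <- function(cohort, i) {
  if (!inherits(cohort, "mass_cohort")) stopf("realize_scene: need a mass_cohort")
  cfg <- cohort$configs[[i]]
  pair <- simulate_pulse_pair(NULL, cfg, cohort$geometry)
  list(pair = pair, truth = cohort$manifest$truth[i], config = cfg)
}

#' @export
print.mass_cohort <- function(x, ...) {
  tb <- table(x$manifest$truth)
  cat(sprintf("Synthetic mass cohort: %d scenes (%s), seed %d\n",
              nrow(x$manifest),
              paste(sprintf("%d %s", tb, names(tb)), collapse = ", "),
              x$seed))
  invisible(x)
}
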