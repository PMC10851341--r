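# Shared fixtures: tiny geometries and frames built in code.

toy_geometry <- function(N = 4L, L = 3L, fs = 40e6, pitch = 0.2,
                         spacing = 0.1, focal = 10) {
  acq_geometry(n_receive_elements = N, n_scan_lines = L,
               sampling_frequency = fs, element_pitch = pitch,
               scan_line_spacing = spacing, focal_depth = focal)
}

# Aligned frame with given samples array (defaults to random), small enough
# for brute-force oracles.
toy_frame <- function(samples = NULL, nt = 16L, N = 4L, L = 3L, seed = 1,
                      tag = "fundamental") {
  g <- toy_geometry(N = N, L = L)
  if (is.null(samples)) {
    set.seed(seed)
    samples <- array(rnorm(nt * N * L), dim = c(nt, N, L))
  }
  channel_frame(samples, g, polarity_tag = tag, delays_applied = TRUE)
}

# Frame where every element carries the same signal: fully coherent.
coherent_frame <- function(nt = 32L, N = 6L, L = 2L, seed = 2) {
  set.seed(seed)
  s <- matrix(rnorm(nt * L), nt, L)
  samples <- array(0, dim = c(nt, N, L))
  for (i in seq_len(N)) samples[, i, ] <- s
  channel_frame(samples, toy_geometry(N = N, L = L), "fundamental",
                delays_applied = TRUE)
}

# Literal nested-loop transcription of the normalized spatial coherence
# (oracle for coherence_stack): average over element pairs of the kernel
# correlation coefficient, kernel symmetrically truncated at the edges.
oracle_coherence <- function(samples, M, k) {
  d <- dim(samples)
  nt <- d[1]; N <- d[2]; L <- d[3]
  half <- k %/% 2
  out <- array(0, dim = c(nt, L, M))
  for (l in seq_len(L)) for (n in seq_len(nt)) {
    n1 <- max(1, n - half); n2 <- min(nt, n + half)
    for (m in seq_len(M)) {
      acc <- 0
      for (i in seq_len(N - m)) {
        si <- samples[n1:n2, i, l]
        sj <- samples[n1:n2, i + m, l]
        den <- sqrt(sum(si^2) * sum(sj^2))
        if (den > 0) acc <- acc + sum(si * sj) / den
      }
      out[n, l, m] <- acc / (N - m)
    }
  }
  out
}

# Brute-force DAS (oracle for das_beamform).
oracle_das <- function(samples) {
  d <- dim(samples)
  out <- matrix(0, d[1], d[3])
  for (l in seq_len(d[3])) for (n in seq_len(d[1])) {
    acc <- 0
    for (i in seq_len(d[2])) acc <- acc + samples[n, i, l]
    out[n, l] <- acc
  }
  out
}

# Small cohort geometry for fast end-to-end tests (not the criterion-6 one).
tiny_cohort_geometry <- function() {
  acq_geometry(n_scan_lines = 48L, scan_line_spacing = 0.15, focal_depth = 11)
}

tiny_cohort_ranges <- function() {
  list(mass_lateral = c(-1.9, -1.7), semi_axis_axial = c(1.1, 1.3),
       semi_axis_lateral = c(1.0, 1.2), depth_extent_mm = 15)
}

# run_config tissue ROI placement matching the tiny geometry
tiny_run_config <- function(cohort, ...) {
  run_config(cohort = cohort, tissue_lateral_mm = 1.8, ...)
}
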