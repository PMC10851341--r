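#' Run configuration for the mode-comparison pipeline
#'
#' Defaults reproduce the reference processing chain exactly: SLSC at
#' `M = select_M(0.10) = 7`, weighted/denoised modes at
#' `M = select_M(0.30) = 20`, a 5-sample correlation kernel, RPCA sparsity
#' `lambda = 1`, thresholds `{LOC 0.28, CD 0 dB, gCNR 0.73}` and a 60-dB
#' display dynamic range.
#'
#' @param cohort a [make_cohort()] result, or `NULL` when `input_files` is
#'   given.
#' @param input_files optional character vector of [write_frame()] container
#'   paths (alternating or tagged normal/inverted pairs are not required;
#'   each file must hold a fundamental- or harmonic-tagged frame).
#' @param M_slsc short-lag cutoff for SLSC (default 10% of the aperture).
#' @param M_weighted lag cutoff for M-SLSC/r-SLSC/R-SLSC (default 30%).
#' @param kernel_length odd correlation kernel length in samples.
#' @param rpca an [rpca_config()].
#' @param thresholds named list `loc`, `cd`, `gcnr`.
#' @param dynamic_range_db display dynamic range.
#' @param bands bands to process (`"fundamental"`, `"harmonic"`).
#' @param modes imaging modes to form (`"B-mode"`, `"SLSC"`, `"M-SLSC"`,
#'   `"r-SLSC"`, `"R-SLSC"`).
#' @param roi_scale mass ROI semi-axes as a fraction of the mass semi-axes.
#' @param tissue_lateral_mm lateral center of the tissue ROI in mm.
#' @param output_dir output directory (`NULL` = no files written).
#' @param write_images also export log-compressed PNG images.
#' @param seed integer seed recorded in the manifest.
#' @return an object of class `run_config` (validated and default-filled).
#' @export
run_config <- function(cohort = NULL, input_files = NULL,
                       M_slsc = NULL, M_weighted = NULL, kernel_length = 5L,
                       rpca = rpca_config(),
                       thresholds = list(loc = 0.28, cd = 0, gcnr = 0.73),
                       dynamic_range_db = 60,
                       bands = c("fundamental", "harmonic"),
                       modes = c("B-mode", "SLSC", "M-SLSC", "r-SLSC", "R-SLSC"),
                       roi_scale = 0.7, tissue_lateral_mm = 2.4,
                       output_dir = NULL, write_images = FALSE, seed = 1L) {
  cfg <- list(cohort = cohort, input_files = input_files, M_slsc = M_slsc,
              M_weighted = M_weighted, kernel_length = kernel_length,
              rpca = rpca, thresholds = thresholds,
              dynamic_range_db = dynamic_range_db, bands = bands,
              modes = modes, roi_scale = roi_scale,
              tissue_lateral_mm = tissue_lateral_mm, output_dir = output_dir,
              write_images = write_images, seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate and normalize a run configuration
#'
#' Fills defaults (`M_slsc`, `M_weighted` from [select_M()]), range-checks
#' every field and echoes the effective parameters.
#'
#' @param config a [run_config()] (possibly partially specified).
#' @param quiet suppress the parameter echo.
#' @return the normalized `run_config`.
#' @export
validate_config <- function(config, quiet = TRUE) {
  geom <- if (!is.null(config$cohort)) config$cohort$geometry else acq_geometry()
  config$M_slsc <- as.integer(config$M_slsc %||% select_M(geom, 0.10))
  config$M_weighted <- as.integer(config$M_weighted %||% select_M(geom, 0.30))
  N <- geom$n_receive_elements
  if (config$M_slsc < 1L || config$M_slsc >= N) {
    stopf("validate_config: M_slsc must be in 1..%d", N - 1L)
  }
  if (config$M_weighted < 1L || config$M_weighted >= N) {
    stopf("validate_config: M_weighted must be in 1..%d", N - 1L)
  }
  if (config$kernel_length < 1L || config$kernel_length %% 2L == 0L) {
    stopf("validate_config: kernel_length must be odd and positive")
  }
  if (!inherits(config$rpca, "rpca_config")) {
    config$rpca <- do.call(rpca_config, config$rpca)
  }
  th <- config$thresholds
  if (!all(c("loc", "cd", "gcnr") %in% names(th))) {
    stopf("validate_config: thresholds must name loc, cd and gcnr")
  }
  if (th$gcnr < 0 || th$gcnr > 1) stopf("validate_config: thresholds$gcnr must be in [0, 1]")
  if (abs(th$loc) > 1) stopf("validate_config: thresholds$loc must be in [-1, 1]")
  if (config$dynamic_range_db <= 0) stopf("validate_config: dynamic_range_db must be > 0")
  bad <- setdiff(config$modes, c("B-mode", "SLSC", "M-SLSC", "r-SLSC", "R-SLSC"))
  if (length(bad)) stopf("validate_config: unknown modes: %s", paste(bad, collapse = ", "))
  bad <- setdiff(config$bands, c("fundamental", "harmonic"))
  if (length(bad)) stopf("validate_config: unknown bands: %s", paste(bad, collapse = ", "))
  if (config$roi_scale <= 0 || config$roi_scale > 1) {
    stopf("validate_config: roi_scale must be in (0, 1]")
  }
  if (!quiet) {
    message(sprintf(
      "run_config: M_slsc=%d M_weighted=%d kernel=%d lambda=%g thresholds={%.2f,%g,%.2f} DR=%g dB",
      config$M_slsc, config$M_weighted, config$kernel_length,
      config$rpca$sparsity_lambda, th$loc, th$cd, th$gcnr, config$dynamic_range_db))
  }
  config
}

# All images for one band of one scene, restricted to the requested modes.
form_band_images <- function(frame, config) {
  out <- list()
  env <- envelope_detect(das_beamform(frame))
  out[["B-mode"]] <- env
  coh_modes <- intersect(config$modes, c("SLSC", "M-SLSC", "r-SLSC", "R-SLSC"))
  if (length(coh_modes)) {
    M_max <- if (any(coh_modes %in% c("M-SLSC", "r-SLSC", "R-SLSC"))) {
      max(config$M_weighted, config$M_slsc)
    } else config$M_slsc
    st <- coherence_stack(frame, M = M_max, kernel_length = config$kernel_length)
    if ("SLSC" %in% coh_modes) out[["SLSC"]] <- slsc_image(st, config$M_slsc)
    if ("M-SLSC" %in% coh_modes) out[["M-SLSC"]] <- m_slsc_image(st, config$M_weighted)
    if (any(coh_modes %in% c("r-SLSC", "R-SLSC"))) {
      den <- rpca_denoise_stack(st, config$rpca)
      if ("r-SLSC" %in% coh_modes) out[["r-SLSC"]] <- r_slsc_image(st, denoised = den)
      if ("R-SLSC" %in% coh_modes) {
        out[["R-SLSC"]] <- R_slsc_image(st, M = config$M_weighted, denoised = den)
      }
    }
  }
  loc_map <- lag_one_coherence_map(frame, config$kernel_length)
  list(images = out, loc_map = loc_map)
}

#' Run the full imaging-mode comparison on a cohort
#'
#' For every mass scene and requested band, forms the requested subset of the
#' ten imaging modes (fundamental/harmonic x B-mode, SLSC, M-SLSC, r-SLSC,
#' R-SLSC), measures contrast, contrast difference, mean lag-one coherence
#' and gCNR on a fixed mass/tissue ROI pair, classifies each mass per metric
#' against the configured thresholds, and aggregates confusion counts with
#' sensitivity/specificity per metric, mode and band.  Mixed masses, if
#' present, are excluded from the confusion statistics.
#'
#' @param config a [run_config()] with a cohort.
#' @return an object of class `comparison_report`: list with `metrics` (one
#'   row per scene x band x mode), `confusion` (per metric/band/mode),
#'   `manifest`, `failures` and `config`.  When `config$output_dir` is set,
#'   CSV tables and a JSON run manifest are written there.
#' @export
run_comparison <- function(config) {
  config <- validate_config(config)
  cohort <- config$cohort
  if (is.null(cohort)) stopf("run_comparison: config must carry a cohort")
  n <- nrow(cohort$manifest)
  if (n == 0L) stopf("run_comparison: empty cohort")
  rows <- list()
  failures <- list()
  for (i in seq_len(n)) {
    res <- tryCatch(evaluate_scene(cohort, i, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(scene_id = i, error = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- res
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  confusion <- if (!is.null(metrics)) summarize_confusion(metrics, config) else NULL
  report <- structure(list(metrics = metrics, confusion = confusion,
                           manifest = cohort$manifest,
                           failures = if (length(failures)) do.call(rbind, failures) else NULL,
                           config = config),
                      class = "comparison_report")
  if (!is.null(config$output_dir)) write_report(report, config)
  report
}

# Metric rows for a single scene: one row per band x mode.
evaluate_scene <- function(cohort, i, config) {
  sc <- realize_scene(cohort, i)
  cfg <- sc$config
  mass_roi <- ellipse_roi(cfg$mass_center, config$roi_scale * cfg$mass_semi_axes,
                          role = "mass")
  tissue_roi <- ellipse_roi(c(cfg$mass_center[1L], config$tissue_lateral_mm),
                            config$roi_scale * cfg$mass_semi_axes, role = "tissue")
  validate_roi_pair(mass_roi, tissue_roi)
  frames <- list()
  if ("fundamental" %in% config$bands) frames$fundamental <- make_fundamental(sc$pair)
  if ("harmonic" %in% config$bands) frames$harmonic <- make_harmonic(sc$pair)
  out <- list()
  for (band in names(frames)) {
    fb <- form_band_images(frames[[band]], config)
    loc <- mean_loc(fb$loc_map, mass_roi)
    bmode <- fb$images[["B-mode"]]
    for (mode in names(fb$images)) {
      img <- fb$images[[mode]]
      ctr <- contrast(img, mass_roi, tissue_roi)
      cd <- if (mode == "B-mode") NA_real_ else {
        contrast_difference(bmode, img, mass_roi, tissue_roi)
      }
      gc <- as.numeric(gcnr(img, mass_roi, tissue_roi))
      labs <- classify_mass(list(mean_loc = loc, contrast_difference = cd,
                                 gcnr = gc), config$thresholds)
      out[[length(out) + 1L]] <- data.frame(
        scene_id = i, mass_kind = cfg$mass_kind, truth = sc$truth,
        band = band, mode = mode,
        contrast_db = ctr, contrast_difference_db = cd,
        mean_loc = loc, gcnr = gc,
        label_loc = labs[["mean_loc"]],
        label_cd = if (mode == "B-mode") NA_character_ else labs[["contrast_difference"]],
        label_gcnr = labs[["gcnr"]],
        stringsAsFactors = FALSE)
    }
    if (!is.null(config$output_dir) && config$write_images) {
      export_images(fb$images, config, i, band)
    }
  }
  do.call(rbind, out)
}

summarize_confusion <- function(metrics, config) {
  considered <- metrics[metrics$truth %in% c("fluid", "solid"), , drop = FALSE]
  rows <- list()
  add <- function(metric, band, mode, truth, pred) {
    cc <- confusion_counts(truth, pred)
    ss <- sensitivity_specificity(cc)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, band = band, mode = mode,
      TP = cc$TP, FN = cc$FN, TN = cc$TN, FP = cc$FP,
      sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
      stringsAsFactors = FALSE)
  }
  for (band in unique(considered$band)) {
    bsub <- considered[considered$band == band, , drop = FALSE]
    # LOC is a per-band metric: one value per scene
    first <- bsub[!duplicated(bsub$scene_id), , drop = FALSE]
    add("mean_loc", band, "(band)", first$truth, first$label_loc)
    for (mode in setdiff(unique(bsub$mode), "B-mode")) {
      msub <- bsub[bsub$mode == mode, , drop = FALSE]
      add("contrast_difference", band, mode, msub$truth, msub$label_cd)
      add("gcnr", band, mode, msub$truth, msub$label_gcnr)
    }
    if ("B-mode" %in% bsub$mode) {
      msub <- bsub[bsub$mode == "B-mode", , drop = FALSE]
      add("gcnr", band, "B-mode", msub$truth, msub$label_gcnr)
    }
  }
  do.call(rbind, rows)
}

write_report <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(config$output_dir, name),
                                row.names = FALSE)
  }
  wr(report$metrics, "metrics.csv")
  wr(report$confusion, "confusion.csv")
  wr(report$manifest, "cohort_manifest.csv")
  wr(report$failures, "failures.csv")
  cfg_json <- file.path(config$output_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "slscbf",
    version = as.character(utils::packageVersion("slscbf")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    n_scenes = nrow(report$manifest),
    n_failures = if (is.null(report$failures)) 0L else nrow(report$failures))
  jsonlite::write_json(manifest, file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

serialize_config <- function(config) {
  keep <- setdiff(names(config), "cohort")
  out <- lapply(unclass(config)[keep], function(x) if (is.list(x)) unclass(x) else x)
  if (!is.null(config$cohort)) {
    out$cohort_seed <- config$cohort$seed
    out$cohort_geometry <- unclass(config$cohort$geometry)
    out$cohort_n <- nrow(config$cohort$manifest)
  }
  out
}

export_images <- function(images, config, scene_id, band) {
  for (mode in names(images)) {
    disp <- display_process(images[[mode]], config$dynamic_range_db)
    fn <- file.path(config$output_dir,
                    sprintf("scene%03d_%s_%s.png", scene_id, band,
                            gsub("[^A-Za-z]", "", mode)))
    grDevices::png(fn, width = 480, height = 480)
    op <- graphics::par(mar = c(2, 2, 2, 1))
    graphics::image(t(disp$values)[, rev(seq_len(nrow(disp$values)))],
                    col = grDevices::gray.colors(256, 0, 1),
                    zlim = c(-config$dynamic_range_db, 0), axes = FALSE,
                    main = sprintf("%s %s (%g dB)", band, mode,
                                   config$dynamic_range_db))
    graphics::par(op)
    grDevices::dev.off()
  }
}

#' @export
print.comparison_report <- function(x, ...) {
  nsc <- length(unique(x$metrics$scene_id))
  cat(sprintf("Imaging-mode comparison: %d scenes evaluated, %d metric rows, %d failures\n",
              nsc, NROW(x$metrics), NROW(x$failures)))
  if (!is.null(x$confusion)) {
    cat("Sensitivity/specificity per metric, band, mode:\n")
    print(x$confusion, row.names = FALSE)
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write cohort frame containers + manifest),
#' `report`/`all` (run the full comparison from a JSON config), `metrics`
#' (alias of `report`).  A JSON config file may provide `n_fluid`, `n_solid`,
#' `seed`, `output_dir` and any [run_config()] scalar field.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
slscbf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: slscbf <simulate|report|all> --config config.json [--out dir]\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opts <- list()
  rest <- args[-1L]
  while (length(rest) >= 2L) {
    key <- sub("^--", "", rest[[1L]])
    opts[[key]] <- rest[[2L]]
    rest <- rest[-(1:2)]
  }
  cfgl <- if (!is.null(opts$config)) jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
  out_dir <- opts$out %||% cfgl$output_dir %||% "slscbf_out"
  seed <- as.integer(opts$seed %||% cfgl$seed %||% 1L)
  cohort <- make_cohort(as.integer(cfgl$n_fluid %||% 7L),
                        as.integer(cfgl$n_solid %||% 28L),
                        parameter_ranges = cfgl$parameter_ranges %||% list(),
                        seed = seed)
  status <- 0L
  if (cmd == "simulate") {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$manifest))) {
      sc <- realize_scene(cohort, i)
      write_frame(make_fundamental(sc$pair),
                  file.path(out_dir, sprintf("scene%03d_fundamental.slscbf", i)))
      write_frame(make_harmonic(sc$pair),
                  file.path(out_dir, sprintf("scene%03d_harmonic.slscbf", i)))
    }
    write.csv(cohort$manifest, file.path(out_dir, "cohort_manifest.csv"),
              row.names = FALSE)
  } else if (cmd %in% c("report", "metrics", "all", "beamform")) {
    rc_args <- cfgl[intersect(names(cfgl),
                              c("M_slsc", "M_weighted", "kernel_length",
                                "dynamic_range_db", "bands", "modes",
                                "roi_scale", "tissue_lateral_mm"))]
    rc_args$cohort <- cohort
    rc_args$seed <- seed
    rc_args$output_dir <- out_dir
    rc_args$write_images <- isTRUE(cfgl$write_images) || cmd == "all"
    rep <- do.call(run_config, rc_args)
    res <- run_comparison(rep)
    print(res)
    if (!is.null(res$failures) && nrow(res$failures)) status <- 1L
  } else {
    cat(sprintf("slscbf: unknown command '%s'\n", cmd))
    status <- 2L
  }
  invisible(status)
}
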