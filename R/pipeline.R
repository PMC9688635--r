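#' Run the full staining-analysis pipeline
#'
#' Ties the stages together for a first/last compartment pair: background
#' estimation, segmentation, band differences, classification, per-class
#' summary, area-ratio counting and transport efficiency. Inputs are either
#' two image files (or arrays) or, when omitted, a simulated compartment
#' pair drawn from the configuration's `simulate` section. The run is
#' deterministic given the configuration seed, and the returned report
#' embeds the configuration together with its hash and the package version.
#'
#' @param config a `pipeline_config`, a path to a YAML configuration, or a
#'   plain list (see [as_pipeline_config()]). Default:
#'   [default_pipeline_config()].
#' @param first,last first/last compartment images - file paths or
#'   `rows x cols x 3` arrays. When both are `NULL` the pair is simulated.
#' @param out_dir optional directory; when given, `report.json` and
#'   per-compartment object CSVs are written there.
#' @return report list with elements `package_version`, `config`,
#'   `config_hash`, `compartments` (per-compartment stage outputs) and
#'   `efficiency`.
#' @examples
#' \donttest{
#' rep <- run_pipeline()
#' rep$efficiency$efficiency_pct
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         first = NULL, last = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config") || is.null(config$optics_profile)) {
    config <- as_pipeline_config(unclass(config))
  }

  truth <- NULL
  if (is.null(first) && is.null(last)) {
    sim <- config$simulate
    if (is.null(sim)) stop("no images given and no 'simulate' section in config")
    pair <- make_compartment_pair(
      density = if (is.null(sim$density)) "ultra_low" else sim$density,
      loss_fraction = if (is.null(sim$loss_fraction)) 0 else sim$loss_fraction,
      seed = config$seed, first_count = sim$first_count,
      optics = config$optics_profile
    )
    pipeline_log("simulating compartment pair: %d -> %d cells",
                 pair$first_cells, pair$last_cells)
    fr <- render_scene(pair$first)
    lr <- render_scene(pair$last)
    first <- fr$image; last <- lr$image
    truth <- list(first = fr$truth, last = lr$truth,
                  first_cells = pair$first_cells, last_cells = pair$last_cells)
  } else {
    if (is.character(first)) first <- read_image(first)
    if (is.character(last)) last <- read_image(last)
  }

  comp <- list(
    first = analyze_compartment(first, config, "first"),
    last = analyze_compartment(last, config, "last")
  )
  eff <- transport_efficiency(comp$first$report, comp$last$report)
  pipeline_log("transport efficiency %.2f%% (loss %.2f%%)",
               eff$efficiency_pct, eff$loss_pct)

  cfg_public <- unclass(config)
  cfg_public$optics_profile <- NULL
  cfg_public$profile_objects <- NULL
  report <- list(
    package_version = as.character(utils::packageVersion("stainsight")),
    config = cfg_public,
    config_hash = rlang::hash(cfg_public),
    compartments = comp,
    efficiency = unclass(eff),
    truth = truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"))
    for (nm in names(comp)) {
      write_objects_csv(comp[[nm]]$objects, file.path(out_dir, paste0(nm, "_objects.csv")),
                        classes = comp[[nm]]$classes)
    }
  }
  report
}

# One compartment image through background -> segmentation -> color
# analysis -> counting.
analyze_compartment <- function(image, config, compartment) {
  stopifnot(length(dim(image)) == 3L)
  bg <- estimate_background(image)
  objs <- segment_objects(image, bg,
                          min_deficit = config$segmentation$min_deficit,
                          min_object_area = config$segmentation$min_object_area)
  pipeline_log("[%s] %d regions, background (%.1f, %.1f, %.1f)",
               compartment, nrow(objs), bg$mean_rgb[1], bg$mean_rgb[2], bg$mean_rgb[3])
  rule <- classification_rules(config$profile_objects,
                               stage1_min_deficit = config$rules$stage1_min_deficit)
  d <- band_differences(objs, bg)
  classes <- if (nrow(objs) > 0L) classify_objects(d, rule) else character(0)
  summary <- if (nrow(objs) > 0L) {
    summarize_differences(d, classes, min_n = config$quantification$min_n,
                          allow_fewer = TRUE)
  } else {
    NULL
  }
  mca <- tryCatch(
    mean_cell_area(objs, classes = classes,
                   cluster_cutoff = config$quantification$cluster_cutoff),
    error = function(e) NA_real_
  )
  report <- if (is.finite(mca)) {
    estimate_count(objs, mca, compartment = compartment,
                   ultra_low_max = config$quantification$ultra_low_max)
  } else {
    estimate_count(objs[0, , drop = FALSE], 1, compartment = compartment,
                   ultra_low_max = config$quantification$ultra_low_max)
  }
  list(background = bg, objects = objs, differences = d, classes = classes,
       summary = summary, report = report)
}

# Status messages go to stderr so machine output on stdout stays clean.
pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[stainsight] ", fmt), ...))
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("Background estimate (%s): mean (%.1f, %.1f, %.1f), sd (%.1f, %.1f, %.1f), %d px\n",
              x$method, x$mean_rgb[1], x$mean_rgb[2], x$mean_rgb[3],
              x$sd_rgb[1], x$sd_rgb[2], x$sd_rgb[3], x$n_pixels))
  invisible(x)
}

#' @export
print.compartment_report <- function(x, ...) {
  cat(sprintf("Compartment '%s': %d regions, conjugate area %d px, mean cell area %.1f px\n",
              x$compartment, x$n_regions, x$total_conjugate_area_px, x$mean_cell_area_px))
  cat(sprintf("  estimated count %.1f (density: %s)\n", x$estimated_count, x$density))
  invisible(x)
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Transport efficiency %.2f%% (loss %.2f%%)%s\n",
              x$efficiency_pct, x$loss_pct,
              if (x$flagged) " [flagged: > 100%]" else ""))
  invisible(x)
}
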