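#' Read an 8-bit RGB image
#'
#' Reads PNG or TIFF into the package's internal raster convention: a
#' numeric `rows x cols x 3` array on the 0-255 scale. Grayscale inputs are
#' replicated to three bands when `convert = TRUE` and rejected otherwise;
#' an alpha channel is dropped.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param convert replicate grayscale to RGB instead of rejecting
#'   (default TRUE).
#' @param pixel_scale optional micrometres-per-pixel to attach to the image.
#' @return numeric `rows x cols x 3` array, 0-255.
#' @export
read_image <- function(path, convert = TRUE, pixel_scale = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format: .", ext)
    ),
    error = function(e) stop("failed to read image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dim(x)) == 2L) {
    if (!convert) stop("grayscale input rejected (convert = FALSE): ", path)
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  } else if (dim(x)[3] == 4L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (dim(x)[3] == 2L) {
    if (!convert) stop("gray+alpha input rejected (convert = FALSE): ", path)
    x <- array(rep(x[, , 1], 3L), dim = c(dim(x)[1:2], 3L))
  }
  out <- round(x * 255)
  if (!is.null(pixel_scale)) attr(out, "pixel_scale") <- pixel_scale
  out
}

#' Write an image as 8-bit PNG or TIFF
#'
#' @param image numeric `rows x cols x 3` array, 0-255.
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  x <- round(pmin(pmax(image, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write segmented objects (optionally with classes) to CSV
#'
#' @param objects [segmented_objects][segment_objects] data frame.
#' @param path output CSV path.
#' @param classes optional class labels added as a `class` column.
#' @return `path`, invisibly.
#' @export
write_objects_csv <- function(objects, path, classes = NULL) {
  df <- as.data.frame(objects)
  if (!is.null(classes)) df$class <- classes
  bg <- attr(objects, "background")
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(bg)) {
    meta <- sub("\\.csv$", ".background.json", path)
    jsonlite::write_json(list(mean_rgb = unname(bg$mean_rgb),
                              sd_rgb = unname(bg$sd_rgb), method = bg$method),
                         meta, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a per-object CSV back into a segmented-objects table
#'
#' @param path CSV written by [write_objects_csv()].
#' @return data frame; a `.background.json` sidecar, when present, is
#'   restored as the `background` attribute.
#' @export
read_objects_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- sub("\\.csv$", ".background.json", path)
  if (file.exists(meta)) {
    bgl <- jsonlite::read_json(meta, simplifyVector = TRUE)
    attr(df, "background") <- structure(
      list(mean_rgb = stats::setNames(bgl$mean_rgb, c("R", "G", "B")),
           sd_rgb = stats::setNames(bgl$sd_rgb, c("R", "G", "B")),
           method = bgl$method, n_pixels = NA_integer_, frac_pixels = NA_real_),
      class = "background_estimate")
  }
  class(df) <- c("segmented_objects", "data.frame")
  df
}

#' Write a pipeline report as JSON
#'
#' Reports are written as UTF-8 JSON with stable key ordering (the order in
#' which the report was assembled) and full numeric precision.
#'
#' @param report a list, e.g. from [run_pipeline()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(jsonable(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# Strip classes/attributes jsonlite cannot serialize faithfully.
jsonable <- function(x) {
  if (inherits(x, "table")) return(as.list(stats::setNames(as.numeric(x), names(x))))
  if (is.data.frame(x)) {
    attrs_keep <- x[]
    return(as.data.frame(lapply(attrs_keep, function(col) col)))
  }
  if (is.list(x)) return(lapply(unclass(x), jsonable))
  if (is.function(x)) return(NULL)
  x
}

#' Default pipeline configuration
#'
#' The fully populated configuration the pipeline runs with when no file is
#' given: optics preset, the bundled stain-profile deficits, the
#' classification rule parameters, segmentation and quantification settings,
#' and the seed. A YAML rendering of the same defaults ships at
#' `system.file("extdata", "default_config.yaml", package = "stainsight")`.
#'
#' @param seed integer seed recorded in the configuration.
#' @return object of class `pipeline_config` (a named list).
#' @export
default_pipeline_config <- function(seed = 1L) {
  profs <- stain_profiles()
  structure(
    list(
      seed = as.integer(seed),
      optics = "microscope_4x",
      profiles = lapply(profs, function(p) {
        list(deficit_rgb = unname(p$deficit_rgb), is_stain = p$is_stain)
      }),
      rules = list(stage1_min_deficit = 10),
      segmentation = list(min_deficit = 10, min_object_area = NULL),
      quantification = list(ultra_low_max = 1000, cluster_cutoff = 1.6,
                            r2_min = 0.95, min_n = 20),
      simulate = list(density = "ultra_low", loss_fraction = 0.19)
    ),
    class = "pipeline_config"
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Missing sections fall back to [default_pipeline_config()] values, except
#' the rule table, which must be present (explicitly or via the defaults
#' flag `use_default_rules: true`).
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop("malformed config '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  as_pipeline_config(y)
}

#' @rdname read_pipeline_config
#' @param x a named list of configuration values.
#' @export
as_pipeline_config <- function(x) {
  stopifnot(is.list(x))
  def <- default_pipeline_config()
  if (is.null(x$rules) && !isTRUE(x$use_default_rules)) {
    stop("configuration error: missing rule table ('rules:' section)")
  }
  cfg <- utils::modifyList(unclass(def), x[setdiff(names(x), "use_default_rules")])
  if (is.character(cfg$optics)) {
    cfg$optics_profile <- optics_preset(cfg$optics)
  } else {
    cfg$optics_profile <- do.call(optics_profile, cfg$optics)
  }
  cfg$profile_objects <- profiles_from_config(cfg$profiles)
  class(cfg) <- "pipeline_config"
  cfg
}

profiles_from_config <- function(pl) {
  out <- lapply(names(pl), function(nm) {
    p <- pl[[nm]]
    stain_profile(nm, p$deficit_rgb,
                  is_stain = if (is.null(p$is_stain)) TRUE else p$is_stain)
  })
  stats::setNames(out, names(pl))
}
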