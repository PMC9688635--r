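#' Optics profile for a synthetic imaging modality
#'
#' Describes the imaging conditions of a bright-field acquisition: the mean
#' background intensity per color band, the per-pixel Gaussian noise level,
#' an optional Gaussian blur, the physical pixel scale and the raster size.
#' Bright-field chip images show a near-uniform light background with a mean
#' intensity close to 225 in every band; the bundled presets all share that
#' background level and differ in pixel scale (objective magnification) and,
#' for the phone modality, in resolution and noise.
#'
#' @param background_mean_rgb numeric length-3, mean background intensity per
#'   band on the 8-bit scale (default `c(225, 225, 225)`).
#' @param noise_sd per-pixel Gaussian noise standard deviation, intensity
#'   units (default 3).
#' @param blur_sigma Gaussian blur sigma in pixels applied after painting
#'   (default 0: objects keep hard, exactly countable edges).
#' @param pixel_scale physical size of one pixel in micrometres.
#' @param image_shape integer length-2, raster size as `c(rows, cols)`.
#' @param modality `"microscope"` or `"phone"`.
#' @return An object of class `optics_profile`.
#' @seealso [optics_preset()] for the bundled presets.
#' @export
optics_profile <- function(background_mean_rgb = c(225, 225, 225),
                           noise_sd = 3,
                           blur_sigma = 0,
                           pixel_scale = 0.65,
                           image_shape = c(512L, 512L),
                           modality = c("microscope", "phone")) {
  modality <- match.arg(modality)
  background_mean_rgb <- as.numeric(background_mean_rgb)
  if (length(background_mean_rgb) == 1L) {
    background_mean_rgb <- rep(background_mean_rgb, 3L)
  }
  stopifnot(
    length(background_mean_rgb) == 3L,
    all(background_mean_rgb >= 0), all(background_mean_rgb <= 255),
    is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
    is.numeric(blur_sigma), length(blur_sigma) == 1L, blur_sigma >= 0,
    is.numeric(pixel_scale), length(pixel_scale) == 1L, pixel_scale > 0,
    length(image_shape) == 2L, all(image_shape >= 8)
  )
  structure(
    list(
      background_mean_rgb = background_mean_rgb,
      noise_sd = noise_sd,
      blur_sigma = blur_sigma,
      pixel_scale = pixel_scale,
      image_shape = as.integer(image_shape),
      modality = modality
    ),
    class = "optics_profile"
  )
}

#' Bundled optics presets
#'
#' Presets for the objectives used to inspect the visualization compartment
#' (4x, 10x, 20x, 50x) and for a low-resolution phone-camera rendering of the
#' chip. Pixel scales are package defaults chosen to be representative of a
#' CCD camera behind each objective; they are configurable, not measured
#' values. The phone preset has a coarser pixel scale than every microscope
#' preset and slightly different noise, reflecting the lower resolution of a
#' handheld capture.
#'
#' @param name one of `"microscope_4x"`, `"microscope_10x"`,
#'   `"microscope_20x"`, `"microscope_50x"`, `"phone"`.
#' @return An [optics_profile()].
#' @examples
#' optics_preset("microscope_10x")$pixel_scale
#' @export
optics_preset <- function(name = c("microscope_10x", "microscope_4x",
                                   "microscope_20x", "microscope_50x",
                                   "phone")) {
  name <- match.arg(name)
  switch(name,
    microscope_4x  = optics_profile(pixel_scale = 1.60),
    microscope_10x = optics_profile(pixel_scale = 0.65),
    microscope_20x = optics_profile(pixel_scale = 0.33),
    microscope_50x = optics_profile(pixel_scale = 0.13),
    phone = optics_profile(pixel_scale = 6.4, noise_sd = 2, blur_sigma = 0.7,
                           image_shape = c(128L, 128L), modality = "phone")
  )
}

#' Stain profile: per-band intensity deficit of an object class
#'
#' A stain profile records how much darker an object class is than the
#' background in each color band (`deficit_rgb = background mean - object
#' mean`, in 8-bit intensity units). The bundled profiles cover
#' immunomagnetic beads, unstained cells, and cells stained with the four
#' basic dyes trypan blue (TB), safranin, methylene blue (MB) and crystal
#' violet (CV). The dominant band of a stain is the band of the dye's own
#' hue: it stays brightest in the stained cell and therefore has the
#' *smallest* deficit.
#'
#' @param name class name, one of `"bead"`, `"unstained"`, `"TB"`,
#'   `"safranin"`, `"MB"`, `"CV"`, or a custom label.
#' @param deficit_rgb numeric length-3, non-negative per-band deficit.
#' @param is_stain logical; stained-cell classes get a dominant band.
#' @return An object of class `stain_profile` with fields `name`,
#'   `deficit_rgb`, `dominant_band` (`NA` for non-stains), `dominant_tie`.
#' @export
stain_profile <- function(name, deficit_rgb, is_stain = TRUE) {
  deficit_rgb <- as.numeric(deficit_rgb)
  stopifnot(length(deficit_rgb) == 3L, all(deficit_rgb >= 0),
            is.character(name), length(name) == 1L)
  dom <- NA_character_
  tie <- FALSE
  if (is_stain) {
    db <- dominant_band(deficit_rgb)
    dom <- db$band
    tie <- db$tie
  }
  structure(
    list(name = name, deficit_rgb = stats::setNames(deficit_rgb, c("R", "G", "B")),
         is_stain = is_stain, dominant_band = dom, dominant_tie = tie),
    class = "stain_profile"
  )
}

#' Bundled stain profiles
#'
#' The default per-band deficits for the six object classes seen in the chip's
#' visualization compartment. Deficits are relative to the nominal background
#' mean of 225 per band. Even the unstained cell, the class closest to the
#' background, is at least 15 intensity units darker in every band; the
#' stained classes span deficits from 25 to 135.
#'
#' @return Named list of [stain_profile()] objects:
#'   `bead`, `unstained`, `TB`, `safranin`, `MB`, `CV`.
#' @examples
#' stain_profiles()$TB$deficit_rgb
#' @export
stain_profiles <- function() {
  list(
    bead      = stain_profile("bead",      c(125, 120, 140), is_stain = FALSE),
    unstained = stain_profile("unstained", c(15,  15,  30),  is_stain = FALSE),
    TB        = stain_profile("TB",        c(50,  40,  40)),
    safranin  = stain_profile("safranin",  c(25,  135, 100)),
    MB        = stain_profile("MB",        c(100, 100, 45)),
    CV        = stain_profile("CV",        c(100, 115, 30))
  )
}

#' Default object diameters in micrometres
#'
#' Beads are 4.5 um superparamagnetic spheres. The K562 cell diameter is a
#' configurable package default of 15 um; patient-derived lymphocytes are
#' about 2.5 times smaller than K562 cells, giving 6 um.
#'
#' @return Named numeric vector with entries `bead`, `K562`, `lymphocyte`.
#' @export
default_diameters <- function() {
  k562 <- 15
  c(bead = 4.5, K562 = k562, lymphocyte = k562 / 2.5)
}

#' Dominant color band of a stained cell
#'
#' The dominant band is the band of the dye's own color: it remains the
#' brightest band of the stained cell, i.e. the band with the minimum
#' difference-from-background. For example a safranin-stained cell with
#' deficits (25, 135, 100) is dominated by red; a crystal-violet-stained cell
#' with deficits (100, 115, 30) by blue. Ties are broken in R > G > B
#' priority and flagged.
#'
#' @param d numeric length-3 deficit triple `(d_R, d_G, d_B)`, or a
#'   `band_differences` row.
#' @return list with `band` (`"R"`, `"G"` or `"B"`) and `tie` (logical).
#' @export
dominant_band <- function(d) {
  d <- as_deficit_triple(d)
  i <- which(d == min(d))
  list(band = c("R", "G", "B")[i[1L]], tie = length(i) > 1L)
}

# Coerce a triple-like input (numeric vector, 1-row data.frame with
# d_r/d_g/d_b or mean_r/mean_g/mean_b columns) to an unnamed numeric triple.
as_deficit_triple <- function(d) {
  if (is.data.frame(d)) {
    cols <- intersect(c("d_r", "d_g", "d_b"), names(d))
    if (length(cols) != 3L) cols <- intersect(c("mean_r", "mean_g", "mean_b"), names(d))
    stopifnot(length(cols) == 3L, nrow(d) == 1L)
    d <- as.numeric(d[1L, cols])
  }
  d <- as.numeric(d)
  stopifnot(length(d) == 3L)
  unname(d)
}
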