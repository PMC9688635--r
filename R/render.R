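#' Render a synthetic bright-field scene with exact ground truth
#'
#' Draws the scene described by a [scene_spec()]: a light background field
#' (independent per-band Gaussian noise around the optics' background mean)
#' on which each object is painted as a filled disk whose interior is darker
#' than the background by its stain profile's per-band deficit. Objects are
#' painted in order, later objects overwriting earlier ones where disks
#' overlap, and the whole field is optionally Gaussian-blurred and clipped to
#' `[0, 255]`.
#'
#' The returned ground truth records, per object, the exact painted disk
#' area in pixels and the deficit applied, and, in totals, the exact pixel
#' union of all object disks (`total_object_area_px`), counts per class, and
#' the mean single-cell disk area over non-bead objects. With zero noise and
#' zero blur, the interior mean of every disk equals
#' `background_mean - deficit` exactly.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` (numeric `rows x cols x 3` array on the
#'   0-255 scale, with attributes `pixel_scale`, `background_mean_rgb` and
#'   `modality`) and `truth` (list with `objects` data frame and `totals`).
#' @examples
#' sc <- render_scene(scene_spec(counts = c(TB = 3), seed = 1))
#' dim(sc$image)
#' sc$truth$totals$n_by_kind
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  optics <- spec$optics
  shape <- optics$image_shape
  with_scene_seed(spec$seed, {
    objects <- if (is.null(spec$objects)) place_objects(spec) else spec$objects
    if (is.null(objects$cluster_id)) objects$cluster_id <- NA_integer_

    n <- nrow(objects)
    npx <- prod(shape)
    noise <- if (optics$noise_sd > 0) {
      array(stats::rnorm(npx * 3, 0, optics$noise_sd), dim = c(shape, 3L))
    } else {
      array(0, dim = c(shape, 3L))
    }

    deficit <- array(0, dim = c(shape, 3L))
    union_mask <- matrix(FALSE, shape[1], shape[2])
    area_px <- integer(n)
    defs <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      kind <- objects$kind[i]
      prof <- spec$profiles[[kind]]
      if (is.null(prof)) stop("no stain profile for kind: ", kind)
      idx <- disk_pixels(objects$row[i], objects$col[i],
                         objects$diameter_um[i] / 2 / optics$pixel_scale, shape)
      area_px[i] <- nrow(idx)
      defs[i, ] <- prof$deficit_rgb
      if (nrow(idx) > 0L) {
        lin <- idx[, 1L] + (idx[, 2L] - 1L) * shape[1]
        union_mask[lin] <- TRUE
        for (b in 1:3) deficit[lin + (b - 1L) * npx] <- prof$deficit_rgb[b]
      }
    }

    img <- array(0, dim = c(shape, 3L))
    for (b in 1:3) {
      img[, , b] <- optics$background_mean_rgb[b] + noise[, , b] - deficit[, , b]
    }
    if (optics$blur_sigma > 0) img <- blur_rgb(img, optics$blur_sigma)
    # quantize to the 8-bit grid an actual camera would deliver
    img <- round(pmin(pmax(img, 0), 255))
    attr(img, "pixel_scale") <- optics$pixel_scale
    attr(img, "background_mean_rgb") <- optics$background_mean_rgb
    attr(img, "modality") <- optics$modality

    obj_df <- data.frame(
      label = seq_len(n), kind = objects$kind,
      row = objects$row, col = objects$col,
      diameter_um = objects$diameter_um, area_px = area_px,
      d_r = defs[, 1], d_g = defs[, 2], d_b = defs[, 3],
      cluster_id = objects$cluster_id
    )
    is_cell <- obj_df$kind != "bead"
    truth <- list(
      objects = obj_df,
      totals = list(
        n_by_kind = table(factor(obj_df$kind)),
        total_object_area_px = sum(union_mask),
        mean_cell_area_px = if (any(is_cell)) mean(obj_df$area_px[is_cell]) else NA_real_
      )
    )
    list(image = img, truth = truth)
  })
}

# Integer (row, col) pixel indices whose centres lie within radius_px of
# (row0, col0), clipped to the image. Pixel centres are at integer coords.
disk_pixels <- function(row0, col0, radius_px, shape) {
  r0 <- max(1L, floor(row0 - radius_px))
  r1 <- min(shape[1], ceiling(row0 + radius_px))
  c0 <- max(1L, floor(col0 - radius_px))
  c1 <- min(shape[2], ceiling(col0 + radius_px))
  if (r1 < r0 || c1 < c0) return(cbind(integer(0), integer(0)))
  rr <- r0:r1
  cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - row0)^2 + (g$col - col0)^2 <= radius_px^2
  cbind(g$row[keep], g$col[keep])
}

# Gaussian blur of a rows x cols x 3 intensity array (0-255 scale).
blur_rgb <- function(img, sigma) {
  x <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  y <- EBImage::gblur(x, sigma = sigma)
  aperm(as.array(y), c(2, 1, 3)) * 255
}

#' Render a phone-camera view of a microscope image
#'
#' Emulates re-imaging the field with a low-resolution phone camera: the
#' image is anti-alias blurred, downsampled to the phone pixel scale, and a
#' small amount of sensor noise is added. The phone pixel scale must be
#' coarser than the source image's.
#'
#' @param image an image array produced by [render_scene()] (or any
#'   `rows x cols x 3` array with a `pixel_scale` attribute).
#' @param optics phone [optics_profile()]; default [optics_preset]`("phone")`.
#' @param seed integer seed for the added sensor noise.
#' @return image array at phone resolution, same attribute conventions.
#' @export
render_phone_view <- function(image, optics = optics_preset("phone"), seed = 0L) {
  src_scale <- attr(image, "pixel_scale")
  if (is.null(src_scale)) stop("image has no pixel_scale attribute")
  k <- optics$pixel_scale / src_scale
  if (k <= 1) {
    stop(sprintf(
      "phone pixel_scale (%.3g um/px) must be coarser than the source (%.3g um/px)",
      optics$pixel_scale, src_scale))
  }
  sm <- blur_rgb(image, sigma = max(k / 2, optics$blur_sigma))
  new_shape <- pmax(c(8L, 8L), as.integer(floor(dim(image)[1:2] / k)))
  x <- EBImage::Image(aperm(sm, c(2, 1, 3)) / 255, colormode = "Color")
  y <- EBImage::resize(x, w = new_shape[2], h = new_shape[1])
  out <- aperm(as.array(y), c(2, 1, 3)) * 255
  out <- with_scene_seed(seed, {
    out + array(stats::rnorm(length(out), 0, optics$noise_sd), dim = dim(out))
  })
  out <- round(pmin(pmax(out, 0), 255))
  attr(out, "pixel_scale") <- optics$pixel_scale
  attr(out, "background_mean_rgb") <- attr(image, "background_mean_rgb")
  attr(out, "modality") <- "phone"
  out
}

#' Paired first/last compartment scenes with a known conjugate loss
#'
#' Builds two scene specs emulating the first and last chip compartments of
#' a magnet-driven transport run: the last compartment holds
#' `round(first * (1 - loss_fraction))` cells, while free-bead content is
#' preserved. The default first-compartment cell counts are scene-scale
#' stand-ins for the chip's density classes (a full compartment at high
#' density holds thousands of conjugates; a single field of view shows tens
#' to low hundreds).
#'
#' @param density density class preset: `"ultra_low"` (95 cells), `"low"`
#'   (60), `"medium"` (90), `"high"` (120). Ignored when `first_count` given.
#' @param loss_fraction fraction of conjugates lost in transport, in `[0, 1)`.
#' @param seed integer seed; the two scenes get derived sub-seeds.
#' @param first_count optional explicit first-compartment cell count.
#' @param optics optics for both scenes (default `microscope_4x`, the
#'   objective used for focal-plane density analysis).
#' @param stain stain profile name for the cells (default `"TB"`).
#' @param n_beads free beads present in both compartments (default 15).
#' @return list with `first` and `last` [scene_spec()]s and the integer
#'   `first_cells` / `last_cells` counts.
#' @examples
#' pr <- make_compartment_pair("ultra_low", loss_fraction = 0.19, seed = 1)
#' c(pr$first_cells, pr$last_cells)
#' @export
make_compartment_pair <- function(density = c("ultra_low", "low", "medium", "high"),
                                  loss_fraction, seed = 1L,
                                  first_count = NULL,
                                  optics = optics_preset("microscope_4x"),
                                  stain = "TB", n_beads = 15L) {
  stopifnot(is.numeric(loss_fraction), length(loss_fraction) == 1L,
            loss_fraction >= 0, loss_fraction < 1)
  if (is.null(first_count)) {
    density <- match.arg(density)
    first_count <- c(ultra_low = 95L, low = 60L, medium = 90L, high = 120L)[[density]]
  }
  first_count <- as.integer(first_count)
  last_count <- as.integer(round(first_count * (1 - loss_fraction)))
  mk <- function(n_cells, s) {
    counts <- c(n_cells, as.integer(n_beads))
    names(counts) <- c(stain, "bead")
    scene_spec(optics = optics, counts = counts[counts > 0],
               placement = "non_overlapping", seed = s)
  }
  list(first = mk(first_count, seed),
       last = mk(last_count, seed + 1L),
       first_cells = first_count, last_cells = last_count)
}
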