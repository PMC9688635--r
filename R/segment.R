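#' Estimate the background intensity of a bright-field image
#'
#' Bright-field chip images have a light, near-uniform background (nominal
#' mean 225 per band) against which cells and beads appear dark. Background
#' pixels are selected by Otsu's threshold on the luminance channel: pixels
#' above the threshold, eroded away from object borders, form the background
#' sample. When the luminance histogram is effectively unimodal (the two
#' Otsu classes differ by less than `min_separation`), the image is treated
#' as object-free and all pixels are used.
#'
#' @param image `rows x cols x 3` intensity array (0-255).
#' @param min_separation minimum Otsu class-mean separation (intensity
#'   units) required to believe the image contains objects; default 12,
#'   below the weakest object-class deficit of 15.
#' @param border_px background pixels closer than this to a foreground pixel
#'   are discarded, guarding against blur halos (default 2).
#' @return object of class `background_estimate`: list with `mean_rgb`,
#'   `sd_rgb` (named R/G/B), `method`, `n_pixels`, `frac_pixels`.
#' @export
estimate_background <- function(image, min_separation = 12, border_px = 2) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  thr <- EBImage::otsu(EBImage::Image(t(lum) / 255), range = c(0, 1)) * 255
  hi <- lum > thr
  method <- "otsu_luminance"
  if (!any(hi) || all(hi) ||
      mean(lum[hi]) - mean(lum[!hi]) < min_separation) {
    bg_mask <- matrix(TRUE, nrow(lum), ncol(lum))
    method <- "full_image"
  } else {
    fg <- EBImage::Image(t(!hi) * 1)
    if (border_px > 0) {
      fg <- EBImage::dilate(fg, EBImage::makeBrush(2L * as.integer(border_px) + 1L, "disc"))
    }
    bg_mask <- t(as.matrix(fg)) == 0
  }
  frac <- mean(bg_mask)
  if (frac < 0.10) {
    stop(sprintf("field too crowded: only %.1f%% candidate background pixels", 100 * frac))
  }
  m <- vapply(1:3, function(b) mean(image[, , b][bg_mask]), numeric(1))
  s <- vapply(1:3, function(b) stats::sd(image[, , b][bg_mask]), numeric(1))
  s[is.na(s)] <- 0
  structure(
    list(mean_rgb = stats::setNames(m, c("R", "G", "B")),
         sd_rgb = stats::setNames(s, c("R", "G", "B")),
         method = method, n_pixels = sum(bg_mask), frac_pixels = frac),
    class = "background_estimate"
  )
}

#' Segment dark objects from a bright-field image
#'
#' Foreground pixels are those darker than the estimated background by more
#' than `min_deficit` in *every* color band (all object classes - beads,
#' unstained and stained cells - have a positive deficit in all bands).
#' 8-connected components above `min_object_area` are returned with their
#' exact interior per-band means. Touching or overlapping objects merge into
#' a single region, matching how conjugate clusters are treated as one area.
#'
#' @param image `rows x cols x 3` intensity array (0-255).
#' @param bg a [background_estimate][estimate_background] for the same image;
#'   computed on the fly when omitted.
#' @param min_deficit minimum per-band difference from background for a
#'   foreground pixel (default 10, below the weakest class deficit of 15).
#' @param min_object_area minimum region area in pixels; default is the area
#'   of a 2 um disk at the image's pixel scale (debris filter).
#' @return data frame of class `segmented_objects`, one row per region:
#'   `label`, `area_px`, `centroid_r`, `centroid_c`, `r0`, `c0`, `r1`, `c1`
#'   (closed 1-based bounding box), `mean_r`, `mean_g`, `mean_b`. The
#'   background estimate and pixel scale travel along as attributes.
#' @examples
#' sc <- render_scene(scene_spec(counts = c(TB = 4), seed = 2))
#' segment_objects(sc$image)
#' @export
segment_objects <- function(image, bg = NULL, min_deficit = 10,
                            min_object_area = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (is.null(bg)) bg <- estimate_background(image)
  stopifnot(inherits(bg, "background_estimate"))
  if (is.null(min_object_area)) {
    px <- attr(image, "pixel_scale")
    min_object_area <- if (is.null(px)) 4L else max(1, round(pi * (1 / px)^2))
  }
  mask <- (bg$mean_rgb[1] - image[, , 1] > min_deficit) &
    (bg$mean_rgb[2] - image[, , 2] > min_deficit) &
    (bg$mean_rgb[3] - image[, , 3] > min_deficit)

  out <- data.frame(label = integer(0), area_px = integer(0),
                    centroid_r = numeric(0), centroid_c = numeric(0),
                    r0 = integer(0), c0 = integer(0),
                    r1 = integer(0), c1 = integer(0),
                    mean_r = numeric(0), mean_g = numeric(0),
                    mean_b = numeric(0))
  if (any(mask)) {
    lab <- label_components8(mask)
    keep_px <- lab > 0L
    labs <- lab[keep_px]
    area <- tabulate(labs)
    keep_lab <- which(area >= min_object_area)
    if (length(keep_lab) > 0L) {
      ri <- row(lab)[keep_px]
      ci <- col(lab)[keep_px]
      f <- factor(labs, levels = keep_lab)
      inc <- !is.na(f)
      f <- f[inc]; ri <- ri[inc]; ci <- ci[inc]
      mr <- image[, , 1][keep_px][inc]
      mg <- image[, , 2][keep_px][inc]
      mb <- image[, , 3][keep_px][inc]
      out <- data.frame(
        label = seq_along(keep_lab),
        area_px = as.integer(area[keep_lab]),
        centroid_r = as.numeric(tapply(ri, f, mean)),
        centroid_c = as.numeric(tapply(ci, f, mean)),
        r0 = as.integer(tapply(ri, f, min)),
        c0 = as.integer(tapply(ci, f, min)),
        r1 = as.integer(tapply(ri, f, max)),
        c1 = as.integer(tapply(ci, f, max)),
        mean_r = as.numeric(tapply(mr, f, mean)),
        mean_g = as.numeric(tapply(mg, f, mean)),
        mean_b = as.numeric(tapply(mb, f, mean))
      )
    }
  }
  rownames(out) <- NULL
  attr(out, "background") <- bg
  attr(out, "pixel_scale") <- attr(image, "pixel_scale")
  attr(out, "min_deficit") <- min_deficit
  class(out) <- c("segmented_objects", "data.frame")
  out
}

# 8-connected labeling of a logical matrix. EBImage::bwlabel is
# 4-connected; labels touching only diagonally are merged afterwards.
label_components8 <- function(mask) {
  lab <- t(as.matrix(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
  storage.mode(lab) <- "integer"
  nl <- max(lab)
  if (nl < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left neighbours
  pick <- function(a, b) {
    i <- a > 0L & b > 0L & a != b
    cbind(a[i], b[i])
  }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Crop a region of interest from an image
#'
#' @param image `rows x cols x 3` intensity array.
#' @param bbox integer length-4 `c(r0, c0, r1, c1)`, closed 1-based bounds.
#' @return the sub-image, retaining pixel-scale attributes. Segmenting the
#'   crop finds the same interior objects as segmenting the full image.
#' @export
crop_roi <- function(image, bbox) {
  stopifnot(length(dim(image)) == 3L, length(bbox) == 4L)
  bbox <- as.integer(bbox)
  d <- dim(image)
  if (bbox[1] < 1L || bbox[2] < 1L || bbox[3] > d[1] || bbox[4] > d[2]) {
    stop("bbox out of image bounds")
  }
  if (bbox[3] < bbox[1] || bbox[4] < bbox[2]) stop("empty bbox")
  out <- image[bbox[1]:bbox[3], bbox[2]:bbox[4], , drop = FALSE]
  for (a in c("pixel_scale", "background_mean_rgb", "modality")) {
    attr(out, a) <- attr(image, a)
  }
  out
}
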