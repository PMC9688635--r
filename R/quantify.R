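#' Density class of a cell count
#'
#' Bins a focal-plane cell count into the density classes used for chip
#' performance analysis: high (> 50,000 cells), medium (30,000-50,000), low
#' (< 30,000), plus an ultra-low regime below a configurable bound (default
#' 1,000). Counts exactly on a bound fall in the lower class.
#'
#' @param count non-negative cell count (may be fractional, as produced by
#'   the area-ratio estimator).
#' @param ultra_low_max upper bound of the ultra-low class (default 1000).
#' @return `"high"`, `"medium"`, `"low"` or `"ultra_low"`.
#' @examples
#' classify_density(60000)  # "high"
#' classify_density(40000)  # "medium"
#' @export
classify_density <- function(count, ultra_low_max = 1000) {
  stopifnot(is.numeric(count), length(count) == 1L, count >= 0)
  if (count < ultra_low_max) "ultra_low"
  else if (count <= 30000) "low"
  else if (count <= 50000) "medium"
  else "high"
}

#' Mean single-cell area from segmented objects
#'
#' The denominator of the area-ratio counter: the mean area of regions that
#' look like single cells. Regions above `cluster_cutoff` times the median
#' area are treated as conjugate clusters and excluded; an optional class
#' filter (from [classify_objects()]) restricts to cell classes, e.g.
#' excluding free beads.
#'
#' @param objects [segmented_objects][segment_objects] data frame.
#' @param classes optional character vector of class labels per object;
#'   rows with labels in `exclude_classes` are dropped before the area
#'   statistics.
#' @param exclude_classes labels that are not cells (default `"bead"`,
#'   `"background"`, `"unknown"`).
#' @param cluster_cutoff multiple of the median area above which a region is
#'   considered a cluster (default 1.6).
#' @return mean single-cell area in pixels.
#' @export
mean_cell_area <- function(objects, classes = NULL,
                           exclude_classes = c("bead", "background", "unknown"),
                           cluster_cutoff = 1.6) {
  area <- objects$area_px
  if (!is.null(classes)) {
    stopifnot(length(classes) == nrow(objects))
    area <- area[!(classes %in% exclude_classes)]
  }
  if (length(area) == 0L) {
    stop("no cell objects available; supply mean cell area manually")
  }
  single <- area[area <= cluster_cutoff * stats::median(area)]
  if (length(single) == 0L) {
    stop("no single-cell sized objects below the cluster cutoff; supply mean cell area manually")
  }
  mean(single)
}

#' Area-ratio cell count for one compartment image
#'
#' The focal-plane value: total conjugate-occupied area divided by the mean
#' single-cell area. This ratio behaves as a cell count and is invariant to
#' uniform rescaling of all areas, so it is comparable across images taken
#' at the same magnification.
#'
#' @param objects [segmented_objects][segment_objects] data frame (all
#'   detected regions contribute their area to the numerator).
#' @param mean_cell_area_px mean single-cell area in pixels (> 0); compute
#'   with [mean_cell_area()] or supply a manual calibration.
#' @param compartment `"first"` or `"last"` (annotation only).
#' @param ultra_low_max passed to [classify_density()].
#' @return object of class `compartment_report`: list with `compartment`,
#'   `total_conjugate_area_px`, `mean_cell_area_px`, `estimated_count`,
#'   `density`, `n_regions`, `pixel_scale`.
#' @examples
#' est <- estimate_count(data.frame(area_px = c(100, 110, 90)), 100)
#' est$estimated_count
#' @export
estimate_count <- function(objects, mean_cell_area_px,
                           compartment = c("first", "last"),
                           ultra_low_max = 1000) {
  compartment <- match.arg(compartment)
  stopifnot(is.numeric(mean_cell_area_px), length(mean_cell_area_px) == 1L)
  if (!(mean_cell_area_px > 0)) stop("mean cell area must be positive")
  total <- sum(objects$area_px)
  count <- total / mean_cell_area_px
  structure(
    list(compartment = compartment,
         total_conjugate_area_px = total,
         mean_cell_area_px = mean_cell_area_px,
         estimated_count = count,
         density = classify_density(count, ultra_low_max),
         n_regions = nrow(objects),
         pixel_scale = attr(objects, "pixel_scale")),
    class = "compartment_report"
  )
}

#' Conjugate transport efficiency between two compartments
#'
#' The percentage of the first compartment's focal-plane value retained in
#' the last compartment, `100 * last / first`; its complement is the
#' conjugate loss. Efficiencies above 100% (more material detected at the
#' end than at the start) are flagged, not clamped. Using estimated counts
#' rather than raw areas makes the figure robust to magnification
#' differences between the two images.
#'
#' @param first first-compartment `compartment_report` or a bare count.
#' @param last last-compartment `compartment_report` or a bare count.
#' @return object of class `efficiency_result`: list with `efficiency_pct`,
#'   `loss_pct` (always summing to 100), `flagged`, `first_count`,
#'   `last_count`.
#' @examples
#' transport_efficiency(95, 77)$efficiency_pct   # 81.05
#' transport_efficiency(8070, 7036)$efficiency_pct
#' @export
transport_efficiency <- function(first, last) {
  fc <- if (inherits(first, "compartment_report")) first$estimated_count else as.numeric(first)
  lc <- if (inherits(last, "compartment_report")) last$estimated_count else as.numeric(last)
  stopifnot(length(fc) == 1L, length(lc) == 1L, lc >= 0)
  if (!(fc > 0)) stop("first-compartment count must be positive")
  eff <- 100 * lc / fc
  structure(
    list(efficiency_pct = eff, loss_pct = 100 - eff, flagged = eff > 100,
         first_count = fc, last_count = lc),
    class = "efficiency_result"
  )
}

#' Linearity of the counter across input cell numbers
#'
#' Least-squares line of estimated count against input cell number, with a
#' verdict on whether the response is linear over the tested range (r-squared
#' at least `r2_min`, default 0.95). The chip counter is expected to be
#' linear between 5,000 and 50,000 input cells.
#'
#' @param points data frame with columns `input_cells` and
#'   `estimated_count`; at least 3 points.
#' @param r2_min r-squared threshold for the `"linear"` verdict.
#' @return list with `slope`, `intercept`, `r_squared`, `verdict`
#'   (`"linear"` / `"non_linear"`), `n`.
#' @examples
#' linearity_check(data.frame(input_cells = c(1, 2, 3), estimated_count = c(1, 2, 3)))
#' @export
linearity_check <- function(points, r2_min = 0.95) {
  stopifnot(is.data.frame(points),
            all(c("input_cells", "estimated_count") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 points for a linearity check")
  fit <- stats::lm(estimated_count ~ input_cells, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$estimated_count - mean(points$estimated_count))^2)
  # a flat response carries no linear information: report r2 = 0, not NaN
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       verdict = if (r2 >= r2_min) "linear" else "non_linear",
       n = nrow(points))
}
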