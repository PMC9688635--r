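#' Per-band difference from background
#'
#' The central stain-quantification statistic: for each object and each
#' color band c, `d_c = background mean - object mean`. Objects darker than
#' the background have positive differences; a trypan-blue-stained cell
#' against a 225 background with interior means (175, 185, 185) yields
#' `(50, 40, 40)`. The subtraction is exact and unclamped, so the statistic
#' is affine in the object mean.
#'
#' @param objects a [segmented_objects][segment_objects] data frame (uses its
#'   `mean_r`/`mean_g`/`mean_b` columns), or a numeric length-3 triple of
#'   object band means.
#' @param bg a [background_estimate][estimate_background], or a numeric
#'   length-3 triple of background band means. Defaults to the estimate
#'   attached to `objects` by [segment_objects()].
#' @return data frame with columns `label`, `d_r`, `d_g`, `d_b`.
#' @examples
#' band_differences(c(175, 185, 185), c(225, 225, 225))
#' @export
band_differences <- function(objects, bg = NULL) {
  if (is.null(bg)) bg <- attr(objects, "background")
  bgm <- if (inherits(bg, "background_estimate")) bg$mean_rgb else as.numeric(bg)
  stopifnot(length(bgm) == 3L)
  if (is.numeric(objects) && length(objects) == 3L) {
    objects <- data.frame(label = 1L, mean_r = objects[1],
                          mean_g = objects[2], mean_b = objects[3])
  }
  stopifnot(is.data.frame(objects),
            all(c("mean_r", "mean_g", "mean_b") %in% names(objects)))
  out <- data.frame(
    label = if ("label" %in% names(objects)) objects$label else seq_len(nrow(objects)),
    d_r = bgm[1] - objects$mean_r,
    d_g = bgm[2] - objects$mean_g,
    d_b = bgm[3] - objects$mean_b
  )
  attr(out, "background") <- bgm
  out
}

#' Build the two-stage classification rule table
#'
#' Stage 1 rejects anything within `stage1_min_deficit` of the background in
#' some band (background speckle and faint debris). Stage 2 assigns one of
#' the object classes by per-band intervals: for each band, the axis is
#' partitioned at the midpoints between adjacent distinct class deficits, and
#' a class's interval is the cell containing its own deficit. An object must
#' fall inside a class's interval in every band to be a candidate; among
#' candidates the nearest class profile in Euclidean deficit space wins.
#' The interval bounds are a calibration derived from the bundled class
#' profiles, not measured thresholds.
#'
#' @param profiles named list of [stain_profile()]s (default
#'   [stain_profiles()]).
#' @param stage1_min_deficit stage-1 rejection threshold (default 10).
#' @return object of class `classification_rule` with the class centers and
#'   per-band intervals.
#' @export
classification_rules <- function(profiles = stain_profiles(),
                                 stage1_min_deficit = 10) {
  stopifnot(length(profiles) >= 1L, stage1_min_deficit >= 0)
  centers <- t(vapply(profiles, function(p) unname(p$deficit_rgb), numeric(3)))
  colnames(centers) <- c("R", "G", "B")
  k <- nrow(centers)
  lo <- hi <- centers
  for (b in 1:3) {
    v <- sort(unique(centers[, b]))
    cuts <- if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2 else numeric(0)
    lower <- c(-Inf, cuts)
    upper <- c(cuts, Inf)
    cell <- findInterval(centers[, b], v)
    lo[, b] <- lower[cell]
    hi[, b] <- upper[cell]
  }
  rule <- structure(
    list(classes = names(profiles), centers = centers, lo = lo, hi = hi,
         stage1_min_deficit = stage1_min_deficit),
    class = "classification_rule"
  )
  validate_rules(rule)
  rule
}

# Intervals must be per-band disjoint or identical (tied classes share a
# cell); partial overlaps would make assignment order-dependent.
validate_rules <- function(rule) {
  stopifnot(inherits(rule, "classification_rule"))
  k <- length(rule$classes)
  if (k != nrow(rule$centers)) stop("malformed rule table")
  for (b in 1:3) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i >= j) next
        li <- rule$lo[i, b]; hj <- rule$hi[j, b]
        lj <- rule$lo[j, b]; hi_ <- rule$hi[i, b]
        identical_cell <- li == lj && hi_ == hj
        disjoint <- hi_ <= lj || hj <= li
        if (!identical_cell && !disjoint) {
          stop(sprintf("overlapping class intervals in band %s: %s vs %s",
                       c("R", "G", "B")[b], rule$classes[i], rule$classes[j]))
        }
      }
    }
  }
  invisible(rule)
}

#' Classify objects from their band differences
#'
#' Applies the two-stage rule of [classification_rules()] to each object's
#' difference-from-background triple. Objects failing stage 1 are labeled
#' `"background"`; objects matching no class's intervals are `"unknown"`.
#'
#' @param d data frame with `d_r`, `d_g`, `d_b` columns (see
#'   [band_differences()]), or a numeric length-3 triple.
#' @param rule a `classification_rule`; default [classification_rules()].
#' @return character vector of class labels, one per object.
#' @examples
#' classify_objects(c(125, 120, 140))  # "bead"
#' @export
classify_objects <- function(d, rule = classification_rules()) {
  stopifnot(inherits(rule, "classification_rule"))
  if (is.numeric(d) && length(d) == 3L) d <- data.frame(d_r = d[1], d_g = d[2], d_b = d[3])
  stopifnot(all(c("d_r", "d_g", "d_b") %in% names(d)))
  dm <- as.matrix(d[, c("d_r", "d_g", "d_b")])
  vapply(seq_len(nrow(dm)), function(i) {
    x <- dm[i, ]
    if (min(x) < rule$stage1_min_deficit) return("background")
    cand <- which(vapply(seq_along(rule$classes), function(j) {
      all(x >= rule$lo[j, ] & x < rule$hi[j, ])
    }, logical(1)))
    if (length(cand) == 0L) return("unknown")
    dist2 <- rowSums((rule$centers[cand, , drop = FALSE] -
                        matrix(x, length(cand), 3, byrow = TRUE))^2)
    rule$classes[cand[which.min(dist2)]]
  }, character(1))
}

#' @rdname classify_objects
#' @export
classify_object <- function(d, rule = classification_rules()) {
  classify_objects(as_deficit_triple(d), rule)[1L]
}

#' Summarize band differences by class
#'
#' Per-class, per-band mean and standard deviation of the
#' difference-from-background statistic, plus the overall minimum and
#' maximum across the per-band means of the stained classes (the span of
#' intensity change that staining produces). Reliable class means need a
#' minimum number of stained cells, by default 20, gathered from various
#' regions; smaller inputs are refused unless `allow_fewer = TRUE`.
#'
#' @param d data frame with `d_r`, `d_g`, `d_b`.
#' @param classes character vector of class labels, one per row of `d`.
#' @param min_n minimum number of stained objects (default 20).
#' @param allow_fewer override the `min_n` check (e.g. when summarizing
#'   published class means directly).
#' @param stained_classes which labels count as stained cells.
#' @return list with `per_class` (data frame: class, n, mean/sd per band) and
#'   `stained_range` (named numeric `min`/`max` over stained per-band means).
#' @export
summarize_differences <- function(d, classes, min_n = 20, allow_fewer = FALSE,
                                  stained_classes = c("TB", "safranin", "MB", "CV")) {
  stopifnot(nrow(d) == length(classes))
  n_stained <- sum(classes %in% stained_classes)
  if (n_stained < min_n && !allow_fewer) {
    stop(sprintf("only %d stained objects; need at least %d (set allow_fewer = TRUE to override)",
                 n_stained, min_n))
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  per_class <- do.call(rbind, lapply(split(seq_along(classes), classes), function(i) {
    data.frame(class = classes[i[1]], n = length(i),
               mean_r = mean(d$d_r[i]), mean_g = mean(d$d_g[i]), mean_b = mean(d$d_b[i]),
               sd_r = sd0(d$d_r[i]), sd_g = sd0(d$d_g[i]), sd_b = sd0(d$d_b[i]))
  }))
  rownames(per_class) <- NULL
  st <- per_class[per_class$class %in% stained_classes, ]
  rng <- if (nrow(st) > 0L) {
    vals <- as.matrix(st[, c("mean_r", "mean_g", "mean_b")])
    c(min = min(vals), max = max(vals))
  } else {
    c(min = NA_real_, max = NA_real_)
  }
  list(per_class = per_class, stained_range = rng)
}

#' Relative per-band intensity change between two regions
#'
#' Percentage change of mean intensity per band,
#' `100 * (reference - sample) / reference`. This is the statistic used for
#' phone-image analysis, where cluster-level band means of a stained capture
#' are compared against an unstained reference capture. When the reference
#' is the background itself, the result equals `100 * d_c / background_c`.
#'
#' @param reference numeric length-3 reference band means (must be > 0), or
#'   a 1-row data frame with `mean_*` columns.
#' @param sample numeric length-3 sample band means, same conventions.
#' @return named numeric length-3 (`R`, `G`, `B`) percent change.
#' @examples
#' relative_change(c(200, 200, 200), c(160, 180, 198))  # 20, 10, 1
#' @export
relative_change <- function(reference, sample) {
  ref <- as_mean_triple(reference)
  smp <- as_mean_triple(sample)
  if (any(ref <= 0)) stop("reference means must be positive")
  stats::setNames(100 * (ref - smp) / ref, c("R", "G", "B"))
}

as_mean_triple <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("mean_r", "mean_g", "mean_b"), names(x))
    stopifnot(length(cols) == 3L, nrow(x) == 1L)
    x <- as.numeric(x[1L, cols])
  }
  if (inherits(x, "background_estimate")) x <- x$mean_rgb
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  unname(x)
}

#' Deficit trend across a stain dilution series
#'
#' As a stain is diluted, each cell takes up less dye and its intensity
#' rises, i.e. its difference-from-background falls. Given per-concentration
#' deficit triples, checks that deficits decrease monotonically with
#' dilution and reports the band with the greatest change.
#'
#' @param series data frame with columns `concentration_pct` (stain
#'   concentration, percent) and `d_r`, `d_g`, `d_b` (mean deficits at that
#'   concentration). At least two concentrations.
#' @return list with `per_band` (verdict `"monotone"`, `"flat"` or
#'   `"non_monotone"` per band), overall `verdict` (`"monotone"` only when
#'   every band is), `greatest_change_band`, and `change` (absolute deficit
#'   change per band from the highest to the lowest concentration).
#' @examples
#' s <- data.frame(concentration_pct = c(0.1, 0.05, 0.01),
#'                 d_r = c(50, 35, 20), d_g = c(40, 30, 22), d_b = c(40, 36, 34))
#' concentration_trend(s)$verdict
#' @export
concentration_trend <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) >= 2L,
            all(c("concentration_pct", "d_r", "d_g", "d_b") %in% names(series)))
  s <- series[order(-series$concentration_pct), ]
  verdict_1 <- function(x) {
    dx <- diff(x)
    if (all(dx == 0)) "flat" else if (all(dx < 0)) "monotone" else "non_monotone"
  }
  per_band <- vapply(c("d_r", "d_g", "d_b"), function(cn) verdict_1(s[[cn]]), character(1))
  names(per_band) <- c("R", "G", "B")
  change <- vapply(c("d_r", "d_g", "d_b"),
                   function(cn) abs(s[[cn]][1] - s[[cn]][nrow(s)]), numeric(1))
  names(change) <- c("R", "G", "B")
  list(
    per_band = per_band,
    verdict = if (all(per_band == "monotone")) "monotone" else if (all(per_band == "flat")) "flat" else "non_monotone",
    greatest_change_band = names(change)[which.max(change)],
    change = change
  )
}
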