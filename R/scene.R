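#' Declarative synthetic scene specification
#'
#' A scene describes the content of one synthetic bright-field field of view:
#' the optics, the objects to draw (either an explicit table or per-class
#' counts with a placement mode) and a seed. The same spec and seed always
#' render to the identical image and ground truth.
#'
#' Objects may be given explicitly as a data frame with columns `kind`,
#' `diameter_um`, `row`, `col` and optionally `cluster_id`, or implicitly as
#' named counts per class (e.g. `c(TB = 20, bead = 10)`), in which case
#' placement is carried out at render time from the scene seed.
#'
#' @param optics an [optics_profile()] (default: the `microscope_10x` preset).
#' @param counts named integer vector of object counts per stain-profile name;
#'   ignored when `objects` is supplied.
#' @param objects optional data frame of explicit objects (see Details).
#' @param placement `"non_overlapping"` (rejection-sampled disjoint disks) or
#'   `"clustered"` (objects packed into dense clumps around cluster centres,
#'   overlaps allowed, as in a magnetically collected conjugate clump).
#' @param seed integer scene seed; all stochastic draws flow from it.
#' @param cell_kind which default diameter non-bead objects take, `"K562"` or
#'   `"lymphocyte"`.
#' @param diameters named numeric vector of diameters in micrometres used for
#'   implicit objects; defaults to [default_diameters()] (stained/unstained
#'   cells take the `cell_kind` entry, beads the `bead` entry).
#' @param n_clusters number of cluster centres in `"clustered"` mode.
#' @param cluster_spacing centre-to-centre pitch between neighbouring cluster
#'   members as a fraction of their mean diameter (default 0.85: disks
#'   overlap slightly, giving the near-solid clump a collected conjugate
#'   forms).
#' @param profiles stain profile list, defaults to [stain_profiles()].
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(counts = c(TB = 5), seed = 1)
#' @export
scene_spec <- function(optics = optics_preset("microscope_10x"),
                       counts = NULL,
                       objects = NULL,
                       placement = c("non_overlapping", "clustered"),
                       seed = 1L,
                       cell_kind = c("K562", "lymphocyte"),
                       diameters = default_diameters(),
                       n_clusters = 1L,
                       cluster_spacing = 0.85,
                       profiles = stain_profiles()) {
  placement <- match.arg(placement)
  cell_kind <- match.arg(cell_kind)
  stopifnot(inherits(optics, "optics_profile"),
            is.numeric(seed), length(seed) == 1L)
  if (is.null(objects)) {
    if (is.null(counts)) counts <- integer(0)
    stopifnot(!is.null(names(counts)) || length(counts) == 0L)
    unknown <- setdiff(names(counts), names(profiles))
    if (length(unknown) > 0L) {
      stop("unknown stain profile(s): ", paste(unknown, collapse = ", "))
    }
  } else {
    stopifnot(is.data.frame(objects),
              all(c("kind", "diameter_um", "row", "col") %in% names(objects)),
              all(objects$diameter_um > 0))
    bad <- objects$row < 1 | objects$row > optics$image_shape[1] |
      objects$col < 1 | objects$col > optics$image_shape[2]
    if (any(bad)) stop("object centres outside image bounds")
    counts <- NULL
  }
  structure(
    list(optics = optics, counts = counts, objects = objects,
         placement = placement, seed = as.integer(seed),
         cell_kind = cell_kind, diameters = diameters,
         n_clusters = as.integer(n_clusters), cluster_spacing = cluster_spacing,
         profiles = profiles),
    class = "scene_spec"
  )
}

# Evaluate a function with a temporary RNG state seeded from `seed`,
# restoring the caller's state afterwards.
with_scene_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Diameter (um) for an implicit object of class `kind`.
kind_diameter <- function(kind, cell_kind, diameters) {
  if (kind == "bead") unname(diameters[["bead"]]) else unname(diameters[[cell_kind]])
}

# Draw object centres for a counts-based scene. Uses the current RNG state.
# Non-overlapping mode rejection-samples disjoint disks (with a 1-px gap and
# an edge margin); clustered mode scatters objects around cluster centres.
place_objects <- function(spec) {
  shape <- spec$optics$image_shape
  px <- spec$optics$pixel_scale
  kinds <- rep(names(spec$counts), times = spec$counts)
  n <- length(kinds)
  if (n == 0L) {
    return(data.frame(kind = character(0), diameter_um = numeric(0),
                      row = numeric(0), col = numeric(0),
                      cluster_id = integer(0)))
  }
  diam <- vapply(kinds, kind_diameter, numeric(1),
                 cell_kind = spec$cell_kind, diameters = spec$diameters)
  r_px <- diam / 2 / px
  # larger objects first: easier packing, deterministic order
  ord <- order(-r_px)
  kinds <- kinds[ord]; diam <- diam[ord]; r_px <- r_px[ord]

  if (spec$placement == "non_overlapping") {
    gap <- 1
    rows <- cols <- numeric(n)
    max_tries <- 200L * n
    tries <- 0L
    for (i in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop(sprintf(
            "could not place %d non-overlapping objects in a %dx%d field (placed %d); scene too dense",
            n, shape[1], shape[2], i - 1L))
        }
        m <- r_px[i] + 1
        rr <- stats::runif(1, m, shape[1] - m)
        cc <- stats::runif(1, m, shape[2] - m)
        if (i == 1L) break
        j <- seq_len(i - 1L)
        if (all((rows[j] - rr)^2 + (cols[j] - cc)^2 >
                (r_px[j] + r_px[i] + gap)^2)) break
      }
      rows[i] <- rr; cols[i] <- cc
    }
    cl <- rep(NA_integer_, n)
  } else {
    # pack each cluster's members onto a jittered hexagonal lattice around
    # the cluster centre: magnetically collected conjugates form dense,
    # slightly overlapping clumps, not diffuse scatters
    k <- max(1L, spec$n_clusters)
    margin <- 0.25 * min(shape)
    cr <- stats::runif(k, margin, shape[1] - margin)
    cc0 <- stats::runif(k, margin, shape[2] - margin)
    cl <- sort(rep_len(seq_len(k), n))
    rows <- cols <- numeric(n)
    for (g in seq_len(k)) {
      mem <- which(cl == g)
      pitch <- spec$cluster_spacing * 2 * mean(r_px[mem])
      pts <- hex_points(length(mem), pitch)
      jit <- 0.1 * pitch
      rows[mem] <- cr[g] + pts[, 1] + stats::rnorm(length(mem), 0, jit)
      cols[mem] <- cc0[g] + pts[, 2] + stats::rnorm(length(mem), 0, jit)
    }
    rows <- pmin(pmax(rows, r_px + 1), shape[1] - r_px - 1)
    cols <- pmin(pmax(cols, r_px + 1), shape[2] - r_px - 1)
  }
  data.frame(kind = kinds, diameter_um = diam, row = rows, col = cols,
             cluster_id = cl)
}

# n points of a hexagonal lattice with the given pitch, nearest-first from
# the origin.
hex_points <- function(n, pitch) {
  m <- ceiling(sqrt(n)) + 2L
  ij <- expand.grid(i = -m:m, j = -m:m)
  r <- ij$i * pitch * sqrt(3) / 2
  c_ <- (ij$j + (ij$i %% 2) / 2) * pitch
  d2 <- r^2 + c_^2
  o <- order(d2)[seq_len(n)]
  cbind(r[o], c_[o])
}
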