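#' Phone-image stain change for a matched conjugate-cluster pair
#'
#' Emulates the mobile readout workflow: a conjugate cluster (cells plus
#' magnetic beads gathered by the magnets) is rendered twice with identical
#' geometry and noise - once with unstained cells (the no-dye reference
#' capture) and once with stained cells - each scene is re-imaged at phone
#' resolution, the cell-bead complex area is identified and separated from
#' the rest of each image, and the per-band relative change of the complex
#' mean intensities is computed with the reference capture as baseline.
#'
#' The complex means are cluster-level (area-weighted over all detected
#' regions), not per cell: at phone resolution individual cells are not
#' resolved.
#'
#' @param seed scene seed shared by the pair (identical placement and noise).
#' @param n_cells number of cells in the cluster (default 30).
#' @param n_beads number of free beads mixed into the cluster (default 10).
#' @param stain stain profile name of the stained capture (default `"TB"`).
#' @param reference profile name of the reference capture (default
#'   `"unstained"`).
#' @param optics microscope optics used for the source scenes (default
#'   `microscope_4x`).
#' @param phone_optics phone rendering optics (default the `phone` preset).
#' @param min_deficit segmentation threshold on the phone images (default 8,
#'   slightly lower than the microscope default because downsampling dilutes
#'   edge deficits).
#' @return list with `change` (named percent change per band, reference vs
#'   stained), `reference_means`, `sample_means`, `largest_band`,
#'   `smallest_band`.
#' @examples
#' \donttest{
#' mobile_stain_change(seed = 1)$change
#' }
#' @export
mobile_stain_change <- function(seed, n_cells = 30L, n_beads = 10L,
                                stain = "TB", reference = "unstained",
                                optics = optics_preset("microscope_4x"),
                                phone_optics = optics_preset("phone"),
                                min_deficit = 8) {
  cluster_means <- function(kind) {
    counts <- c(n_cells, n_beads)
    names(counts) <- c(kind, "bead")
    sp <- scene_spec(optics = optics, counts = counts[counts > 0],
                     placement = "clustered", seed = seed)
    img <- render_phone_view(render_scene(sp)$image, phone_optics, seed = seed)
    objs <- segment_objects(img, min_deficit = min_deficit)
    if (nrow(objs) == 0L) stop("no cell-bead complex detected in phone image")
    w <- objs$area_px / sum(objs$area_px)
    c(sum(w * objs$mean_r), sum(w * objs$mean_g), sum(w * objs$mean_b))
  }
  ref <- cluster_means(reference)
  smp <- cluster_means(stain)
  ch <- relative_change(ref, smp)
  list(change = ch,
       reference_means = stats::setNames(ref, c("R", "G", "B")),
       sample_means = stats::setNames(smp, c("R", "G", "B")),
       largest_band = names(ch)[which.max(ch)],
       smallest_band = names(ch)[which.min(ch)])
}
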