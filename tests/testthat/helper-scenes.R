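# Shared fixture builders. All fixtures are generated in code at test time.

noiseless_optics <- function(preset = "microscope_10x") {
  op <- optics_preset(preset)
  op$noise_sd <- 0
  op$blur_sigma <- 0
  op
}

# Render n objects of one class and push them through segmentation and
# band differences. Returns the pieces most tests need.
render_class_fixture <- function(kind, n, seed, noiseless = FALSE,
                                 preset = "microscope_10x") {
  op <- if (noiseless) noiseless_optics(preset) else optics_preset(preset)
  counts <- stats::setNames(n, kind)
  sc <- render_scene(scene_spec(optics = op, counts = counts, seed = seed))
  objs <- segment_objects(sc$image)
  list(scene = sc, objects = objs,
       differences = band_differences(objs),
       truth = sc$truth)
}

table1_deficits <- function() {
  t(vapply(stain_profiles(), function(p) unname(p$deficit_rgb), numeric(3)))
}
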