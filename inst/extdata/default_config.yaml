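# Default stainsight pipeline configuration.
# Deficits are per-band differences from the nominal background mean (225)
# for the six bundled object classes.
seed: 1
optics: microscope_4x
profiles:
  bead:      {deficit_rgb: [125, 120, 140], is_stain: false}
  unstained: {deficit_rgb: [15, 15, 30],    is_stain: false}
  TB:        {deficit_rgb: [50, 40, 40],    is_stain: true}
  safranin:  {deficit_rgb: [25, 135, 100],  is_stain: true}
  MB:        {deficit_rgb: [100, 100, 45],  is_stain: true}
  CV:        {deficit_rgb: [100, 115, 30],  is_stain: true}
rules:
  stage1_min_deficit: 10
segmentation:
  min_deficit: 10
  min_object_area: ~   # null: derived from the pixel scale (2 um disk)
quantification:
  ultra_low_max: 1000
  cluster_cutoff: 1.6
  r2_min: 0.95
  min_n: 20
simulate:
  density: ultra_low
  loss_fraction: 0.19
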