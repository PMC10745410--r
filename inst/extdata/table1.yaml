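# Full digital-phantom benchmark: 256 x 256 Shepp-Logan, 512 detectors,
# 30/60/90 equispaced views over 180 degrees, five reconstructors.
phantom:
  kind: shepp_logan
  n: 256
  variant: modified
pixel_size: 1
geometry:
  n_views: [30, 60, 90]
  n_detectors: 512
  angular_span: 180
algorithms: [SART, SART_TV, SART_FDTV, ASD_POCS, ADAPTIVE_FDTV]
recon:
  kIter: 200
  nTV: 20
  lambdaFixed: 0.5
  stepFixed: 0.3
profiles:
  row: 128
  col: 128
output_dir: table1-output
seed: 0
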