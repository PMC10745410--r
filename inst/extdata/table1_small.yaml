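# Fast scaled-down preset of the digital-phantom benchmark (64 x 64 grid,
# 128 detectors, 40 outer iterations) for quick smoke runs.
phantom:
  kind: shepp_logan
  n: 64
  variant: modified
pixel_size: 1
geometry:
  n_views: [30]
  n_detectors: 128
  angular_span: 180
algorithms: [SART, SART_TV, SART_FDTV, ADAPTIVE_FDTV]
recon:
  kIter: 40
  nTV: 20
  lambdaFixed: 0.5
  stepFixed: 0.3
output_dir: table1-small-output
seed: 0
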