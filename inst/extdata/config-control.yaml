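seed: 1
outDir: control-run
stages: junctions
tube:
  radius: 6.0
  length: 35.0
  nRings: 7
  nAround: 6
  vertexJitter: 0.12
  enrichment: 1.0
  baseIntensity: 12000.0
  intensityCV: 0.2
  psfSigma: 0.15
  shotScale: 1.0
  voxel:
  - 0.12
  - 0.12
  - 0.125
  curvature: 0.0
junctions:
  nEmbryos: 15
  bandWidthPx: 5
  azimuthWindowDeg: 60.0
  lcjMaxDeg: 30.0
  tcjMinDeg: 60.0
unroll:
  ringRadius: 6.0
  sarBandPx: 6
frap:
  nTraces: 10
  mf: 0.6
  tHalf: 40.0
  bleachFloor: 0.2
  nPre: 10
  dt: 10.0
  duration: 600.0
  noiseSD: 0.02
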