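# Down-scaled example configuration for `spectrafuse run --config ...`
# (the default five-class split-signal peaks on coarser grids; runs in
# well under a minute).
data:
  type: synthetic
  classSizes: [12, 12, 12, 12, 12]
  uvAxis: [190, 700, 5]
  mirAxis: [400, 4000, 25]
preprocess: snv
split: {trainFraction: 0.7, stratified: true}
ga: {populationSize: 10, generations: 5, patience: 5, cvFolds: 3}
gaPlacement: post_fusion
blockSets:
  - [mir, uv]
classifiers: [svc, rf]
globalSeed: 1
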