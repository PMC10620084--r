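# Demo pipeline configuration: a small synthetic fixation session in which
# spontaneous movements have no direct drive on the neurons, but eye
# movements change the retinal input during uncontrolled epochs
# (confoundGain > 0). All seeds derive from `seed`.
task: fixation
nTrials: 60
nUnits: 6
seed: 42
couplings:
  face: 0.0
  body: 0.0
confoundGain: 0.05
topComponents: 30
segmentSeconds: 60
threshold: 0.1
nPermutations: 1000
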