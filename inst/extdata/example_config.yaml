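# Minimal run configuration: everything not named here takes its default
# (500 Hz sampling, 100 um/s feed, FEM calibration, 8-animal design).
beam:
  pia_only: beam1
  dura_pia: beam3
seed: 42
design:
  animals: 2
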