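# Default lesion complexity weights. Every key is optional: omitted keys
# keep the defaults built into the package (which are these same values).
prolapse:
  p1: 1
  p2: 1
  p3: 1
  a1: 2
  a2: 2
  a3: 2
  anterolateral_commissure: 2
  posteromedial_commissure: 2
ruptured_chordae: 1
morphology:
  normal: 0
  thickening: 1
  redundant: 3
calcification:
  leaflet: 1
  annulus: 3
  chordae: 3
commissure_fusion: 2
perforation_cleft:
  "0": 0
  "1": 1
  "2": 2
vegetation:
  "0": 0
  "1": 1
  "2": 2
motion:
  normal: 0
  excessive: 1
  restriction: 2
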