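# 62-channel extended 10-20 montage (ESI NeuroScan layout used by the
# SEED-series datasets).  Left/right by electrode-name parity (odd = left,
# even = right), listed front-to-back; midline are the z-suffixed reference
# electrodes removed before hemisphere-wise modelling.
left:
  - FP1
  - AF3
  - F7
  - F5
  - F3
  - F1
  - FT7
  - FC5
  - FC3
  - FC1
  - T7
  - C5
  - C3
  - C1
  - TP7
  - CP5
  - CP3
  - CP1
  - P7
  - P5
  - P3
  - P1
  - PO7
  - PO5
  - PO3
  - CB1
  - O1
right:
  - FP2
  - AF4
  - F8
  - F6
  - F4
  - F2
  - FT8
  - FC6
  - FC4
  - FC2
  - T8
  - C6
  - C4
  - C2
  - TP8
  - CP6
  - CP4
  - CP2
  - P8
  - P6
  - P4
  - P2
  - PO8
  - PO6
  - PO4
  - CB2
  - O2
midline:
  - FPZ
  - FZ
  - FCZ
  - CZ
  - CPZ
  - PZ
  - POZ
  - OZ
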