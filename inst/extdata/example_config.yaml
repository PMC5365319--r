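# Example phloemflow run configuration. Any subset of keys may be
# given; everything omitted falls back to the base-scenario defaults
# (see defaultConfig() for the full structure). Unknown keys are
# rejected.
tube:
  diameter_um: 3.6
  velocity_um_s: 22.6
  zone_length_um: 350
sap:
  concentration_mm: 500
pd:
  mouth_nm: 150
flags:
  leak_law: linear
seed: 1
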