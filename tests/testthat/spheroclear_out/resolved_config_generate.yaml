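simulation:
  diamter: 300.0
output_dir: spheroclear_out
channels:
  nuclear: nuclei
  marker: marker
  tracker: tracker
roi_diameter_um: 100.0
marker_mode: segment
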