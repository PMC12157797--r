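[
  {"id": "dpd0", "rgb": [250, 245, 245]},
  {"id": "dpd1", "rgb": [248, 225, 232]},
  {"id": "dpd2", "rgb": [245, 200, 220]},
  {"id": "dpd3", "rgb": [240, 175, 205]},
  {"id": "dpd4", "rgb": [235, 150, 190]},
  {"id": "dpd5", "rgb": [228, 120, 175]},
  {"id": "dpd6", "rgb": [220, 95, 160]},
  {"id": "dpd7", "rgb": [210, 70, 145]},
  {"id": "white", "rgb": [255, 255, 255]},
  {"id": "gray80", "rgb": [204, 204, 204]},
  {"id": "gray60", "rgb": [153, 153, 153]},
  {"id": "gray40", "rgb": [102, 102, 102]},
  {"id": "gray20", "rgb": [51, 51, 51]},
  {"id": "black", "rgb": [10, 10, 10]},
  {"id": "red", "rgb": [220, 60, 50]},
  {"id": "green", "rgb": [60, 180, 70]},
  {"id": "blue", "rgb": [50, 70, 200]},
  {"id": "yellow", "rgb": [230, 230, 60]},
  {"id": "magenta", "rgb": [210, 70, 200]},
  {"id": "cyan", "rgb": [60, 210, 210]},
  {"id": "orange", "rgb": [250, 160, 60]},
  {"id": "maroon", "rgb": [90, 40, 50]},
  {"id": "plum", "rgb": [120, 40, 90]},
  {"id": "sage", "rgb": [170, 210, 120]}
]
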