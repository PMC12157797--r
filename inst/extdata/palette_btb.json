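[
  {"id": "btb0", "rgb": [235, 220, 80]},
  {"id": "btb1", "rgb": [200, 215, 90]},
  {"id": "btb2", "rgb": [160, 205, 110]},
  {"id": "btb3", "rgb": [120, 190, 130]},
  {"id": "btb4", "rgb": [90, 170, 150]},
  {"id": "btb5", "rgb": [60, 140, 170]},
  {"id": "btb6", "rgb": [40, 100, 180]},
  {"id": "btb7", "rgb": [25, 60, 160]},
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
  {"id": "brown", "rgb": [140, 80, 40]},
  {"id": "violet", "rgb": [130, 60, 140]},
  {"id": "olive", "rgb": [80, 120, 60]}
]
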