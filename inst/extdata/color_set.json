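{
  "normal": {
    "A": "#D62728",
    "B": "#1F77B4",
    "het": "#2CA02C",
    "missing": "#BFBFBF"
  },
  "Aqua": {
    "A": "#006D77",
    "B": "#83C5BE",
    "het": "#EE6C4D",
    "missing": "#E0E0E0"
  },
  "grayscale": {
    "A": "#252525",
    "B": "#BDBDBD",
    "het": "#737373",
    "missing": "#F5F5F5"
  }
}
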