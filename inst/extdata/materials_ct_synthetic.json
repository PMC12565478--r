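{
  "meta": {
    "description": "Energy-dependent linear attenuation coefficients (cm^-1). Anchor values at 80 and 120 keV for seven reference materials; remaining grid points are a SYNTHETIC log-log linear extension of the two anchors, intended only for smooth spectrum integration over 20-150 keV.",
    "units": {
      "energy": "keV",
      "lac": "cm^-1"
    },
    "anchors_keV": [80, 120],
    "synthetic_extension": true,
    "energy_span_keV": [20, 150]
  },
  "materials": {
    "air": [
      [20, 0.00048878826385],
      [40, 0.00031266220234],
      [60, 0.0002407498958],
      [80, 0.0002],
      [100, 0.00017320536254],
      [120, 0.000154],
      [150, 0.00013336812916]
    ],
    "lung": [
      [20, 0.11579692288],
      [40, 0.074126107328],
      [60, 0.057101675437],
      [80, 0.047451],
      [100, 0.041103573788],
      [120, 0.036553],
      [150, 0.031663377646]
    ],
    "water": [
      [20, 0.44436247377],
      [40, 0.28560434496],
      [60, 0.22053019328],
      [80, 0.183566],
      [100, 0.15921752997],
      [120, 0.141741],
      [150, 0.12294026081]
    ],
    "pancreas": [
      [20, 0.45699407457],
      [40, 0.29430348953],
      [60, 0.22750985365],
      [80, 0.189531],
      [100, 0.16449583852],
      [120, 0.146516],
      [150, 0.12716269252]
    ],
    "skull": [
      [20, 1.4808952017],
      [40, 0.71099295466],
      [60, 0.46287285762],
      [80, 0.341355],
      [100, 0.26953860388],
      [120, 0.22223],
      [150, 0.17547586513]
    ],
    "aluminum": [
      [20, 2.6218826948],
      [40, 1.1943006329],
      [60, 0.75396156212],
      [80, 0.544019],
      [100, 0.42235316586],
      [120, 0.343439],
      [150, 0.26663140245]
    ],
    "titanium": [
      [20, 67.0864703346],
      [40, 11.0969960425],
      [60, 3.8734545993],
      [80, 1.835591],
      [100, 1.0285177847],
      [120, 0.640721],
      [150, 0.35900859371]
    ]
  }
}
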