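{
  "provenance": "Published melting properties, densities, glass transitions, PC-SAFT pure-component parameters and binary interaction coefficients for naproxen, venetoclax, PVPVA64 and water (ASD dissolution study, 2023). Venetoclax melting enthalpy varied between API lots; the printed 59.9 kJ/mol is stored.",
  "units": {
    "molar_mass": "g/mol",
    "segment_ratio": "mol/g",
    "segment_diameter": "angstrom",
    "dispersion_energy": "K",
    "assoc_energy": "K",
    "assoc_volume": "1",
    "melting_T": "K",
    "melting_enthalpy": "kJ/mol",
    "delta_cp": "J/mol/K",
    "density": "kg/m3",
    "glass_T": "K",
    "kij_m": "1/K",
    "kij_b": "1"
  },
  "components": [
    {
      "name": "naproxen",
      "molar_mass": 230.26,
      "segment_ratio": 0.0352,
      "segment_diameter": 2.939,
      "dispersion_energy": 229.45,
      "assoc_energy": 934.2,
      "assoc_volume": 0.02,
      "assoc_sites": [2, 2],
      "melting_T": 429.47,
      "melting_enthalpy": 31.50,
      "delta_cp": 87,
      "density": 1250,
      "glass_T": 265.15
    },
    {
      "name": "venetoclax",
      "molar_mass": 868.44,
      "segment_ratio": 0.03938,
      "segment_diameter": 2.546,
      "dispersion_energy": 233.70,
      "assoc_energy": 0,
      "assoc_volume": null,
      "assoc_sites": [0, 0],
      "melting_T": 418.15,
      "melting_enthalpy": 59.9,
      "delta_cp": null,
      "density": 1340,
      "glass_T": 393.15
    },
    {
      "name": "PVPVA64",
      "molar_mass": 65000,
      "segment_ratio": 0.0372,
      "segment_diameter": 2.947,
      "dispersion_energy": 205.27,
      "assoc_energy": 0,
      "assoc_volume": 0.02,
      "assoc_sites": [653, 653],
      "melting_T": null,
      "melting_enthalpy": null,
      "delta_cp": null,
      "density": 1190,
      "glass_T": 384.15
    },
    {
      "name": "water",
      "molar_mass": 18.015,
      "segment_ratio": 0.0669,
      "segment_diameter": null,
      "sigma_temperature_dependent": true,
      "dispersion_energy": 353.95,
      "assoc_energy": 2425.7,
      "assoc_volume": 0.0451,
      "assoc_sites": [1, 1],
      "melting_T": null,
      "melting_enthalpy": null,
      "delta_cp": null,
      "density": 1000,
      "glass_T": 138.00
    }
  ],
  "interactions": [
    { "pair": ["PVPVA64", "water"],      "kij_m": 0,          "kij_b": -0.1565 },
    { "pair": ["naproxen", "water"],     "kij_m": 0.000227,   "kij_b": -0.0612 },
    { "pair": ["naproxen", "PVPVA64"],   "kij_m": 0,          "kij_b": -0.0574 },
    { "pair": ["venetoclax", "water"],   "kij_m": 0,          "kij_b": -0.0283 },
    { "pair": ["venetoclax", "PVPVA64"], "kij_m": -0.0000467, "kij_b": 0.0075 }
  ]
}
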