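# Constitutive parameter catalog, version 1.
# Moduli in MPa unless a *_gpa key is used; D1 in 1/MPa; density in kg/m^3.
version: 1
materials:
  aortic_wall:
    law: linear_elastic
    nu: 0.475
    E: ~          # patient-specific, identified by inverse analysis
    label: aortic root wall (linear elastic, modulus calibrated per patient)
  leaflet:
    law: linear_elastic
    nu: 0.475
    E: ~          # patient-specific, identified by inverse analysis
    label: native valve leaflet (linear elastic, modulus calibrated per patient)
  calcification:
    law: neo_hookean
    C10: 67.7
    D1: 7.5e-3
    label: calcific plaque (neo-Hookean)
  pericardium:
    law: ogden2
    mu1: 0.96
    alpha1: -56.5
    mu2: 3.57
    alpha2: 1.87
    D1: 0.027
    label: bioprosthetic pericardium (2nd-order Ogden)
  cobalt_chromium:
    law: johnson_cook
    E_gpa: 238.54
    nu: 0.29
    A: 465.0
    B: 2140.0
    "n": 0.73
    density: 7650
    label: stent frame cobalt-chromium (elastic + Johnson-Cook hardening)
  skirt:
    law: neo_hookean
    C10: 1.7
    D1: 0.65
    label: device skirt (neo-Hookean)
  balloon:
    law: neo_hookean
    C10: 36.5
    D1: 1.36e-3
    label: delivery balloon (neo-Hookean)
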