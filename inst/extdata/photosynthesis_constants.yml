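# Temperature-response and Rubisco kinetic constants for the FvCB model.
#
# Units:
#   ha, hd : J mol-1      (activation / deactivation energy)
#   ds     : J mol-1 K-1  (entropy term of the peaked Arrhenius form)
#   kc25   : umol mol-1   (Michaelis constant of Rubisco for CO2 at 25 C)
#   ko25   : mmol mol-1   (Michaelis constant of Rubisco for O2 at 25 C)
#   gammastar25 : umol mol-1 (CO2 compensation point without Rdark at 25 C)
#   oxygen : mmol mol-1   (chamber O2 mole fraction)
#
# A parameter entry with ha only uses the pure Arrhenius form; entries with
# ha, hd and ds use the peaked (modified) Arrhenius form. All scalers equal 1
# exactly at tref_c. Kinetics are the in-vivo tobacco values of Bernacchi and
# colleagues expressed as mole fractions; the peaked-Arrhenius parameters are
# widely used temperate-default values. Edit this file (or pass a copy via
# fvcb_constants(path=)) to substitute site- or biome-specific values.
reference:
  tref_c: 25.0
  gas_constant: 8.314
kinetics:
  kc25: 404.9
  ko25: 278.4
  gammastar25: 42.75
  oxygen: 210.0
temperature_response:
  vcmax:
    ha: 65330.0
    hd: 149250.0
    ds: 485.0
  jmax:
    ha: 43540.0
    hd: 152040.0
    ds: 495.0
  tp:
    ha: 53100.0
    hd: 201800.0
    ds: 650.0
  rdark:
    ha: 46390.0
  kc:
    ha: 79430.0
  ko:
    ha: 36380.0
  gammastar:
    ha: 37830.0
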