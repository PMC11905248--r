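- structure: PTV_eval
  doseGy: 36.25
  bound: 95.0
  direction: '>='
  unit: pct
- structure: PTV_eval
  doseGy: 34.4
  bound: 98.0
  direction: '>='
  unit: pct
- structure: PTV_eval
  doseGy: 33.7
  bound: 99.0
  direction: '>='
  unit: pct
- structure: PTV_eval
  doseGy: 38.78
  bound: 20.0
  direction: <=
  unit: cc
- structure: PTV_eval
  doseGy: 43.5
  bound: 0.03
  direction: <=
  unit: cc
- structure: rectum
  doseGy: 38.06
  bound: 0.03
  direction: <=
  unit: cc
- structure: rectum
  doseGy: 34.4
  bound: 3.0
  direction: <=
  unit: cc
- structure: rectum
  doseGy: 32.6
  bound: 10.0
  direction: <=
  unit: pct
- structure: rectum
  doseGy: 29.0
  bound: 20.0
  direction: <=
  unit: pct
- structure: rectum
  doseGy: 18.13
  bound: 50.0
  direction: <=
  unit: pct
- structure: bladder
  doseGy: 38.06
  bound: 0.03
  direction: <=
  unit: cc
- structure: bladder
  doseGy: 18.12
  bound: 10.0
  direction: <=
  unit: pct
- structure: urethra_prv
  doseGy: 38.78
  bound: 0.03
  direction: <=
  unit: cc
- structure: femur_r
  doseGy: 19.9
  bound: 10.0
  direction: <=
  unit: cc
- structure: femur_l
  doseGy: 19.9
  bound: 10.0
  direction: <=
  unit: cc
- structure: penile_bulb
  doseGy: 36.25
  bound: 0.03
  direction: <=
  unit: cc
- structure: penile_bulb
  doseGy: 19.9
  bound: 3.0
  direction: <=
  unit: cc
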