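# Final adult PK/PD population model: transit-compartment absorption into a
# two-compartment disposition system, effect-compartment link, sigmoid Imax
# with full inhibition. Units: rates 1/h, Mtt h, CL/Q L/h, V L, IC50 ug/L;
# E0 and gamma dimensionless. IIV reported as CV%.
fixed:
  ktr: 5.31
  Mtt: 1.46
  ka: 1.19
  CL: 36.39
  V1: 223.71
  Q: 6.38
  V2: 108.26
  ke0: 0.48
  gamma: 2.02
  E0: 0.043
  IC50: 30.01
iiv_cv_percent:
  ktr: 72.89
  Mtt: 33.7
  CL: 30.17
  V1: 46.61
  E0: 141.9
  IC50: 79.35
correlations:
- par1: V1
  par2: CL
  r: 0.84
error:
  pk:
    a: 0.42
    b: 0.072
  pd:
    b: 0.41
error_form: combined1
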