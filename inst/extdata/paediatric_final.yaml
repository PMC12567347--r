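# Final paediatric population PD model: direct Imax with full inhibition and
# no sigmoidicity, measured enalaprilat concentrations as input. E0
# dimensionless, IC50 ug/L; IIV on IC50 only, proportional residual error.
fixed:
  E0: 0.19
  IC50: 1.19
iiv_cv_percent:
  IC50: 59.92
error:
  pd:
    b: 0.37
error_form: combined1
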