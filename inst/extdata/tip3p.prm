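# Three-site water (TIP3P) parameters, CHARMM-style units:
#   charge e, lj_epsilon kcal/mol, lj_rmin_half A, mass amu,
#   kb kcal/mol/A^2 (E = kb (b-b0)^2), ktheta kcal/mol/rad^2, theta0 deg.
# Flexible internal terms are used only at the analysis stage; sampling
# keeps waters rigid at the ideal geometry.
atom  OT water_O -0.834 0.1521 1.7682 15.9994
atom  HT water_H  0.417 0.0460 0.2245  1.0080
bond  OT HT 450.0 0.9572
angle HT OT HT 55.0 104.52
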