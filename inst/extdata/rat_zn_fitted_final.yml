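# Reference whole-body zinc cycle of a 370 g adult rat: final fitted
# configuration. Bone exchange is set so the bone mean residence time is
# 300.2 days (3212/300.2 = 10.69953 ug/day each way), integument loss is
# 4 ug/day (low integument loss / high endogenous loss), renal fractionation
# is alpha = 1.00044, and the intestinal absorption / endogenous loss and
# plasma-to-integument fractionations are the representative node of the
# package's default parameter sweep fitted against the supplier-diet
# observation table (split amplitude -0.025 / +0.025 per mil, and -0.25 per
# mil, respectively). Masses in ug, fluxes in ug/day.
name: rat_zn_fitted_final
compartments:
  - {name: diet, mass: infinite, role: source, delta0: 0.42}
  - {name: intestine, mass: 1000, role: internal, delta0: 0.42}
  - {name: plasma, mass: 32, role: internal, delta0: 0.36}
  - {name: liver, mass: 378, role: internal, delta0: -0.48}
  - {name: rbc, mass: 320, role: internal, delta0: 0.47}
  - {name: muscle, mass: 1960, role: internal, delta0: -0.21}
  - {name: bone, mass: 3212, role: internal, delta0: 0.37}
  - {name: kidney, mass: 63, role: internal, delta0: -0.12}
  - {name: integument, mass: 2787, role: internal, delta0: 0.08}
  - {name: feces, mass: 813, role: accumulator, delta0: 0.44}
  - {name: urine, mass: 7, role: accumulator, delta0: 0.42}
  - {name: waste, mass: infinite, role: sink}
fluxes:
  - {from: diet, to: intestine, rate: 1000, alpha: 1.0}
  - {from: intestine, to: feces, rate: 989, alpha: 1.0}
  - {from: intestine, to: plasma, rate: 305, alpha: 0.9999750003}
  - {from: plasma, to: intestine, rate: 294, alpha: 1.0000250003}
  - {from: plasma, to: liver, rate: 900, alpha: 0.99958}
  - {from: plasma, to: rbc, rate: 35, alpha: 1.00005}
  - {from: plasma, to: muscle, rate: 227, alpha: 0.99972}
  - {from: plasma, to: bone, rate: 10.69953364, alpha: 1.00001}
  - {from: plasma, to: integument, rate: 4, alpha: 0.9997500312}
  - {from: plasma, to: kidney, rate: 118, alpha: 1.0}
  - {from: liver, to: plasma, rate: 900, alpha: 1.00042}
  - {from: rbc, to: plasma, rate: 35, alpha: 0.99995}
  - {from: muscle, to: plasma, rate: 227, alpha: 1.00028}
  - {from: bone, to: plasma, rate: 10.69953364, alpha: 0.99999}
  - {from: kidney, to: plasma, rate: 111, alpha: 1.0}
  - {from: kidney, to: urine, rate: 7, alpha: 1.00044}
  - {from: urine, to: waste, rate: 7, alpha: 1.0}
  - {from: integument, to: waste, rate: 4, alpha: 1.0}
  - {from: feces, to: waste, rate: 989, alpha: 1.0}
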