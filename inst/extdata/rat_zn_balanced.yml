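# Mass-balanced rat zinc cycle with literature (House & Wastney 1997 style)
# values for the poorly constrained fluxes: muscle efflux corrected to
# 227 ug/day (the published 900 breaks plasma and muscle balance), bone
# exchange 229.428571 ug/day (14-day bone residence), integument loss
# 39.814286 ug/day (70-day integument residence, with endogenous loss and
# fecal flux compensated to preserve balance), and neutral (alpha = 1)
# fractionation on the swept edges. This is the natural starting point for
# parameter sweeps. Masses in ug, fluxes in ug/day.
name: rat_zn_balanced
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
  - {from: intestine, to: feces, rate: 953.185714, alpha: 1.0}
  - {from: intestine, to: plasma, rate: 305, alpha: 1.0}
  - {from: plasma, to: intestine, rate: 258.185714, alpha: 1.0}
  - {from: plasma, to: liver, rate: 900, alpha: 0.99958}
  - {from: plasma, to: rbc, rate: 35, alpha: 1.00005}
  - {from: plasma, to: muscle, rate: 227, alpha: 0.99972}
  - {from: plasma, to: bone, rate: 229.428571, alpha: 1.00001}
  - {from: plasma, to: integument, rate: 39.814286, alpha: 1.0}
  - {from: plasma, to: kidney, rate: 118, alpha: 1.0}
  - {from: liver, to: plasma, rate: 900, alpha: 1.00042}
  - {from: rbc, to: plasma, rate: 35, alpha: 0.99995}
  - {from: muscle, to: plasma, rate: 227, alpha: 1.00028}
  - {from: bone, to: plasma, rate: 229.428571, alpha: 0.99999}
  - {from: kidney, to: plasma, rate: 111, alpha: 1.0}
  - {from: kidney, to: urine, rate: 7, alpha: 1.0}
  - {from: urine, to: waste, rate: 7, alpha: 1.0}
  - {from: integument, to: waste, rate: 39.814286, alpha: 1.0}
  - {from: feces, to: waste, rate: 953.185714, alpha: 1.0}
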