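compartment,delta66Zn,ci_halfwidth,n,excluded_from_fit
diet,0.42,0.08,5,FALSE
plasma,0.36,0.20,1,FALSE
liver,-0.48,0.12,3,FALSE
rbc,0.47,0.03,3,FALSE
muscle,-0.21,0.21,2,FALSE
bone,0.37,0.12,3,FALSE
integument,0.08,0.20,1,FALSE
feces,0.44,0.14,3,FALSE
kidney,-0.12,0.12,3,TRUE
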