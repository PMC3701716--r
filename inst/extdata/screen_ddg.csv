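mutant,ddG_coulomb,ddG_vdw,ddG_total,ddG_total_err,ddG_exp,ddG_exp_err
H22K,-0.0,-0.6,-0.6,0.65,-0.3,0.03
H22W,-0.6,-2.2,-2.8,0.67,-1.2,0.06
V25I,0,-2.3,-2.3,0.22,-0.4,0.07
T30M,-1.8,-3.7,-5.5,0.63,-0.5,0.06
A33Y,-0.7,-1.5,-2.2,0.35,-0.5,0.05
T50M,-1.1,-0.7,-1.8,0.38,0.50,0.14
T54Y,1.4,-4.0,-2.6,0.43,-0.2,0.02
A81M,0.1,-1.3,-1.2,0.37,0.4,0.19
V88L,0,-1.1,-1.1,0.28,0.2,0.21
V90I,0,-1.3,-1.3,0.28,0.7,0.04
L106M,-3.9,0.8,-3.1,0.50,,
N107F,-0.3,-2.0,-2.3,0.73,-0.9,0.07
N107Y,-0.4,-2.5,-2.9,0.70,-0.8,0.08
D109E,-7.1,-0.8,-7.9,1.17,-0.3,0.14
M111F,-1.8,-0.6,-2.4,0.64,-2.9,0.36
V120I,0,-1.5,-1.5,0.26,-1.4,0.60
N124F,-0.4,-3.2,-3.6,0.54,-1.1,0.03
N124Y,-1.2,-3.0,-4.2,0.41,-2.6,0.22
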