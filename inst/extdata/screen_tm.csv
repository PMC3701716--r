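mutant,tm_c,tm_err,single
WT,42.8,0.3,FALSE
H22K,45.3,0.2,TRUE
H22W,49.4,0.2,TRUE
V25I,46.6,0.5,TRUE
T30M,47.3,0.4,TRUE
A33Y,46.6,0.3,TRUE
T50M,36.4,1.7,TRUE
T54Y,43.7,0.1,TRUE
A81M,39.8,2.3,TRUE
V88L,41.0,2.5,TRUE
V90I,33.6,1.1,TRUE
L106M,,,TRUE
N107F,50.9,0.3,TRUE
N107Y,52.0,0.5,TRUE
D109E,46.8,2.0,TRUE
M111F,56.5,1.0,TRUE
V120I,54.2,0.9,TRUE
N124F,50.2,0.1,TRUE
N124Y,63.8,0.1,TRUE
N107F-N124F,59.3,0.8,FALSE
N107Y-N124Y,69.5,0.1,FALSE
N107Y-V120I,56.4,0.6,FALSE
N107Y-N124Y-H22W,67.5,0.2,FALSE
N107Y-N124Y-M111F,74.9,0.2,FALSE
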