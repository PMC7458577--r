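wound,planimetry_program,autosegmentation,caliper_kundin,rigid_ruler_kundin
A,1.44,-2.60,-1.78,-16.07
B,2.63,5.41,-24.01,-25.66
C,1.88,0.99,-62.72,-38.86
D,3.76,-0.80,-195.16,-195.16
E,0.99,-2.75,-32.15,-32.98
F,0.94,-0.73,-35.12,0.45
G,3.00,-0.31,-16.71,-30.90
H,-6.60,-6.06,8.54,-18.44
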