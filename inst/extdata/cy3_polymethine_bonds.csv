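# Equilibrium bond lengths (Angstrom) along the polymethine chain of a
# trimethine cyanine (Cy3), ring nitrogen N1 to ring nitrogen N2.
# Columns: R0_QM_S0 / R0_QM_S1 = wB97XD/Def2SVP optimized ground / first
# excited state; R0_FF = Amber99SB-dyes force-field equilibrium value;
# k_FF = force-field force constant in kJ mol^-1 nm^-2.
# Reparameterization reference values: chain C-C bonds set to the cag-cag
# parameters (R0 = 1.3970 A, k = 389275 kJ mol^-1 nm^-2) and terminal N-C
# bonds to c2g-nhg parameters (R0 = 1.3550 A, k = 387100 kJ mol^-1 nm^-2).
bond,R0_QM_S0,R0_QM_S1,R0_FF,k_FF
"R(N1,1)",1.3435,1.3712,1.391,343760
"R(1,2)",1.3966,1.3960,1.4510,326770
"R(2,3)",1.3938,1.4071,1.3379,470620
"R(3,4)",1.3938,1.4071,1.4511,326770
"R(4,5)",1.3966,1.3960,1.3390,469030
"R(5,N2)",1.3435,1.3712,1.355,387100
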