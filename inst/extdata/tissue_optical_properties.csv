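name,mu_a,mu_s,g,n
Scalp,0.018,19.0,0.9,1.37
Skull,0.016,16.0,0.9,1.43
Cerebrospinal fluid,0.004,2.4,0.9,1.33
Gray matter,0.036,22.0,0.9,1.37
White matter,0.014,91.0,0.9,1.37
Blood vessel,0.223,50.0,0.99,1.4
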