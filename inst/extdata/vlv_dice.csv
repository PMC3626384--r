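subject_id,group,vlv_semi_L,vlv_manual_L,dice
H1,healthy,3.05,3.14,0.96
H2,healthy,3.82,3.73,0.97
H3,healthy,4.88,4.87,0.96
H4,healthy,3.78,3.84,0.96
A1,asthmatic,3.50,3.55,0.96
A2,asthmatic,3.24,3.19,0.97
A3,asthmatic,3.16,3.14,0.96
A4,asthmatic,6.04,6.19,0.96
A5,asthmatic,3.80,3.80,0.96
A6,asthmatic,3.23,3.23,0.95
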