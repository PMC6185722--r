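bgr,k,sd_k,eta,sd_eta,rmse
D17,0.362,0.060,0.844,0.009,0.007
D24,0.420,0.075,0.871,0.018,0.008
D33,0.279,0.036,0.828,0.018,0.006
D52,0.506,0.081,0.851,0.016,0.008
D61,0.391,0.034,0.802,0.015,0.009
D100,0.575,0.076,0.890,0.009,0.009
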