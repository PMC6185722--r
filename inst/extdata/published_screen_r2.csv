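predictor,r2_k,r2_eta
dm,0.245,0.046
dm_org,0.035,0.139
ct,0.180,0.001
nh4n,0.064,0.189
norg,0.547,0.624
nt,0.402,0.007
ct_nt,0.495,0.028
ct_norg,0.371,0.696
ph,0.863,0.411
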