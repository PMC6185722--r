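bgr,dm,dm_org,ph,ct,nh4n,norg,nt,ct_nt,ct_norg
D17,5.5,28.1,8,38.4,2.9,3.4,6.3,6.1,11.3
D24,9.2,27.9,7.8,39.2,3.5,3.0,6.5,6.0,13.1
D33,9.6,33.0,8,41.3,2,3.0,5.0,8.3,13.8
D52,7.2,29.2,7.7,40.7,4.3,3.4,7.7,5.3,12.0
D61,8.1,33.48,7.9,42,5.5,2.7,8.2,5.1,15.6
D100,6.8,34.08,7.7,43.2,2.9,4.3,7.2,6.0,10.0
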