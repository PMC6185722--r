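bgr,maize_silage,grass_silage,rye_silage,shredded_grain,pig_slurry,cattle_slurry,farmyard_manure
D17,17,0,0,0,19,64,0
D24,24,31,8,0,0,37,0
D33,33,0,25,0,20,0,22
D52,52,8,0,2,35,0,3
D61,61,0,0,5,34,0,0
D100,100,0,0,0,0,0,0
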