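numerator,denominator,fold,sd,n_blots
GFP:APC2,Axin:GFP,4.3,1.4,4
Axin:GFP,Axin,1.0,0.5,4
GFP:APC2,APC2,0.9,0.4,4
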