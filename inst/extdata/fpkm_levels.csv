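gene,stage,fpkm
APC2,early,484
APC1,early,26
APC2,mid,201
APC1,mid,27
APC1,late,120
APC2,late,23
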