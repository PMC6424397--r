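reference,complete,partial,non_defoliated,oak
complete,32,11,0,0
partial,0,28,1,0
non_defoliated,0,4,9,0
oak,0,2,3,20
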