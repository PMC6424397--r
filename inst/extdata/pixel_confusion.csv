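reference,defoliated,non_defoliated,shaded
defoliated,34,4,6
non_defoliated,3,37,0
shaded,4,2,10
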