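loop,pair_index,mode,p_star
outer,11,first,0.31
outer,13,first,0.42
outer,15,first,0.09
outer,17,first,0.09
outer,19,first,0.05
outer,11,last,0.07
outer,13,last,0.10
outer,15,last,0.27
outer,17,last,0.47
outer,19,last,0.06
inner,1,first,0.30
inner,3,first,0.45
inner,5,first,0.07
inner,7,first,0.09
inner,9,first,0.06
inner,1,last,0.08
inner,3,last,0.13
inner,5,last,0.03
inner,7,last,0.29
inner,9,last,0.45
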