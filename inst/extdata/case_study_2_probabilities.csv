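loop,pair_index,mode,p_star
outer,11,first,0.02
outer,13,first,0.87
outer,15,first,0.07
outer,17,first,0.01
outer,19,first,0.01
outer,11,last,0.01
outer,13,last,0.02
outer,15,last,0.01
outer,17,last,0.74
outer,19,last,0.20
inner,1,first,0.01
inner,3,first,0.89
inner,5,first,0.06
inner,7,first,0.01
inner,9,first,0.01
inner,1,last,0.01
inner,3,last,0.02
inner,5,last,0.01
inner,7,last,0.58
inner,9,last,0.37
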