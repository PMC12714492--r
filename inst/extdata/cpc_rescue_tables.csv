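section,comparison,a,b,c,d
overall,tiger_use,11,5,197,194
overall,population,10,6,236,155
overall,prey_use,13,3,208,183
prey_by_population,low_population,5,1,145,10
prey_by_population,high_population,8,2,63,173
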