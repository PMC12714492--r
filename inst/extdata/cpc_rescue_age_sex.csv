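sex,adult,cub,subadult,unknown
female,7,2,0,0
male,17,1,1,4
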