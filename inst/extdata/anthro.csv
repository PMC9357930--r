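sex,segment,length_frac_height,com_frac_length
male,thorax,0.200,0.50
male,clavicle,0.105,0.50
male,upper_arm,0.186,0.44
male,forearm,0.146,0.43
male,hand,0.054,0.50
female,thorax,0.195,0.50
female,clavicle,0.100,0.50
female,upper_arm,0.173,0.46
female,forearm,0.138,0.43
female,hand,0.050,0.50
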