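; 3-member positioned family, weight 10, 24 positions, read length 34
####-##-####	0,1,2,3,4,5,6,7,8,18,19,20
#-########-#	2,12,15,16,18,19,20,21
####-#-------#-####	0,1,11,14
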