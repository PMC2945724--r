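; the F3 and S2,0 periodic seeds of the PerM mapper, all positions
###-#--#---###-#--#---##	*
####--#----####--#----##	*
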