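# Demonstration list of genera repeatedly reported from mine service water
# and mine air, used to screen subsurface amplicon tables for potential
# mining contamination.  This is a small demo list, not a comprehensive
# database.
Acinetobacter
Blastomonas
Burkholderia
Meiothermus
Novosphingobium
Pseudomonas
Ralstonia
Rheinheimera
Sphingomonas
Stenotrophomonas
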