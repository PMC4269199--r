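site1	site2	shared_genera
Sagole	Siloam	41
Souting	Tshipise	5
NO14	MM51940	551
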