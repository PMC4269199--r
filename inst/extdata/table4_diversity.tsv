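site	environment	reads	reads_classified	genera_observed	pielou	chao1	chao1_se
Eiland	spring	720	698	49	0.57	79	19
Mphephu	spring	721	673	92	0.69	135	20
Sagole	spring	794	662	113	0.72	190	30
Siloam	spring	568	515	119	0.78	209	34
Souting	spring	132	120	39	0.83	68	21
Tshipise	spring	120	110	30	0.74	64	31
Be326_2011	subsurface	14227	13328	551	0.80	716	37
Be326_2012	subsurface	23343	21806	634	0.80	739	25
Dr5IPC	subsurface	18215	15876	549	0.80	653	24
FI88	subsurface	18719	17282	573	0.78	725	34
MM51940	subsurface	22984	20768	655	0.80	760	24
NO14	subsurface	22237	20676	640	0.79	744	24
TT109	subsurface	19367	17792	569	0.77	689	27
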