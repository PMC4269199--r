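site	Latitude (S)	Longitude (E)	elevation_masl	temperature_C	pH	TDS_ppm	O2_M	Na_M	K_M	Ca_M	Mg_M	NO3_M	Cl_M	SO4_M	HPO4_M	DIC_M
Eiland	23°39′31″	30°40′23.6″	433	40-42	7.63	>1862	n.a.	2.7e-2	5.6e-4	1.3e-3	3.9e-4	4.0e-5	2.8e-2	1.5e-3	2.6e-4	<d.l.
Mphephu	22°54′20″	30°10′38″	796	43	8.08-8.19	275	1.3e-4	1.9e-3	2.9e-5	3.4e-4	4.6e-4	3.4e-5	1.1e-3	9.5e-5	<d.l.	2.5e-3
Sagole	22°31′45.4″	30°40′50″	446	45	9.24-9.70	237	1.9e-5	2.8e-3	2.8e-5	3.3e-5	2.9e-6	<d.l.	1.4e-3	1.9e-4	<d.l.	2.0e-3
Siloam	22°53′22.6″	30°11′39″	841	63-67	8.8-9.5	252	6.9e-5	2.9e-3	7.2e-5	3.4e-5	5.5e-4	<d.l.	1.3e-3	1.1e-5	<d.l.	2.0e-3
Souting	23°25′9″	30°54′44″	389	40.1-43.9	7.8	10130	n.a.	1.5e-1	7.9e-4	6.0e-3	3.3e-3	4.3e-5	1.6e-1	7.9e-3	<2.5e-5	n.a.
Tshipise	22°36′31.5″	30°10′16.7″	542	58	8.3-8.94	523	6.1e-5	6.8e-3	1.1e-4	1.4e-4	6.7e-6	9.8e-6	4.8e-3	5.5e-4	2.8e-5	2.2e-3
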