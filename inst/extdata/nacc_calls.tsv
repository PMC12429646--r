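gene	system	call_c1	call_c2	call_c3
Th	catecholaminergic	up	down	down
Slc6a3	catecholaminergic	up	ns	ns
Adra1a	catecholaminergic	up	ns	ns
Slc18a2	catecholaminergic	up	ns	ns
Adra2a	catecholaminergic	down	ns	ns
Drd1	catecholaminergic	down	up	ns
Maoa	catecholaminergic	down	down	down
Maob	catecholaminergic	down	ns	up
Ppp1r1b	catecholaminergic	down	up	ns
Snca	catecholaminergic	down	ns	ns
Adra2c	catecholaminergic	ns	up	ns
Drd2	catecholaminergic	ns	up	ns
Drd3	catecholaminergic	ns	ns	up
Adrb1	catecholaminergic	ns	ns	up
Oprd1	opioidergic_cannabinoidergic	up	ns	ns
Cnr1	opioidergic_cannabinoidergic	down	ns	ns
Faah	opioidergic_cannabinoidergic	down	ns	ns
Oprk1	opioidergic_cannabinoidergic	ns	ns	up
Pdyn	opioidergic_cannabinoidergic	ns	ns	up
Penk	opioidergic_cannabinoidergic	ns	up	ns
Htr1f	serotonergic	up	ns	down
Htr2c	serotonergic	down	ns	up
Htr1d	serotonergic	down	ns	up
Htr1a	serotonergic	ns	up	up
Htr3a	serotonergic	ns	ns	down
Slc6a11	GABAergic	up	ns	ns
Gabra5	GABAergic	up	up	ns
Gabrb2	GABAergic	up	ns	ns
Gabrb3	GABAergic	up	ns	ns
Gabbr2	GABAergic	down	ns	ns
Gabrg1	GABAergic	down	ns	ns
Grin2a	glutamatergic	up	ns	ns
Grin2d	glutamatergic	up	ns	ns
Grid2ip	glutamatergic	up	ns	ns
Grik1	glutamatergic	up	ns	ns
Grik3	glutamatergic	up	ns	ns
Gria4	glutamatergic	up	ns	ns
Grin1	glutamatergic	up	ns	ns
Grm1	glutamatergic	up	ns	ns
Grm4	glutamatergic	up	ns	ns
Grm8	glutamatergic	up	ns	ns
Gad2	glutamatergic	up	ns	ns
Gad1	glutamatergic	up	down	ns
Grm2	glutamatergic	up	down	ns
Gria3	glutamatergic	down	ns	ns
Grm3	glutamatergic	down	ns	ns
Slc17a7	glutamatergic	down	ns	ns
Slc17a8	glutamatergic	down	ns	ns
Grid1	glutamatergic	ns	up	ns
Grin3a	glutamatergic	ns	up	ns
Grik4	glutamatergic	ns	up	ns
Grik5	glutamatergic	ns	up	ns
Grm5	glutamatergic	ns	up	ns
Grm7	glutamatergic	ns	ns	up
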