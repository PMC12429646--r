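gene	system	subclass
Th	catecholaminergic	enzyme
Ddc	catecholaminergic	enzyme
Dbh	catecholaminergic	enzyme
Maoa	catecholaminergic	enzyme
Maob	catecholaminergic	enzyme
Comt	catecholaminergic	enzyme
Slc6a2	catecholaminergic	transporter
Slc6a3	catecholaminergic	transporter
Slc18a2	catecholaminergic	transporter
Snca	catecholaminergic	
Sncb	catecholaminergic	
Sncg	catecholaminergic	
Ppp1r1b	catecholaminergic	
Drd1	catecholaminergic	receptor
Drd2	catecholaminergic	receptor
Drd3	catecholaminergic	receptor
Drd4	catecholaminergic	receptor
Drd5	catecholaminergic	receptor
Adra1a	catecholaminergic	receptor
Adra1b	catecholaminergic	receptor
Adra1d	catecholaminergic	receptor
Adra2a	catecholaminergic	receptor
Adra2b	catecholaminergic	receptor
Adra2c	catecholaminergic	receptor
Adrb1	catecholaminergic	receptor
Adrb2	catecholaminergic	receptor
Adrb3	catecholaminergic	receptor
Adrbk1	catecholaminergic	enzyme
Adrbk2	catecholaminergic	enzyme
Pdyn	opioidergic_cannabinoidergic	peptide_precursor
Penk	opioidergic_cannabinoidergic	peptide_precursor
Pomc	opioidergic_cannabinoidergic	peptide_precursor
Pnoc	opioidergic_cannabinoidergic	peptide_precursor
Oprm1	opioidergic_cannabinoidergic	receptor
Oprd1	opioidergic_cannabinoidergic	receptor
Oprk1	opioidergic_cannabinoidergic	receptor
Opcml	opioidergic_cannabinoidergic	
Ogfr	opioidergic_cannabinoidergic	receptor
Ogfrl1	opioidergic_cannabinoidergic	receptor
Cnr1	opioidergic_cannabinoidergic	receptor
Cnr2	opioidergic_cannabinoidergic	receptor
Faah	opioidergic_cannabinoidergic	enzyme
Tph2	serotonergic	enzyme
Ddc	serotonergic	enzyme
Maoa	serotonergic	enzyme
Maob	serotonergic	enzyme
Htr1a	serotonergic	receptor
Htr1b	serotonergic	receptor
Htr2a	serotonergic	receptor
Htr2c	serotonergic	receptor
Htr3a	serotonergic	receptor
Htr4	serotonergic	receptor
Htr5b	serotonergic	receptor
Htr6	serotonergic	receptor
Htr7	serotonergic	receptor
Htr1d	serotonergic	receptor
Htr1f	serotonergic	receptor
Htr2b	serotonergic	receptor
Htr3b	serotonergic	receptor
Htr5a	serotonergic	receptor
Slc6a4	serotonergic	transporter
Slc18a2	serotonergic	transporter
Gabra1	GABAergic	ionotropic_receptor
Gabra2	GABAergic	ionotropic_receptor
Gabra3	GABAergic	ionotropic_receptor
Gabra4	GABAergic	ionotropic_receptor
Gabra5	GABAergic	ionotropic_receptor
Gabra6	GABAergic	ionotropic_receptor
Gabrb1	GABAergic	ionotropic_receptor
Gabrb2	GABAergic	ionotropic_receptor
Gabrb3	GABAergic	ionotropic_receptor
Gabrg1	GABAergic	ionotropic_receptor
Gabrg2	GABAergic	ionotropic_receptor
Gabrg3	GABAergic	ionotropic_receptor
Gabrd	GABAergic	ionotropic_receptor
Gabre	GABAergic	ionotropic_receptor
Gabrp	GABAergic	ionotropic_receptor
Gabrq	GABAergic	ionotropic_receptor
Gabbr1	GABAergic	metabotropic_receptor
Gabbr2	GABAergic	metabotropic_receptor
Gabrr1	GABAergic	ionotropic_receptor
Gabrr2	GABAergic	ionotropic_receptor
Gabrr3	GABAergic	ionotropic_receptor
Slc6a11	GABAergic	transporter
Slc6a13	GABAergic	transporter
Gria1	glutamatergic	ionotropic_receptor
Gria2	glutamatergic	ionotropic_receptor
Gria3	glutamatergic	ionotropic_receptor
Gria4	glutamatergic	ionotropic_receptor
Grik1	glutamatergic	ionotropic_receptor
Grik2	glutamatergic	ionotropic_receptor
Grik3	glutamatergic	ionotropic_receptor
Grik4	glutamatergic	ionotropic_receptor
Grik5	glutamatergic	ionotropic_receptor
Grin1	glutamatergic	ionotropic_receptor
Grin2a	glutamatergic	ionotropic_receptor
Grin2b	glutamatergic	ionotropic_receptor
Grin2c	glutamatergic	ionotropic_receptor
Grin2d	glutamatergic	ionotropic_receptor
Grin3a	glutamatergic	ionotropic_receptor
Grin3b	glutamatergic	ionotropic_receptor
Grm1	glutamatergic	metabotropic_receptor
Grm2	glutamatergic	metabotropic_receptor
Grm3	glutamatergic	metabotropic_receptor
Grm4	glutamatergic	metabotropic_receptor
Grm5	glutamatergic	metabotropic_receptor
Grm6	glutamatergic	metabotropic_receptor
Grm7	glutamatergic	metabotropic_receptor
Grm8	glutamatergic	metabotropic_receptor
Grid1	glutamatergic	ionotropic_receptor
Grid2	glutamatergic	ionotropic_receptor
Grid2ip	glutamatergic	ionotropic_receptor
Gad1	glutamatergic	decarboxylase
Gad2	glutamatergic	decarboxylase
Slc17a6	glutamatergic	transporter
Slc17a7	glutamatergic	transporter
Slc17a8	glutamatergic	transporter
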