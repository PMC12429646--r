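gene	Adra2c	Drd1	Drd2	Drd3	Oprk1	Pdyn	Penk	Ppp1r1b
Adra2c	1	0.965	0.935	0.851	0.966	0.958	0.945	0.974
Drd1	0.965	1	0.983	0.947	0.991	0.99	0.983	0.993
Drd2	0.935	0.983	1	0.975	0.99	0.993	0.995	0.987
Drd3	0.851	0.947	0.975	1	0.944	0.948	0.959	0.945
Oprk1	0.966	0.991	0.99	0.944	1	0.996	0.997	0.997
Pdyn	0.958	0.99	0.993	0.948	0.996	1	0.995	0.99
Penk	0.945	0.983	0.995	0.959	0.997	0.995	1	0.991
Ppp1r1b	0.974	0.993	0.987	0.945	0.997	0.99	0.991	1
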