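gene	is_top_gwas_gene	has_missense_in_ld	has_blood_eqtl	go_bp	go_cc	go_mf	is_pid_gene
IL6R	1	1	1	1	1	1	0
F5	1	1	1	1	1	0	0
ABO	1	1	1	1	0	1	0
F2	0	1	0	1	1	1	0
F9	0	1	0	1	1	1	0
F11	0	1	1	1	1	0	0
IL1RN	0	0	1	1	1	0	1
KLKB1	0	1	1	1	0	1	0
SH2B3	1	1	1	1	0	0	0
FGB	1	0	1	1	1	0	0
VWF	0	1	1	1	1	0	0
FGA	1	0	1	1	1	0	0
ADAMTS13	0	1	1	1	0	1	0
THBD	0	0	1	1	1	1	0
PLCG2	0	1	1	1	0	0	0
ST3GAL4	0	0	1	1	1	0	0
PROC	0	1	0	1	1	0	0
PLEK	0	0	1	1	0	1	0
ATP1B1	1	0	1	1	0	0	0
NME7	1	0	1	0	1	0	0
FGG	0	0	1	1	1	0	0
PROCR	0	1	0	1	1	0	0
SLC44A2	0	1	1	1	0	0	0
TSPAN15	0	0	1	1	0	1	0
F8	0	1	0	1	1	0	0
SERPINC1	0	0	0	1	1	1	0
PROS1	0	1	0	1	1	0	0
GP6	0	1	1	0	1	0	0
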