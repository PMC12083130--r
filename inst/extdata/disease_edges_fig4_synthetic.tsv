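gene	concept_id	concept_label	source
F2	DOID:0001	deep vein thrombosis	disease
F5	DOID:0001	deep vein thrombosis	disease
PROC	DOID:0001	deep vein thrombosis	disease
F9	DOID:0001	deep vein thrombosis	disease
THBD	DOID:0001	deep vein thrombosis	disease
F2	DOID:0002	thrombophilia	disease
F5	DOID:0002	thrombophilia	disease
PROC	DOID:0002	thrombophilia	disease
F5	HP:0001	venous thrombosis	phenotype
F2	HP:0001	venous thrombosis	phenotype
F11	HP:0002	prolonged partial thromboplastin time	phenotype
KLKB1	HP:0002	prolonged partial thromboplastin time	phenotype
F9	HP:0002	prolonged partial thromboplastin time	phenotype
FGB	DOID:0003	congenital afibrinogenemia	disease
FGA	DOID:0003	congenital afibrinogenemia	disease
VWF	DOID:0004	von Willebrand disease	disease
ADAMTS13	DOID:0005	thrombotic thrombocytopenic purpura	disease
SH2B3	DOID:0006	myeloproliferative neoplasm	disease
PLCG2	DOID:0007	immune dysregulation syndrome	disease
PLEK	HP:0003	abnormal platelet function	phenotype
ST3GAL4	HP:0004	abnormal protein glycosylation	phenotype
THBD	HP:0005	abnormal thrombosis	phenotype
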